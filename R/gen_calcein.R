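#' Generate a synthetic calcein time-lapse with ground truth
#'
#' Renders `n_mito` adsorbed, calcein-loaded mitochondria as diffraction-
#' blurred spots on a dark field and acquires `config$n_frames` frames at
#' `config$frame_interval_min` intervals. A mitochondrion undergoing
#' permeability transition loses its trapped calcein abruptly: at its event
#' frame the spot's integrated intensity drops by the specified fraction in a
#' single frame step. Positions are fixed across frames (the dish is
#' stationary). The manifest records, per object, the centre, diameter,
#' rendered intensity, event frame and drop fraction, so every downstream
#' quantity has an exact ground truth.
#'
#' @param config A [sim_config()].
#' @param n_mito Number of mitochondria to render (>= 0).
#' @param event_spec `NULL` (no events) or a data frame with one row per
#'   mitochondrion and columns `event_frame` (1-based frame index at which the
#'   drop appears, or `NA` for no event) and `drop_fraction` (fraction of the
#'   pre-event intensity lost, in (0, 1]).
#' @param amplitude Mean integrated spot intensity, arbitrary units.
#' @param amplitude_cv Coefficient of variation of per-object intensities.
#' @param diameter_um Spot diameter; a scalar for a mono-disperse field or a
#'   length-2 range sampled uniformly. Defaults to `config$particle_diameter_um`.
#' @param event_shape `"step"` (abrupt single-frame loss, the permeability-
#'   transition signature) or `"ramp"` (the same total loss spread linearly
#'   over the remaining frames; a negative control that must not trigger the
#'   per-interval caller).
#' @param centers Optional data frame of 0-based integer centres (`x`, `y`).
#'   Centres closer than one spot diameter are rejected with an error.
#' @return A list with `bundle` (an [image_bundle()] of class `"calcein"`) and
#'   `manifest` (a `ground_truth` object; see [manifest_objects()]).
#' @examples
#' sim <- gen_calcein_timelapse(sim_config(seed = 1, field_px = 64), n_mito = 3)
#' sim$manifest$objects
#' @export
gen_calcein_timelapse <- function(config, n_mito, event_spec = NULL,
                                  amplitude = 1000, amplitude_cv = 0,
                                  diameter_um = NULL,
                                  event_shape = c("step", "ramp"),
                                  centers = NULL) {
  stopifnot(inherits(config, "sim_config"), n_mito >= 0,
            n_mito == round(n_mito))
  event_shape <- match.arg(event_shape)
  n_mito <- as.integer(n_mito)
  if (is.null(diameter_um)) diameter_um <- config$particle_diameter_um
  set.seed(config$seed)

  if (is.null(event_spec)) {
    event_spec <- data.frame(event_frame = rep(NA_integer_, n_mito),
                             drop_fraction = rep(NA_real_, n_mito))
  }
  stopifnot(is.data.frame(event_spec), nrow(event_spec) == n_mito,
            all(c("event_frame", "drop_fraction") %in% names(event_spec)))
  ev <- event_spec$event_frame
  if (any(!is.na(ev) & (ev < 2 | ev > config$n_frames))) {
    stop("event frames must lie in 2..n_frames")
  }
  dr <- event_spec$drop_fraction
  if (any(!is.na(ev) & (is.na(dr) | dr <= 0 | dr > 1))) {
    stop("drop_fraction must lie in (0, 1] wherever an event frame is given")
  }

  d_um <- if (length(diameter_um) == 1L || diameter_um[1] == diameter_um[2]) {
    rep(diameter_um[1], n_mito)
  } else {
    stats::runif(n_mito, diameter_um[1], diameter_um[2])
  }
  r_px <- if (n_mito > 0) {
    vapply(d_um, spot_footprint_radius_px, integer(1), pixel_size_um = config$pixel_size_um)
  } else integer(0)
  dim <- c(config$field_px, config$field_px)

  if (is.null(centers)) {
    min_sep <- if (n_mito > 0) 2 * max(r_px) + 2 else 0
    centers <- place_centers(n_mito, dim, min_sep, if (n_mito > 0) max(r_px) + 1L else 0L)
  } else {
    stopifnot(is.data.frame(centers), nrow(centers) == n_mito)
    if (n_mito > 1) {
      dmat <- as.matrix(stats::dist(cbind(centers$x, centers$y))) * config$pixel_size_um
      lim <- outer(d_um, d_um, function(a, b) pmax(a, b))
      diag(dmat) <- Inf
      if (any(dmat < lim)) {
        stop("spot centers closer than one diameter: per-object truth would be ambiguous")
      }
    }
  }

  amp <- amplitude * pmax(0.05, 1 + amplitude_cv * stats::rnorm(n_mito))
  tp <- (seq_len(config$n_frames) - 1) * config$frame_interval_min

  kernels <- lapply(seq_len(n_mito), function(i) {
    spot_kernel(d_um[i], config$pixel_size_um, 1)
  })

  frames <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames)) {
    img <- matrix(0, dim[1], dim[2])
    for (i in seq_len(n_mito)) {
      a <- amp[i]
      if (!is.na(ev[i]) && f >= ev[i]) {
        if (event_shape == "step") {
          a <- amp[i] * (1 - dr[i])
        } else {
          span <- max(1L, config$n_frames - ev[i] + 1L)
          prog <- (f - ev[i] + 1L) / span
          a <- amp[i] * (1 - dr[i] * prog)
        }
      }
      img <- add_kernel(img, centers$x[i], centers$y[i], kernels[[i]] * a)
    }
    frames[[f]] <- add_noise(img, config$noise_sd)
  }

  objects <- data.frame(
    object_id = if (n_mito > 0) sprintf("mito%03d", seq_len(n_mito)) else character(),
    class = rep("mitochondrion", n_mito),
    x = centers$x, y = centers$y,
    diameter_um = d_um,
    amplitude = amp,
    footprint_radius_px = r_px,
    mpt_event_frame = as.integer(ev),
    drop_fraction = as.numeric(dr),
    stringsAsFactors = FALSE
  )
  list(
    bundle = image_bundle(frames, "calcein", timepoints_min = tp,
                          pixel_size_um = config$pixel_size_um),
    manifest = new_manifest("calcein_timelapse", objects, config,
                            extra = list(event_shape = event_shape))
  )
}
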