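#' Generate transmitted-light z-stack series with ground truth
#'
#' Emulates the swelling morphometry acquisition: at each timepoint a z-stack
#' of `config$n_slices` transmitted-light slices at `config$z_step_um` spacing
#' is captured over a field of adsorbed mitochondria. The blank field has
#' normalized intensity 1; each particle attenuates the light over a disc of
#' its own diameter, most strongly in its focal slice, so that the darkest
#' in-focus pixels equal the particle's transmittance ratio exactly. Swelling
#' raises a particle's transmittance from `baseline` to `post` at its onset
#' time (swollen mitochondria scatter less and transmit more light).
#'
#' @param config A [sim_config()]. The z-stack channel is acquired at higher
#'   magnification than the time-lapse, so the default pixel size is
#'   `config$pixel_size_um / 2`.
#' @param n_mito Number of particles.
#' @param swell_spec `NULL` or a data frame with one row per particle and
#'   columns `baseline`, `post` (transmittance ratios in (0, 1]) and
#'   `onset_min` (`NA` for a particle that never swells). Default: all
#'   particles at baseline 0.6, no swelling.
#' @param timepoints_min Acquisition times (minutes); the first is the
#'   pre-exposure baseline.
#' @param diameter_um Particle diameter (um), scalar or range.
#' @param axial_sigma_um Axial extent of the defocus attenuation profile.
#' @param pixel_size_um Pixel size for this channel; see above.
#' @return A list with `stacks` (a list of [image_bundle()] z-stacks, one per
#'   timepoint), `timepoints_min`, and `manifest` carrying per-particle truth
#'   (centre, diameter, focal slice, baseline/post transmittance, onset).
#' @export
gen_transmittance_zstacks <- function(config, n_mito, swell_spec = NULL,
                                      timepoints_min = 0:10,
                                      diameter_um = 2,
                                      axial_sigma_um = 0.4,
                                      pixel_size_um = config$pixel_size_um / 2) {
  stopifnot(inherits(config, "sim_config"), n_mito >= 0,
            length(timepoints_min) >= 1)
  n_mito <- as.integer(n_mito)
  set.seed(config$seed)

  if (is.null(swell_spec)) {
    swell_spec <- data.frame(baseline = rep(0.6, n_mito),
                             post = rep(0.6, n_mito),
                             onset_min = rep(NA_real_, n_mito))
  }
  stopifnot(is.data.frame(swell_spec), nrow(swell_spec) == n_mito,
            all(c("baseline", "post", "onset_min") %in% names(swell_spec)))
  tr <- c(swell_spec$baseline, swell_spec$post)
  if (any(!is.na(tr) & (tr <= 0 | tr > 1))) {
    stop("transmittance values must lie in (0, 1]; transmittance > 1 requested")
  }

  d_um <- if (length(diameter_um) == 1L || diameter_um[1] == diameter_um[2]) {
    rep(diameter_um[1], n_mito)
  } else stats::runif(n_mito, diameter_um[1], diameter_um[2])
  r_px <- d_um / 2 / pixel_size_um
  dim <- c(config$field_px, config$field_px)
  min_sep <- if (n_mito > 0) 2 * max(ceiling(r_px)) + 4 else 0
  centers <- place_centers(n_mito, dim, min_sep,
                           if (n_mito > 0) max(ceiling(r_px)) + 2L else 0L)

  # Focal slice chosen among interior slices so the defocus profile peaks
  # exactly at an acquired plane (min intensity is then exactly blank * T).
  interior <- max(2L, ceiling(config$n_slices * 0.25)):
    min(config$n_slices - 1L, floor(config$n_slices * 0.75))
  focus <- if (n_mito > 0) sample(interior, n_mito, replace = TRUE) else integer(0)

  z <- (seq_len(config$n_slices) - 1) * config$z_step_um
  discs <- lapply(seq_len(n_mito), function(i) {
    disc_indices(centers$x[i], centers$y[i], r_px[i], dim)
  })

  stacks <- vector("list", length(timepoints_min))
  for (ti in seq_along(timepoints_min)) {
    t <- timepoints_min[ti]
    slices <- vector("list", config$n_slices)
    t_now <- ifelse(!is.na(swell_spec$onset_min) & t >= swell_spec$onset_min,
                    swell_spec$post, swell_spec$baseline)
    for (si in seq_len(config$n_slices)) {
      img <- matrix(1, dim[1], dim[2])
      for (i in seq_len(n_mito)) {
        f <- exp(-0.5 * ((z[si] - z[focus[i]]) / axial_sigma_um)^2)
        img[discs[[i]]] <- 1 - (1 - t_now[i]) * f
      }
      slices[[si]] <- add_noise(img, config$noise_sd)
    }
    stacks[[ti]] <- image_bundle(slices, "transmitted", z_um = z,
                                 pixel_size_um = pixel_size_um)
  }

  objects <- data.frame(
    object_id = if (n_mito > 0) sprintf("mito%03d", seq_len(n_mito)) else character(),
    class = rep("mitochondrion", n_mito),
    x = centers$x, y = centers$y,
    diameter_um = d_um,
    focus_slice = as.integer(focus),
    transmittance_baseline = swell_spec$baseline,
    transmittance_post = swell_spec$post,
    swelling_onset_min = swell_spec$onset_min,
    stringsAsFactors = FALSE
  )
  list(
    stacks = stacks,
    timepoints_min = timepoints_min,
    manifest = new_manifest("transmittance_zstacks", objects, config,
                            extra = list(pixel_size_um = pixel_size_um,
                                         axial_sigma_um = axial_sigma_um))
  )
}
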