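# Per-mitochondrion decision rules: permeability-transition calling from
# calcein traces, swelling from transmittance series, polarization from TMRE
# intensity, and the electron-transport-chain response to malate.

#' Call mitochondrial permeability transition on a calcein trace
#'
#' A mitochondrion is scored as having undergone permeability transition (MPT)
#' if its integrated calcein fluorescence decreases by more than
#' `threshold` x 100% of its initial value within any single between-frame
#' interval (2 min at the default acquisition). A slow decline of the same
#' total magnitude spread over many intervals does not qualify: the rule is
#' per-interval, anchored by default to the trace's initial value.
#'
#' @param trace An `intensity_trace` (see [extract_trace()]) or a numeric
#'   vector of integrated intensities.
#' @param threshold Drop fraction; default 0.20.
#' @param relative_to `"initial"` (default; the drop is compared with
#'   `threshold * F(t0)`) or `"current"` (compared with `threshold * F(t)`,
#'   the alternative reading offered as a configuration switch).
#' @return An `mpt_call`: `underwent_mpt`, `event_interval` (1-based frame
#'   pair `c(i, i+1)` of the first qualifying interval or `NULL`),
#'   `drop_fraction` (largest single-interval drop as a fraction of the
#'   initial value), `roi_id`.
#' @examples
#' call_mpt(c(100, 100, 75, 74, 74))$underwent_mpt
#' @export
call_mpt <- function(trace, threshold = 0.20,
                     relative_to = c("initial", "current")) {
  relative_to <- match.arg(relative_to)
  v <- if (inherits(trace, "intensity_trace")) trace$values else as.numeric(trace)
  roi_id <- if (inherits(trace, "intensity_trace")) trace$roi_id else NULL
  if (length(v) < 2) stop("trace must have at least 2 timepoints")
  if (!is.finite(v[1]) || v[1] <= 0) stop("initial trace value must be positive")
  drops <- v[-length(v)] - v[-1]
  ref <- if (relative_to == "initial") {
    rep(threshold * v[1], length(drops))
  } else {
    threshold * v[-length(v)]
  }
  hit <- drops > ref
  first <- if (any(hit)) which(hit)[1] else NA_integer_
  structure(
    list(roi_id = roi_id,
         underwent_mpt = any(hit),
         event_interval = if (is.na(first)) NULL else c(first, first + 1L),
         drop_fraction = max(drops) / v[1]),
    class = "mpt_call"
  )
}

#' Percentage of mitochondria undergoing permeability transition
#'
#' @param calls Non-empty list of `mpt_call` objects (or a logical vector of
#'   per-object decisions).
#' @return Percentage (0-100) of flagged mitochondria.
#' @export
mpt_fraction <- function(calls) {
  if (is.list(calls)) {
    if (!length(calls)) stop("empty set of MPT calls")
    flags <- vapply(calls, function(x) isTRUE(x$underwent_mpt), logical(1))
  } else {
    flags <- as.logical(calls)
    if (!length(flags)) stop("empty set of MPT calls")
  }
  100 * mean(flags)
}

#' Transmittance ratio of one mitochondrion from a z-stack
#'
#' For every slice, the mean intensity over the darkest region of
#' `region_area_um2` (default 0.46 um^2) within the particle ROI is divided
#' by the mean intensity of an adjacent blank area; the minimum of these
#' blank-normalized ratios across the stack is the particle's transmittance.
#' Taking the slice-wise minimum of normalized ratios subsumes the two-stage
#' minimum (darkest intensity, then lowest ratio) because the blank is
#' constant across slices up to noise.
#'
#' @param zstack An [image_bundle()] whose frames are the z-slices.
#' @param roi Particle [roi()].
#' @param blank Blank [roi()] adjacent to the particle; its mean must be
#'   positive.
#' @param region_area_um2 Area of the averaged darkest region.
#' @return The transmittance ratio (a single number).
#' @export
compute_transmittance <- function(zstack, roi, blank, region_area_um2 = 0.46) {
  stopifnot(inherits(zstack, "image_bundle"), inherits(roi, "roi"),
            inherits(blank, "roi"), length(zstack$frames) >= 1)
  px_area <- zstack$pixel_size_um^2
  n_px <- max(1L, round(region_area_um2 / px_area))
  if (n_px > roi$area_px) n_px <- roi$area_px
  ratios <- vapply(zstack$frames, function(f) {
    b <- mean(f[blank$pixels])
    if (!is.finite(b) || b <= 0) stop("blank mean must be positive")
    mean(sort(f[roi$pixels], partial = n_px)[seq_len(n_px)]) / b
  }, numeric(1))
  min(ratios)
}

#' Transmittance series of one mitochondrion across timepoints
#'
#' Applies [compute_transmittance()] to each timepoint's z-stack.
#'
#' @param stacks List of [image_bundle()] z-stacks, one per timepoint.
#' @param roi,blank As in [compute_transmittance()].
#' @param timepoints_min Acquisition times (minutes).
#' @param region_area_um2 Darkest-region area.
#' @return A `transmittance_series`: `timepoints_min`, `transmittance`,
#'   `roi_id`.
#' @export
transmittance_series <- function(stacks, roi, blank, timepoints_min,
                                 region_area_um2 = 0.46) {
  stopifnot(length(stacks) == length(timepoints_min))
  tr <- vapply(stacks, compute_transmittance, numeric(1),
               roi = roi, blank = blank, region_area_um2 = region_area_um2)
  structure(list(timepoints_min = timepoints_min, transmittance = tr,
                 roi_id = roi$id),
            class = "transmittance_series")
}

#' Call swelling on a transmittance series
#'
#' A mitochondrion has swollen if the absolute change of its transmittance
#' from the pre-exposure baseline (the first timepoint) exceeds `threshold`
#' (0.16 by default) at any later timepoint. Swollen mitochondria scatter
#' less light, so the change is typically an increase; the absolute value is
#' used because the criterion is stated as a change.
#'
#' @param series A `transmittance_series` (see [transmittance_series()]) or a
#'   numeric vector of transmittance ratios whose first element is the
#'   baseline.
#' @param threshold Transmittance-change threshold.
#' @return The series augmented with `baseline`, `change` (max absolute
#'   deviation from baseline) and `swollen`.
#' @examples
#' call_swelling(c(0.60, 0.62, 0.80))$swollen
#' @export
call_swelling <- function(series, threshold = 0.16) {
  tr <- if (inherits(series, "transmittance_series")) series$transmittance
        else as.numeric(series)
  if (length(tr) < 2) stop("need at least 2 timepoints to call swelling")
  baseline <- tr[1]
  change <- max(abs(tr[-1] - baseline))
  out <- if (inherits(series, "transmittance_series")) series else
    structure(list(timepoints_min = seq_along(tr), transmittance = tr,
                   roi_id = NULL), class = "transmittance_series")
  out$baseline <- baseline
  out$change <- change
  out$swollen <- change > threshold
  out
}

#' Classify membrane-potential polarization from TMRE intensity
#'
#' A particle is polarized when its raw integrated TMRE intensity exceeds the
#' local background by at least `ratio_threshold`-fold: the ratio is
#' `tmre_integrated / (background_per_pixel * area_px)`, so a particle with no
#' TMRE accumulation sits at ratio 1 and is depolarized.
#'
#' @param tmre_integrated Raw integrated TMRE intensity over the ROI.
#' @param background_per_pixel Local background level per pixel (> 0).
#' @param area_px ROI area in pixels.
#' @param ratio_threshold Polarization ratio threshold (default 2; the
#'   absolute value is a configuration choice, and cohort-level checks use
#'   ground-truth recovery rather than this number).
#' @param roi_id,substrate Metadata carried into the call.
#' @return A `polarization_call`: `polarized`, `tmre_over_background`,
#'   `substrate`, `roi_id`.
#' @export
classify_polarization <- function(tmre_integrated, background_per_pixel,
                                  area_px, ratio_threshold = 2,
                                  roi_id = NULL,
                                  substrate = c("none", "malate", "succinate")) {
  substrate <- match.arg(substrate)
  if (!is.finite(background_per_pixel) || background_per_pixel <= 0) {
    stop("background must be positive")
  }
  ratio <- tmre_integrated / (background_per_pixel * area_px)
  structure(
    list(roi_id = roi_id, polarized = ratio >= ratio_threshold,
         tmre_over_background = ratio, substrate = substrate),
    class = "polarization_call"
  )
}

#' Electron-transport-chain response to malate
#'
#' Per-cell TMRE fluorescence is followed over 10 frames at 1-min intervals;
#' malate is added between frames `malate_frame` and `malate_frame + 1`
#' (between the third and fourth images by default). The response is the mean
#' of the post-addition plateau minus the mean of the pre-addition frames,
#' skipping the first post-addition frame to avoid the mixing transient, and
#' is optionally normalized so that untreated control cells score 100.
#'
#' @param series Numeric vector of per-cell integrated TMRE intensities, one
#'   per frame.
#' @param malate_frame Last pre-addition frame index (default 3).
#' @param control_increase Mean increase of untreated control cells; when
#'   given (must be > 0) the normalized response is returned as a percentage
#'   of control.
#' @param cell_id Metadata.
#' @return An `etc_response`: `increase`, `normalized_increase` (or `NA`),
#'   `pre_frames`, `post_frames`, `cell_id`.
#' @export
etc_response <- function(series, malate_frame = 3, control_increase = NULL,
                         cell_id = NULL) {
  series <- as.numeric(series)
  if (length(series) < malate_frame + 2) {
    stop("series too short for the requested malate frame")
  }
  pre <- seq_len(malate_frame)
  post <- (malate_frame + 2L):length(series)
  increase <- mean(series[post]) - mean(series[pre])
  norm <- NA_real_
  if (!is.null(control_increase)) {
    if (!is.finite(control_increase) || control_increase <= 0) {
      stop("control_increase must be positive for normalization")
    }
    norm <- 100 * increase / control_increase
  }
  structure(
    list(cell_id = cell_id, increase = increase, normalized_increase = norm,
         pre_frames = pre, post_frames = post),
    class = "etc_response"
  )
}
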