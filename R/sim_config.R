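#' Simulation configuration for synthetic microscopy
#'
#' Bundles the acquisition geometry shared by all synthetic-image generators:
#' pixel size, frame timing of the calcein time-lapse (11 frames at 2-min
#' intervals, t = 0..20 min), z-stack geometry of the transmitted-light
#' morphometry (20 slices at 0.2 um steps), the particle-diameter range that
#' defines an individual mitochondrion (0.5-3 um), additive Gaussian noise, and
#' the random seed. Identical configuration plus identical seed yields
#' bit-identical synthetic output.
#'
#' @param pixel_size_um Pixel size in micrometres per pixel. The instrument
#'   class emulated here (CCD with 2x2 binning behind a 20x objective) is
#'   typically ~0.325 um/px; transmitted-light stacks acquired at 40x halve
#'   this, so the z-stack generator defaults to `pixel_size_um / 2` unless
#'   overridden.
#' @param frame_interval_min Time between calcein frames, minutes.
#' @param n_frames Number of calcein time-lapse frames.
#' @param z_step_um Axial step between z-slices, micrometres.
#' @param n_slices Number of z-slices per transmitted-light stack.
#' @param particle_diameter_um Length-2 range (um) of particle diameters
#'   regarded as single mitochondria.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in the
#'   intensity units of the channel being generated (arbitrary units for
#'   fluorescence; fraction of the blank level for transmitted light).
#' @param seed Integer random seed consumed by every generator call.
#' @param exposure_model Detector response model; only `"linear"` is
#'   implemented (counts proportional to photon flux).
#' @param field_px Edge length of the square synthetic field, pixels.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_frames
#' @export
sim_config <- function(pixel_size_um = 0.325,
                       frame_interval_min = 2,
                       n_frames = 11,
                       z_step_um = 0.2,
                       n_slices = 20,
                       particle_diameter_um = c(0.5, 3),
                       noise_sd = 0,
                       seed = 1L,
                       exposure_model = "linear",
                       field_px = 256L) {
  stopifnot(
    is.numeric(pixel_size_um), length(pixel_size_um) == 1L, pixel_size_um > 0,
    is.numeric(frame_interval_min), frame_interval_min > 0,
    is.numeric(n_frames), n_frames >= 1, n_frames == round(n_frames),
    is.numeric(z_step_um), z_step_um > 0,
    is.numeric(n_slices), n_slices >= 1, n_slices == round(n_slices),
    is.numeric(particle_diameter_um), length(particle_diameter_um) %in% 1:2,
    all(particle_diameter_um > 0),
    is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
    is.numeric(seed), length(seed) == 1L, seed == round(seed),
    is.numeric(field_px), field_px >= 16, field_px == round(field_px)
  )
  exposure_model <- match.arg(exposure_model, "linear")
  if (length(particle_diameter_um) == 1L) {
    particle_diameter_um <- rep(particle_diameter_um, 2L)
  }
  if (particle_diameter_um[1] > particle_diameter_um[2]) {
    stop("particle_diameter_um must be an increasing range")
  }
  structure(
    list(
      pixel_size_um = as.numeric(pixel_size_um),
      frame_interval_min = as.numeric(frame_interval_min),
      n_frames = as.integer(n_frames),
      z_step_um = as.numeric(z_step_um),
      n_slices = as.integer(n_slices),
      particle_diameter_um = as.numeric(particle_diameter_um),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed),
      exposure_model = exposure_model,
      field_px = as.integer(field_px)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-microscopy configuration\n")
  cat(sprintf("  pixel size      : %.4g um/px (field %d x %d px)\n",
              x$pixel_size_um, x$field_px, x$field_px))
  cat(sprintf("  time-lapse      : %d frames every %g min\n",
              x$n_frames, x$frame_interval_min))
  cat(sprintf("  z-stack         : %d slices at %g um\n",
              x$n_slices, x$z_step_um))
  cat(sprintf("  particle gate   : %g-%g um\n",
              x$particle_diameter_um[1], x$particle_diameter_um[2]))
  cat(sprintf("  noise sd        : %g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

#' Construct an image bundle
#'
#' Light container used throughout the package for a stack of same-shaped 2-D
#' frames from one channel: a time-lapse (frames indexed by time) or a z-stack
#' (frames indexed by axial position).
#'
#' @param frames List of numeric matrices, all of identical dimension.
#' @param channel One of `"calcein"`, `"GFP"`, `"TMRE"`, `"MSR"`,
#'   `"transmitted"`.
#' @param timepoints_min Optional numeric vector of acquisition times
#'   (minutes), strictly increasing, one per frame.
#' @param z_um Optional numeric vector of axial positions (um), one per frame.
#' @param pixel_size_um Pixel size, um/px.
#' @return An object of class `image_bundle`.
#' @export
image_bundle <- function(frames, channel, timepoints_min = NULL, z_um = NULL,
                         pixel_size_um) {
  channel <- match.arg(channel, c("calcein", "GFP", "TMRE", "MSR", "transmitted"))
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimension")
  if (!is.null(timepoints_min)) {
    stopifnot(length(timepoints_min) == length(frames))
    if (any(diff(timepoints_min) <= 0)) {
      stop("timepoints_min must be strictly increasing")
    }
  }
  if (!is.null(z_um)) stopifnot(length(z_um) == length(frames))
  structure(
    list(frames = frames, channel = channel, timepoints_min = timepoints_min,
         z_um = z_um, pixel_size_um = pixel_size_um, dim = d),
    class = "image_bundle"
  )
}

#' @export
print.image_bundle <- function(x, ...) {
  cat(sprintf("<image_bundle> %s, %d frame(s) of %d x %d px (%.4g um/px)\n",
              x$channel, length(x$frames), x$dim[1], x$dim[2], x$pixel_size_um))
  invisible(x)
}
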