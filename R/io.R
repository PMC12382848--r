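# Multi-page TIFF I/O for image bundles. Intensities are stored as 32-bit
# float pages scaled into [0, 1] by a bundle-wide factor recorded in a JSON
# sidecar together with channel/time/z metadata, so a round trip restores
# the original arrays and axes.

#' Write / read an image bundle as multi-page TIFF plus JSON sidecar
#'
#' @param bundle An [image_bundle()].
#' @param path Output `.tif` path; the sidecar is written at `<path>.json`.
#' @return `write_bundle_tiff` returns `path` invisibly; `read_bundle_tiff`
#'   returns the reconstructed [image_bundle()].
#' @export
write_bundle_tiff <- function(bundle, path) {
  stopifnot(inherits(bundle, "image_bundle"))
  hi <- max(1e-12, max(vapply(bundle$frames, max, numeric(1))))
  lo <- min(0, min(vapply(bundle$frames, min, numeric(1))))
  scale <- hi - lo
  pages <- lapply(bundle$frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channel = bundle$channel, scale = scale, offset = lo,
               timepoints_min = bundle$timepoints_min, z_um = bundle$z_um,
               pixel_size_um = bundle$pixel_size_um)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bundle_tiff
#' @export
read_bundle_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(p) p * meta$scale + meta$offset)
  image_bundle(frames, meta$channel,
               timepoints_min = meta$timepoints_min,
               z_um = meta$z_um,
               pixel_size_um = meta$pixel_size_um)
}
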