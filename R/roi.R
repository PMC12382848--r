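# Regions of interest: binary pixel masks with 0-based, row-major pixel-centre
# coordinates. Stored sparsely as 1-based linear indices plus the image
# dimension, which keeps whole-field ROI sets cheap.

#' Construct a region of interest
#'
#' @param pixels Integer vector of 1-based linear pixel indices into an image
#'   of dimension `dim`, or a logical mask matrix (in which case `dim` is
#'   taken from the mask).
#' @param dim Image dimension `c(nrow, ncol)` (ignored when `pixels` is a
#'   mask).
#' @param pixel_size_um Pixel size used to express the equivalent diameter in
#'   micrometres.
#' @param id Optional identifier.
#' @return An object of class `roi` with fields `pixels`, `dim`, `centroid`
#'   (0-based `c(x, y)`), `area_px` and `equivalent_diameter_um` (diameter of
#'   the circle whose area equals the mask area).
#' @export
roi <- function(pixels, dim = NULL, pixel_size_um = 1, id = NULL) {
  if (is.matrix(pixels) && is.logical(pixels)) {
    dim <- base::dim(pixels)
    pixels <- which(pixels)
  }
  stopifnot(length(pixels) >= 1, !is.null(dim))
  pixels <- as.integer(sort(unique(pixels)))
  if (pixels[1] < 1L || pixels[length(pixels)] > prod(dim)) {
    stop("roi pixels outside image bounds")
  }
  row0 <- (pixels - 1L) %% dim[1]
  col0 <- (pixels - 1L) %/% dim[1]
  area <- length(pixels)
  structure(
    list(id = id, pixels = pixels, dim = as.integer(dim),
         centroid = c(x = mean(col0), y = mean(row0)),
         area_px = area,
         equivalent_diameter_um = 2 * sqrt(area / pi) * pixel_size_um),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi%s> %d px, centroid (%.1f, %.1f), eq. diameter %.2f um\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$area_px, x$centroid["x"], x$centroid["y"],
              x$equivalent_diameter_um))
  invisible(x)
}

#' Square window ROI around a 0-based centre
#'
#' Convenience constructor for the measurement windows used on rendered spots:
#' a (2r+1) x (2r+1) square clipped to the image.
#'
#' @param x0,y0 0-based centre (column, row).
#' @param radius_px Half-width in pixels.
#' @param dim Image dimension.
#' @param pixel_size_um Pixel size.
#' @param id Optional identifier.
#' @return An `roi`.
#' @export
roi_window <- function(x0, y0, radius_px, dim, pixel_size_um = 1, id = NULL) {
  rows <- max(1L, round(y0) + 1L - radius_px):min(dim[1], round(y0) + 1L + radius_px)
  cols <- max(1L, round(x0) + 1L - radius_px):min(dim[2], round(x0) + 1L + radius_px)
  idx <- as.integer(outer(rows, (cols - 1L) * dim[1], `+`))
  roi(idx, dim, pixel_size_um, id = id)
}

roi_disjoint <- function(a, b) length(intersect(a$pixels, b$pixels)) == 0L

#' Detect mitochondrion-scale particles in a 2-D image
#'
#' Thresholds the image, labels connected bright regions, and keeps those
#' whose equivalent diameter (diameter of the circle with the mask's area)
#' lies inside `d_range` inclusive — the operational definition of an
#' individual mitochondrion (0.5-3 um by default).
#'
#' @param image Numeric matrix with finite values.
#' @param pixel_size_um Pixel size, um/px (> 0).
#' @param d_range Inclusive equivalent-diameter gate in um.
#' @param threshold `"otsu"` for Otsu's method on the rescaled image (the
#'   parameter-free default), or a numeric absolute intensity threshold.
#' @return A list of [roi()] objects (possibly empty), each carrying its
#'   centroid and equivalent diameter.
#' @examples
#' img <- matrix(0, 64, 64); img[30:33, 30:33] <- 10
#' length(detect_particles(img, 0.325, threshold = 5))
#' @export
detect_particles <- function(image, pixel_size_um, d_range = c(0.5, 3.0),
                             threshold = "otsu") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix")
  }
  if (!all(is.finite(image))) stop("image must be finite-valued")
  stopifnot(pixel_size_um > 0, length(d_range) == 2, d_range[1] <= d_range[2])

  rng <- range(image)
  if (rng[1] == rng[2]) return(list())
  if (identical(threshold, "otsu")) {
    img01 <- (image - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
    binary <- img01 > th
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    binary <- image > threshold
  }
  if (!any(binary)) return(list())
  lab <- as.matrix(EBImage::bwlabel(binary * 1))
  n <- max(lab)
  out <- vector("list", n)
  kept <- 0L
  idx_by_label <- split(seq_along(lab), lab)
  idx_by_label[["0"]] <- NULL
  for (li in seq_along(idx_by_label)) {
    r <- roi(idx_by_label[[li]], dim(image), pixel_size_um,
             id = sprintf("roi%03d", li))
    if (r$equivalent_diameter_um >= d_range[1] &&
        r$equivalent_diameter_um <= d_range[2]) {
      kept <- kept + 1L
      out[[kept]] <- r
    }
  }
  out[seq_len(kept)]
}

#' Extract a background-subtracted integrated intensity trace
#'
#' For each frame of a stationary time-lapse, integrates intensity over the
#' ROI and subtracts the mean intensity of a particle-free blank region times
#' the ROI area. Positions are fixed across frames (the dish does not move
#' during acquisition), so the same pixel mask is used throughout.
#'
#' @param stack An [image_bundle()] time-lapse.
#' @param roi Particle [roi()].
#' @param blank Blank [roi()]; must be disjoint from `roi`.
#' @return An `intensity_trace`: list with `timepoints_min`, `values`,
#'   `roi_id`.
#' @export
extract_trace <- function(stack, roi, blank) {
  stopifnot(inherits(stack, "image_bundle"), inherits(roi, "roi"),
            inherits(blank, "roi"))
  if (!identical(roi$dim, as.integer(stack$dim))) {
    stop("roi outside image bounds: dimension mismatch")
  }
  if (!roi_disjoint(roi, blank)) stop("roi and blank regions must be disjoint")
  vals <- vapply(stack$frames, function(f) {
    sum(f[roi$pixels]) - mean(f[blank$pixels]) * roi$area_px
  }, numeric(1))
  tp <- stack$timepoints_min
  if (is.null(tp)) tp <- seq_along(vals)
  structure(list(timepoints_min = tp, values = vals, roi_id = roi$id),
            class = "intensity_trace")
}

#' Integrated per-cell fluorescence with in-cell background subtraction
#'
#' Integrates intensity over a cell mask and subtracts the per-pixel
#' background — estimated from a region inside the same cell lacking labelled
#' structures — times the mask area. Used identically for the GFP
#' (I_cell.GFP), TMRE (F_TMRE) and MitoSOX (F_MSR) channels. Negative
#' post-subtraction totals are clipped to zero and flagged.
#'
#' @param image Numeric matrix (one channel).
#' @param cell_mask [roi()] covering the cell.
#' @param internal_background_region [roi()] inside the cell, free of labelled
#'   structures; must be a subset of `cell_mask` (a background region larger
#'   than the cell is an error).
#' @param channel Channel label recorded in the result.
#' @param cell_id Optional identifier.
#' @return A `cell_fluorescence` record: `total` (integrated background-
#'   subtracted intensity, >= 0), `background_per_pixel`, `clipped`, `area_px`.
#' @export
measure_cell_fluorescence <- function(image, cell_mask,
                                      internal_background_region,
                                      channel = "GFP", cell_id = NULL) {
  stopifnot(is.matrix(image), inherits(cell_mask, "roi"),
            inherits(internal_background_region, "roi"))
  if (!all(internal_background_region$pixels %in% cell_mask$pixels)) {
    stop("background region must lie inside the cell mask")
  }
  bpp <- mean(image[internal_background_region$pixels])
  total <- sum(image[cell_mask$pixels]) - bpp * cell_mask$area_px
  clipped <- total < 0
  structure(
    list(cell_id = cell_id %||% cell_mask$id, channel = channel,
         total = max(total, 0), background_per_pixel = bpp,
         clipped = clipped, area_px = cell_mask$area_px),
    class = "cell_fluorescence"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Find a particle-free square blank window by scanning a coarse grid and
# picking the first window that avoids all detected footprints.
find_blank_window <- function(dim, occupied_pixels, radius_px = 6L,
                              pixel_size_um = 1) {
  step <- 2L * radius_px + 3L
  for (y0 in seq(radius_px + 1L, dim[1] - radius_px - 2L, by = step)) {
    for (x0 in seq(radius_px + 1L, dim[2] - radius_px - 2L, by = step)) {
      w <- roi_window(x0, y0, radius_px, dim, pixel_size_um, id = "blank")
      if (!length(intersect(w$pixels, occupied_pixels))) return(w)
    }
  }
  stop("no particle-free blank region found")
}
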