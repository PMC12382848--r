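#' Generate a two-channel GFP/TMRE uptake field with ground truth
#'
#' Renders a field of recipient cells containing a known number of implanted
#' GFP-labelled mitochondria each, plus isolated extracellular (free) GFP
#' particles in cell-free regions. Cells are convex polygons with uniform
#' autofluorescence. Implanted puncta share a unit reference integrated
#' intensity up to the stated dispersion; free particles carry the same
#' reference intensity, which is what makes the intensity-ratio counting
#' estimator unbiased. The TMRE channel renders polarized structures only:
#' internalized mitochondria are depolarized (no TMRE signal), while a chosen
#' fraction of the free particles is polarized.
#'
#' @param config A [sim_config()].
#' @param n_cells Number of cells.
#' @param per_cell_counts Integer vector (recycled to `n_cells`) of implanted
#'   puncta per cell.
#' @param n_free_particles Number of extracellular particles.
#' @param punctum_intensity Reference integrated GFP intensity of a single
#'   mitochondrion, arbitrary units.
#' @param intensity_cv Coefficient of variation of per-punctum intensities.
#' @param punctum_diameter_um Diameter of implanted puncta (um).
#' @param free_diameter_um Diameter (scalar or range) of free particles;
#'   defaults to the middle of `config$particle_diameter_um`. Values outside
#'   the 0.5-3 um gate are legitimate truth (they must be rejected downstream).
#' @param polarized_fraction_free Fraction of free particles that are
#'   polarized (carry TMRE signal).
#' @param tmre_intensity Integrated TMRE intensity of a polarized particle.
#' @param cell_background Uniform autofluorescence level inside cells (GFP
#'   channel, per pixel).
#' @param tmre_background Uniform TMRE background level (per pixel), > 0.
#' @param cell_radius_um Nominal cell radius (um).
#' @return A list with `gfp` and `tmre` ([image_bundle()]s of one frame each),
#'   `cell_labels` (integer matrix, 0 = outside any cell), and `manifest`
#'   whose objects table lists every punctum and free particle and whose
#'   `cells` table gives the implanted count per cell.
#' @export
gen_uptake_field <- function(config, n_cells, per_cell_counts,
                             n_free_particles = 50,
                             punctum_intensity = 500, intensity_cv = 0,
                             punctum_diameter_um = 1,
                             free_diameter_um = NULL,
                             polarized_fraction_free = 1,
                             tmre_intensity = 800,
                             cell_background = 40,
                             tmre_background = 5,
                             cell_radius_um = 12) {
  stopifnot(inherits(config, "sim_config"), n_cells >= 0,
            n_free_particles >= 0, tmre_background > 0,
            polarized_fraction_free >= 0, polarized_fraction_free <= 1)
  n_cells <- as.integer(n_cells)
  n_free <- as.integer(n_free_particles)
  if (n_cells > 0) {
    per_cell_counts <- as.integer(rep_len(per_cell_counts, n_cells))
    stopifnot(all(per_cell_counts >= 0))
  } else per_cell_counts <- integer(0)
  if (is.null(free_diameter_um)) {
    free_diameter_um <- mean(config$particle_diameter_um)
  }
  set.seed(config$seed)

  px <- config$pixel_size_um
  dim <- c(config$field_px, config$field_px)
  cell_r_px <- cell_radius_um / px
  fp_r <- spot_footprint_radius_px(punctum_diameter_um, px)

  # --- cells ---------------------------------------------------------------
  cell_centers <- place_centers(n_cells, dim, 2.3 * cell_r_px,
                                as.integer(ceiling(cell_r_px)) + 2L)
  cell_labels <- matrix(0L, dim[1], dim[2])
  cell_masks <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    poly <- random_cell_polygon(cell_centers$x[ci], cell_centers$y[ci], cell_r_px)
    m <- fill_convex_polygon(poly$x, poly$y, dim)
    cell_masks[[ci]] <- m
    cell_labels[m] <- ci
  }

  gfp <- matrix(0, dim[1], dim[2])
  gfp[cell_labels > 0L] <- cell_background
  tmre <- matrix(tmre_background, dim[1], dim[2])

  # --- implanted puncta ----------------------------------------------------
  objects <- list()
  kern_punct <- spot_kernel(punctum_diameter_um, px, 1)
  for (ci in seq_len(n_cells)) {
    k <- per_cell_counts[ci]
    if (k == 0L) next
    eroded <- EBImage::erode(cell_masks[[ci]] * 1,
                             EBImage::makeBrush(2L * (fp_r + 2L) + 1L, "disc"))
    cand <- which(as.matrix(eroded) > 0)
    if (length(cand) < k) stop("field too small to place objects without overlap")
    xs <- integer(0); ys <- integer(0); tries <- 0L
    while (length(xs) < k) {
      tries <- tries + 1L
      if (tries > 4000L * k) stop("field too small to place objects without overlap")
      idx <- cand[sample.int(length(cand), 1L)]
      y <- (idx - 1L) %% dim[1]
      x <- (idx - 1L) %/% dim[1]
      if (length(xs) == 0L ||
          all((xs - x)^2 + (ys - y)^2 >= (fp_r + 2)^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    amp <- punctum_intensity * pmax(0.05, 1 + intensity_cv * stats::rnorm(k))
    for (i in seq_len(k)) {
      gfp <- add_kernel(gfp, xs[i], ys[i], kern_punct * amp[i])
      objects[[length(objects) + 1L]] <- data.frame(
        object_id = sprintf("cell%02d_p%02d", ci, i), class = "mitochondrion",
        type = "implanted", cell_id = ci, x = xs[i], y = ys[i],
        diameter_um = punctum_diameter_um, intensity = amp[i],
        polarized = FALSE, stringsAsFactors = FALSE)
    }
  }

  # --- free extracellular particles ---------------------------------------
  d_free <- if (length(free_diameter_um) == 1L ||
                free_diameter_um[1] == free_diameter_um[2]) {
    rep(free_diameter_um[1], n_free)
  } else stats::runif(n_free, free_diameter_um[1], free_diameter_um[2])
  if (n_free > 0) {
    fr <- vapply(d_free, spot_footprint_radius_px, integer(1), pixel_size_um = px)
    free_zone <- cell_labels == 0L
    if (n_cells > 0) {
      # keep free particles far enough from cells that a square measurement
      # window (detected footprint + margin, corner reach sqrt(2) larger)
      # around any particle cannot touch cell autofluorescence
      margin <- as.integer(ceiling((max(fr) + 6L) * sqrt(2)) + 3L)
      dil <- EBImage::dilate((cell_labels > 0L) * 1,
                             EBImage::makeBrush(2L * margin + 1L, "disc"))
      free_zone <- !(as.matrix(dil) > 0)
    }
    marg <- max(fr) + 1L
    free_zone[c(seq_len(marg), dim[1] - seq_len(marg) + 1L), ] <- FALSE
    free_zone[, c(seq_len(marg), dim[2] - seq_len(marg) + 1L)] <- FALSE
    cand <- which(free_zone)
    if (length(cand) < n_free) stop("field too small to place objects without overlap")
    xs <- integer(0); ys <- integer(0); tries <- 0L
    while (length(xs) < n_free) {
      tries <- tries + 1L
      if (tries > 4000L * n_free) stop("field too small to place objects without overlap")
      idx <- cand[sample.int(length(cand), 1L)]
      y <- (idx - 1L) %% dim[1]
      x <- (idx - 1L) %/% dim[1]
      # separation wide enough that a square measurement window (detected
      # footprint + margin, corner reach sqrt(2) larger) around one particle
      # cannot touch a neighbour's rendered footprint
      if (length(xs) == 0L ||
          all((xs - x)^2 + (ys - y)^2 >= (2 * max(fr) + 14)^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    n_pol <- round(polarized_fraction_free * n_free)
    polarized <- sample(rep(c(TRUE, FALSE), c(n_pol, n_free - n_pol)))
    amp <- punctum_intensity * pmax(0.05, 1 + intensity_cv * stats::rnorm(n_free))
    for (i in seq_len(n_free)) {
      gfp <- add_kernel(gfp, xs[i], ys[i], spot_kernel(d_free[i], px, amp[i]))
      if (polarized[i]) {
        tmre <- add_kernel(tmre, xs[i], ys[i],
                           spot_kernel(d_free[i], px, tmre_intensity))
      }
      objects[[length(objects) + 1L]] <- data.frame(
        object_id = sprintf("free%03d", i), class = "mitochondrion",
        type = "free", cell_id = NA_integer_, x = xs[i], y = ys[i],
        diameter_um = d_free[i], intensity = amp[i],
        polarized = polarized[i], stringsAsFactors = FALSE)
    }
  }

  gfp <- add_noise(gfp, config$noise_sd)
  tmre <- add_noise(tmre, config$noise_sd)

  objects <- if (length(objects)) do.call(rbind, objects) else
    data.frame(object_id = character(), class = character(), type = character(),
               cell_id = integer(), x = integer(), y = integer(),
               diameter_um = numeric(), intensity = numeric(),
               polarized = logical(), stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = seq_len(n_cells),
                      x = cell_centers$x, y = cell_centers$y,
                      implanted_count = per_cell_counts)
  manifest <- new_manifest("uptake_field", objects, config,
                           extra = list(cells = cells,
                                        punctum_intensity = punctum_intensity,
                                        cell_background = cell_background,
                                        tmre_background = tmre_background))
  list(
    gfp = image_bundle(list(gfp), "GFP", pixel_size_um = px),
    tmre = image_bundle(list(tmre), "TMRE", pixel_size_um = px),
    cell_labels = cell_labels,
    manifest = manifest
  )
}
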