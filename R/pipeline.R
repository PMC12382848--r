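# Configuration-driven orchestration: each experiment kind reproduces one
# figure-style analysis end to end on synthetic inputs — generate, quantify,
# run statistics, and write images/tables/report/log with full provenance.

experiment_kinds <- c("mpt_fbs", "swelling", "polarization_timecourse",
                      "uptake", "plate_coadmin", "plate_postdamage")

#' Experiment configuration
#'
#' Bundles an experiment kind, its generator parameters, the analysis
#' thresholds (all defaulting to the reference values: 20% calcein drop per
#' 2-min interval, 0.16 transmittance change, 0.46 um^2 darkest region,
#' 0.5-3 um particle gate, alpha 0.05), a seed and an output directory.
#' Serializes losslessly to YAML or JSON.
#'
#' @param kind One of `"mpt_fbs"`, `"swelling"`, `"polarization_timecourse"`,
#'   `"uptake"`, `"plate_coadmin"`, `"plate_postdamage"`.
#' @param generator Named list of generator parameters; kind-specific
#'   defaults fill anything not supplied.
#' @param analysis Named list of analysis parameters; defaults above.
#' @param seed Integer seed driving all randomness of the run.
#' @param out_dir Output directory for [run_experiment()].
#' @return An `experiment_config`.
#' @export
experiment_config <- function(kind, generator = list(), analysis = list(),
                              seed = 1L, out_dir = NULL) {
  if (length(kind) != 1L || !kind %in% experiment_kinds) {
    stop("unknown experiment_kind: ", paste(kind, collapse = ", "),
         " (expected one of ", paste(experiment_kinds, collapse = ", "), ")")
  }
  if (!is.list(generator)) stop("config field 'generator' must be a list")
  if (!is.list(analysis)) stop("config field 'analysis' must be a list")
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))

  gen_defaults <- switch(kind,
    mpt_fbs = list(n_experiments = 3L, n_mito = 50L, event_fraction = 0.85,
                   drop_range = c(0.5, 0.8), diameter_um = 1.5,
                   amplitude = 1000, amplitude_cv = 0, noise_sd = 0,
                   field_px = 256L),
    swelling = list(n_experiments = 3L, n_mito = 50L, swell_fraction = 0.8,
                    baseline_range = c(0.5, 0.7), delta_range = c(0.18, 0.3),
                    onset_range_min = c(1, 8), timepoints_min = c(0, 5, 10),
                    diameter_um = 2, noise_sd = 0, field_px = 220L),
    polarization_timecourse = list(n_experiments = 3L, n_mito = 50L,
                                   times_h = c(0, 1, 2),
                                   polarized_fractions = c(0.9, 0.8, 0.24),
                                   substrate = "succinate",
                                   tmre_intensity = 800, noise_sd = 0,
                                   field_px = 320L),
    uptake = list(n_cells = 10L, per_cell_counts = 8L, n_free_particles = 50L,
                  punctum_intensity = 500, intensity_cv = 0, noise_sd = 0,
                  field_px = 512L, cell_radius_um = 15),
    plate_coadmin = list(n_wells = 6L, n_replicates = 3L, noise_sd = 0.04,
                         dh_means = c(H2O2 = 0.50, `H2O2+Imit` = 0.68,
                                      `H2O2+Hmit` = 0.62),
                         atp_means = c(H2O2 = 1200, `H2O2+Imit` = 1650,
                                       `H2O2+Hmit` = 1500),
                         h2o2_remaining_uM = c(H2O2 = 55, `H2O2+Imit` = 25,
                                               `H2O2+Hmit` = 25),
                         amplex_slope = 220, amplex_intercept = 150,
                         amplex_noise_sd = 0,
                         standards_uM = seq(0, 12, by = 2)),
    plate_postdamage = list(n_wells = 6L, n_replicates = 3L, noise_sd = 0.04,
                            dh_means = c(H2O2 = 0.50, `H2O2+Imit` = 0.75,
                                         `H2O2+Hmit` = 0.62),
                            atp_means = c(H2O2 = 1100, `H2O2+Imit` = 1600,
                                          `H2O2+Hmit` = 1350),
                            count_pre_mean = 120,
                            adherent_ratio_true = c(H2O2 = 0.9,
                                                    `H2O2+Imit` = 1.2,
                                                    `H2O2+Hmit` = 1.17))
  )
  ana_defaults <- list(mpt_threshold = 0.20, swelling_threshold = 0.16,
                       region_area_um2 = 0.46, d_range = c(0.5, 3),
                       polarization_ratio_threshold = 2, alpha = 0.05,
                       overlap_threshold = 0.5, detect_rel_threshold = 0.3)
  unknown <- setdiff(names(generator), names(gen_defaults))
  if (length(unknown)) stop("unknown generator field(s) for kind ", kind, ": ",
                            paste(unknown, collapse = ", "))
  unknown <- setdiff(names(analysis), names(ana_defaults))
  if (length(unknown)) stop("unknown analysis field(s): ",
                            paste(unknown, collapse = ", "))
  structure(
    list(kind = kind,
         generator = utils::modifyList(gen_defaults, generator),
         analysis = utils::modifyList(ana_defaults, analysis),
         seed = as.integer(seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> kind = %s, seed = %d\n", x$kind, x$seed))
  invisible(x)
}

#' Write / read an experiment configuration (YAML or JSON)
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`);
#' serialization is lossless, so read(write(config)) reproduces the
#' configuration exactly.
#'
#' @param config An [experiment_config()].
#' @param path Destination path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns the `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(x$kind)) stop("config is missing required field 'kind'")
  if (is.null(x$generator)) stop("config is missing required field 'generator'")
  gen <- lapply(x$generator, function(v) if (is.list(v)) unlist(v) else v)
  ana <- lapply(x$analysis %||% list(), function(v) if (is.list(v)) unlist(v) else v)
  experiment_config(x$kind, generator = gen, analysis = ana,
                    seed = x$seed %||% 1L, out_dir = x$out_dir)
}

derive_seed <- function(seed, i) as.integer((abs(seed) * 1009L + i) %% 2147483629L)

#' Run one configured experiment end to end
#'
#' Generates the synthetic inputs for the configured experiment kind, runs
#' the matching quantifiers and statistics, and writes every artefact into
#' `config$out_dir`: images as multi-page TIFF (microscopy kinds), tables as
#' CSV, the report and ground-truth manifest as JSON, and a timestamp-free
#' log of every parameter and seed. Rerunning the same configuration and
#' seed reproduces the output files byte for byte.
#'
#' @param config An [experiment_config()] with a non-`NULL` `out_dir`.
#' @return The report (a named list), invisibly; the same structure is
#'   written to `report.json`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir must be set")
  existed <- dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }

  report <- tryCatch(
    switch(config$kind,
      mpt_fbs = run_mpt_fbs(config, out, note),
      swelling = run_swelling(config, out, note),
      polarization_timecourse = run_polarization(config, out, note),
      uptake = run_uptake(config, out, note),
      plate_coadmin = run_plate(config, out, note),
      plate_postdamage = run_plate(config, out, note)
    ),
    error = function(e) {
      unlink(written)
      unlink(paste0(written, ".json"))
      if (!existed) unlink(out, recursive = TRUE)
      stop(e)
    }
  )
  report$kind <- config$kind
  report$seed <- config$seed
  jsonlite::write_json(report, note(file.path(out, "report.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log_lines <- c(
    sprintf("mitoquant run_experiment kind=%s seed=%d", config$kind, config$seed),
    "generator:",
    utils::capture.output(utils::str(config$generator, give.attr = FALSE)),
    "analysis:",
    utils::capture.output(utils::str(config$analysis, give.attr = FALSE)))
  writeLines(log_lines, note(file.path(out, "log.txt")))
  invisible(report)
}

# ---- calcein / MPT --------------------------------------------------------

# Build the per-object event specification for one simulated dish: the stated
# fraction of mitochondria undergoes an abrupt drop at a frame boundary after
# the serum addition at t = 5 min (frames at t >= 6 min).
mpt_event_spec <- function(n_mito, event_fraction, drop_range, config) {
  n_event <- round(event_fraction * n_mito)
  frames_min <- (seq_len(config$n_frames) - 1) * config$frame_interval_min
  eligible <- which(frames_min >= 6)
  ev <- rep(NA_integer_, n_mito)
  dr <- rep(NA_real_, n_mito)
  which_event <- sample(seq_len(n_mito), n_event)
  ev[which_event] <- sample(eligible, n_event, replace = TRUE)
  dr[which_event] <- stats::runif(n_event, drop_range[1], drop_range[2])
  data.frame(event_frame = ev, drop_fraction = dr)
}

#' Quantify one simulated field
#'
#' The per-field quantification stages used by [run_experiment()], exposed so
#' a field generated (or loaded) separately can be pushed through the same
#' analysis: particle detection, trace/series extraction, the decision rules,
#' and matching against the ground-truth manifest.
#'
#' @param sim,field Output of [gen_calcein_timelapse()] /
#'   [gen_transmittance_zstacks()] / [gen_uptake_field()] respectively.
#' @param analysis Analysis parameter list, e.g.
#'   `experiment_config(<kind>)$analysis`.
#' @return A list of per-field results: recovered and manifest-truth
#'   fractions plus per-object detail (see each kind's section of the
#'   methods vignette).
#' @name quantify_field
NULL

#' @rdname quantify_field
#' @export
quantify_mpt_field <- function(sim, analysis) {
  f1 <- sim$bundle$frames[[1]]
  px <- sim$bundle$pixel_size_um
  thr <- analysis$detect_rel_threshold * max(f1)
  rois <- detect_particles(f1, px, d_range = analysis$d_range, threshold = thr)
  if (!length(rois)) stop("no particles detected")
  occupied <- unlist(lapply(rois, function(r) {
    roi_window(r$centroid["x"], r$centroid["y"], 10L, r$dim, px)$pixels
  }))
  blank <- find_blank_window(dim(f1), occupied, radius_px = 6L, pixel_size_um = px)
  calls <- lapply(rois, function(r) {
    call_mpt(extract_trace(sim$bundle, r, blank),
             threshold = analysis$mpt_threshold)
  })
  truth <- manifest_objects(sim$manifest)
  matched_truth <- vapply(rois, function(r) {
    d2 <- (truth$x - r$centroid["x"])^2 + (truth$y - r$centroid["y"])^2
    i <- which.min(d2)
    if (d2[i] > 4) NA else !is.na(truth$mpt_event_frame[i]) &&
      truth$drop_fraction[i] > analysis$mpt_threshold
  }, logical(1))
  list(fraction = mpt_fraction(calls),
       truth_fraction = 100 * mean(matched_truth, na.rm = TRUE),
       n_detected = length(rois), calls = calls)
}

run_mpt_fbs <- function(config, out, note) {
  g <- config$generator
  per_exp <- lapply(seq_len(g$n_experiments), function(i) {
    cfg <- sim_config(seed = derive_seed(config$seed, i),
                      noise_sd = g$noise_sd, field_px = g$field_px)
    set.seed(derive_seed(config$seed, 1000L + i))
    spec <- mpt_event_spec(g$n_mito, g$event_fraction, g$drop_range, cfg)
    sim <- gen_calcein_timelapse(cfg, g$n_mito, spec,
                                 amplitude = g$amplitude,
                                 amplitude_cv = g$amplitude_cv,
                                 diameter_um = g$diameter_um)
    if (i == 1L) {
      write_bundle_tiff(sim$bundle, note(file.path(out, "calcein_exp1.tif")))
      write_manifest(sim$manifest, note(file.path(out, "manifest_exp1.json")))
    }
    quantify_mpt_field(sim, config$analysis)
  })
  frac <- vapply(per_exp, `[[`, numeric(1), "fraction")
  truth <- vapply(per_exp, `[[`, numeric(1), "truth_fraction")
  tab <- data.frame(experiment = seq_along(frac),
                    mpt_percent = frac, truth_percent = truth,
                    n_detected = vapply(per_exp, `[[`, integer(1), "n_detected"))
  utils::write.csv(tab, note(file.path(out, "mpt_per_experiment.csv")),
                   row.names = FALSE)
  list(mpt_percent_mean = mean(frac), mpt_percent_sem = sem(frac),
       truth_percent_mean = mean(truth), per_experiment = tab)
}

# ---- swelling -------------------------------------------------------------

swelling_spec <- function(n_mito, g) {
  n_sw <- round(g$swell_fraction * n_mito)
  swollen <- sample(rep(c(TRUE, FALSE), c(n_sw, n_mito - n_sw)))
  baseline <- stats::runif(n_mito, g$baseline_range[1], g$baseline_range[2])
  delta <- stats::runif(n_mito, g$delta_range[1], g$delta_range[2])
  post <- pmin(1, ifelse(swollen, baseline + delta, baseline))
  onset <- ifelse(swollen,
                  stats::runif(n_mito, g$onset_range_min[1], g$onset_range_min[2]),
                  NA_real_)
  data.frame(baseline = baseline, post = post, onset_min = onset)
}

#' @rdname quantify_field
#' @export
quantify_swelling_field <- function(sim, analysis) {
  stack0 <- sim$stacks[[1]]
  px <- stack0$pixel_size_um
  minproj <- Reduce(pmin, stack0$frames)
  inverted <- max(minproj) - minproj
  rois <- detect_particles(inverted, px, d_range = analysis$d_range,
                           threshold = "otsu")
  if (!length(rois)) stop("no particles detected")
  occupied <- unlist(lapply(rois, function(r) {
    roi_window(r$centroid["x"], r$centroid["y"], 12L, r$dim, px)$pixels
  }))
  blank <- find_blank_window(dim(minproj), occupied, radius_px = 6L,
                             pixel_size_um = px)
  series <- lapply(rois, function(r) {
    call_swelling(
      transmittance_series(sim$stacks, r, blank, sim$timepoints_min,
                           region_area_um2 = analysis$region_area_um2),
      threshold = analysis$swelling_threshold)
  })
  truth <- manifest_objects(sim$manifest)
  t_max <- max(sim$timepoints_min)
  t_min <- min(sim$timepoints_min)
  matched_truth <- vapply(rois, function(r) {
    d2 <- (truth$x - r$centroid["x"])^2 + (truth$y - r$centroid["y"])^2
    i <- which.min(d2)
    if (d2[i] > 9) NA else {
      !is.na(truth$swelling_onset_min[i]) &&
        truth$swelling_onset_min[i] > t_min &&
        truth$swelling_onset_min[i] <= t_max &&
        abs(truth$transmittance_post[i] - truth$transmittance_baseline[i]) >
          analysis$swelling_threshold
    }
  }, logical(1))
  list(fraction = 100 * mean(vapply(series, `[[`, logical(1), "swollen")),
       truth_fraction = 100 * mean(matched_truth, na.rm = TRUE),
       n_detected = length(rois))
}

run_swelling <- function(config, out, note) {
  g <- config$generator
  per_exp <- lapply(seq_len(g$n_experiments), function(i) {
    cfg <- sim_config(seed = derive_seed(config$seed, i),
                      noise_sd = g$noise_sd, field_px = g$field_px)
    set.seed(derive_seed(config$seed, 2000L + i))
    spec <- swelling_spec(g$n_mito, g)
    sim <- gen_transmittance_zstacks(cfg, g$n_mito, spec,
                                     timepoints_min = g$timepoints_min,
                                     diameter_um = g$diameter_um)
    if (i == 1L) {
      write_bundle_tiff(sim$stacks[[1]], note(file.path(out, "zstack_t0_exp1.tif")))
      write_manifest(sim$manifest, note(file.path(out, "manifest_exp1.json")))
    }
    quantify_swelling_field(sim, config$analysis)
  })
  frac <- vapply(per_exp, `[[`, numeric(1), "fraction")
  truth <- vapply(per_exp, `[[`, numeric(1), "truth_fraction")
  tab <- data.frame(experiment = seq_along(frac),
                    swollen_percent = frac, truth_percent = truth,
                    n_detected = vapply(per_exp, `[[`, integer(1), "n_detected"))
  utils::write.csv(tab, note(file.path(out, "swelling_per_experiment.csv")),
                   row.names = FALSE)
  list(swollen_percent_mean = mean(frac), swollen_percent_sem = sem(frac),
       truth_percent_mean = mean(truth), per_experiment = tab)
}

# ---- polarization time course --------------------------------------------

#' @rdname quantify_field
#' @export
quantify_polarization_field <- function(field, analysis) {
  gfp <- field$gfp$frames[[1]]
  tmre <- field$tmre$frames[[1]]
  px <- field$gfp$pixel_size_um
  rois <- detect_particles(gfp, px, d_range = analysis$d_range,
                           threshold = analysis$detect_rel_threshold * max(gfp))
  if (!length(rois)) stop("no particles detected")
  occupied <- unlist(lapply(rois, function(r) {
    roi_window(r$centroid["x"], r$centroid["y"], 10L, r$dim, px)$pixels
  }))
  bg <- mean(tmre[setdiff(seq_along(tmre), occupied)])
  calls <- lapply(rois, function(r) {
    classify_polarization(sum(tmre[r$pixels]), bg, r$area_px,
                          ratio_threshold = analysis$polarization_ratio_threshold)
  })
  truth <- manifest_objects(field$manifest)
  matched_truth <- vapply(rois, function(r) {
    d2 <- (truth$x - r$centroid["x"])^2 + (truth$y - r$centroid["y"])^2
    i <- which.min(d2)
    if (d2[i] > 4) NA else truth$polarized[i]
  }, logical(1))
  list(fraction = 100 * mean(vapply(calls, `[[`, logical(1), "polarized")),
       truth_fraction = 100 * mean(matched_truth, na.rm = TRUE),
       n_detected = length(rois))
}

run_polarization <- function(config, out, note) {
  g <- config$generator
  stopifnot(length(g$polarized_fractions) == length(g$times_h))
  rows <- list()
  for (ti in seq_along(g$times_h)) {
    per_exp <- lapply(seq_len(g$n_experiments), function(i) {
      cfg <- sim_config(seed = derive_seed(config$seed, 100L * ti + i),
                        noise_sd = g$noise_sd, field_px = g$field_px)
      field <- gen_uptake_field(cfg, n_cells = 0L, per_cell_counts = integer(0),
                                n_free_particles = g$n_mito,
                                polarized_fraction_free = g$polarized_fractions[ti],
                                tmre_intensity = g$tmre_intensity)
      quantify_polarization_field(field, config$analysis)
    })
    frac <- vapply(per_exp, `[[`, numeric(1), "fraction")
    truth <- vapply(per_exp, `[[`, numeric(1), "truth_fraction")
    rows[[ti]] <- data.frame(time_h = g$times_h[ti], substrate = g$substrate,
                             polarized_percent_mean = mean(frac),
                             polarized_percent_sem = sem(frac),
                             truth_percent_mean = mean(truth))
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, note(file.path(out, "polarization_timecourse.csv")),
                   row.names = FALSE)
  list(timecourse = tab)
}

# ---- uptake ---------------------------------------------------------------

measure_free_particle <- function(img, r, bg_per_px, window_radius_px) {
  w <- roi_window(r$centroid["x"], r$centroid["y"], window_radius_px,
                  r$dim, 1)
  sum(img[w$pixels]) - bg_per_px * w$area_px
}

#' @rdname quantify_field
#' @export
quantify_uptake_field <- function(field, analysis) {
  gfp <- field$gfp$frames[[1]]
  px <- field$gfp$pixel_size_um
  labels <- field$cell_labels
  dimg <- dim(gfp)

  # calibration from free extracellular particles
  free_img <- gfp
  free_img[labels > 0L] <- 0
  rois <- detect_particles(free_img, px, d_range = analysis$d_range,
                           threshold = analysis$detect_rel_threshold * max(free_img))
  if (!length(rois)) stop("no extracellular particles detected")
  occupied <- unlist(lapply(rois, function(r) {
    roi_window(r$centroid["x"], r$centroid["y"], 12L, r$dim, px)$pixels
  }))
  # background from the whole unoccupied extracellular area: the estimate is
  # multiplied by the measurement-window area, so it must come from far more
  # pixels than one small blank window
  avail <- setdiff(which(labels == 0L), occupied)
  if (!length(avail)) stop("no particle-free blank region found")
  bg_free <- mean(gfp[avail])
  win_r <- max(vapply(rois, function(r) {
    spot_footprint_radius_px(r$equivalent_diameter_um, px)
  }, integer(1))) + 2L
  intensities <- vapply(rois, measure_free_particle, numeric(1),
                        img = gfp, bg_per_px = bg_free,
                        window_radius_px = win_r)
  calibration <- calibrate_single_mito_intensity(intensities[intensities > 0])

  # per-cell counting
  cells <- field$manifest$cells
  per_cell <- lapply(seq_len(nrow(cells)), function(ci) {
    mask_idx <- which(labels == cells$cell_id[ci])
    cell_roi <- roi(mask_idx, dimg, px, id = sprintf("cell%02d", ci))
    vals <- gfp[mask_idx]
    thr <- stats::median(vals) + 0.5 * (max(vals) - stats::median(vals))
    bright <- mask_idx[vals > thr]
    if (length(bright)) {
      bin <- matrix(FALSE, dimg[1], dimg[2]); bin[bright] <- TRUE
      fp <- spot_footprint_radius_px(1, px)
      dil <- as.matrix(EBImage::dilate(bin * 1,
               EBImage::makeBrush(2L * (fp + 1L) + 1L, "disc"))) > 0
      bg_idx <- setdiff(mask_idx, which(dil))
    } else bg_idx <- mask_idx
    if (length(bg_idx) < 10) stop("no structure-free background region in cell")
    rec <- measure_cell_fluorescence(gfp, cell_roi,
                                     roi(bg_idx, dimg, px), channel = "GFP",
                                     cell_id = cells$cell_id[ci])
    count_internalized(rec, calibration)
  })
  est <- vapply(per_cell, `[[`, numeric(1), "estimated_count")

  # colocalization of intracellular GFP puncta with TMRE
  tmre <- field$tmre$frames[[1]]
  cell_img <- gfp
  cell_img[labels == 0L] <- 0
  gfp_puncta <- detect_particles(cell_img, px, d_range = analysis$d_range,
                                 threshold = stats::median(gfp[labels > 0L]) +
                                   0.5 * (max(cell_img) - stats::median(gfp[labels > 0L])))
  tmre_bg <- stats::median(tmre)
  tmre_rois <- detect_particles(tmre, px, d_range = c(0, Inf),
                                threshold = tmre_bg + 0.3 * (max(tmre) - tmre_bg))
  coloc <- if (length(gfp_puncta)) {
    colocalize_polarized(gfp_puncta, tmre_rois,
                         overlap_threshold = analysis$overlap_threshold)
  } else NA_real_

  list(calibration = calibration,
       per_cell = data.frame(cell_id = cells$cell_id,
                             true_count = cells$implanted_count,
                             estimated_count = est),
       colocalized_polarized_fraction = coloc)
}

run_uptake <- function(config, out, note) {
  g <- config$generator
  cfg <- sim_config(seed = derive_seed(config$seed, 1L),
                    noise_sd = g$noise_sd, field_px = g$field_px)
  field <- gen_uptake_field(cfg, n_cells = g$n_cells,
                            per_cell_counts = g$per_cell_counts,
                            n_free_particles = g$n_free_particles,
                            punctum_intensity = g$punctum_intensity,
                            intensity_cv = g$intensity_cv,
                            cell_radius_um = g$cell_radius_um)
  write_bundle_tiff(field$gfp, note(file.path(out, "uptake_gfp.tif")))
  write_bundle_tiff(field$tmre, note(file.path(out, "uptake_tmre.tif")))
  write_manifest(field$manifest, note(file.path(out, "manifest.json")))
  q <- quantify_uptake_field(field, config$analysis)
  utils::write.csv(q$per_cell, note(file.path(out, "uptake_per_cell.csv")),
                   row.names = FALSE)
  list(I_mit_GFP = q$calibration$I_mit_GFP,
       calibration_n = q$calibration$n_particles,
       mean_count = mean(q$per_cell$estimated_count),
       true_mean_count = mean(q$per_cell$true_count),
       colocalized_polarized_fraction = q$colocalized_polarized_fraction,
       per_cell = q$per_cell)
}

# ---- plate kinds ----------------------------------------------------------

run_plate <- function(config, out, note) {
  g <- config$generator
  conds <- names(g$dh_means)
  design <- data.frame(condition = conds, n_wells = g$n_wells)
  truth <- rbind(
    data.frame(condition = conds, assay = "DH", true_mean = unname(g$dh_means),
               noise_sd = g$noise_sd * unname(g$dh_means) / mean(g$dh_means)),
    data.frame(condition = conds, assay = "ATP", true_mean = unname(g$atp_means),
               noise_sd = g$noise_sd * unname(g$atp_means)))
  sim <- gen_plate_readouts(design, truth, n_replicates = g$n_replicates,
                            seed = derive_seed(config$seed, 1L))
  wells <- sim$wells
  utils::write.csv(wells, note(file.path(out, "wells.csv")), row.names = FALSE)

  report <- list()
  for (a in c("DH", "ATP")) {
    w <- wells[wells$assay == a, c("well", "condition", "value")]
    s <- summarize_conditions(w, conds, control_condition = conds[1],
                              reference_condition = if (length(conds) >= 3) conds[3])
    write_condition_summary(s,
      path_csv = note(file.path(out, sprintf("summary_%s.csv", a))))
    report[[paste0("summary_", a)]] <- s$table
    report[[paste0("anova_p_", a)]] <- s$anova$p
  }

  if (config$kind == "plate_coadmin") {
    # Amplex Red H2O2 readout: dose arithmetic, calibration, inversion.
    dose <- dose_mix(c(10, 100, 10), c(720, 0, 0))
    protein <- dose_mix(c(10), c(160))     # uL x ug/mL -> ug per 1000 uL
    set.seed(derive_seed(config$seed, 9L))
    standards <- data.frame(
      concentration = g$standards_uM,
      signal = g$amplex_slope * g$standards_uM + g$amplex_intercept +
        if (g$amplex_noise_sd > 0)
          stats::rnorm(length(g$standards_uM), sd = g$amplex_noise_sd) else 0)
    curve <- fit_calibration(standards)
    diluted <- unname(g$h2o2_remaining_uM) / 5
    sig <- curve$slope * diluted + curve$intercept
    recovered <- as.numeric(invert_calibration(curve, sig, dilution_factor = 5))
    amplex <- data.frame(condition = names(g$h2o2_remaining_uM),
                         true_uM = unname(g$h2o2_remaining_uM),
                         recovered_uM = recovered)
    utils::write.csv(amplex, note(file.path(out, "h2o2_remaining.csv")),
                     row.names = FALSE)
    report$dose <- list(
      h2o2_start_uM = dose$final_concentration,
      final_volume_uL = dose$final_volume,
      mito_protein_ug_per_well = protein$total_amount / 1000)
    report$amplex <- amplex
    report$calibration_r_squared <- curve$r_squared
  }

  if (config$kind == "plate_postdamage") {
    set.seed(derive_seed(config$seed, 9L))
    cnt_truth <- rbind(
      data.frame(condition = conds, assay = "count_pre",
                 true_mean = g$count_pre_mean, noise_sd = sqrt(g$count_pre_mean)),
      data.frame(condition = conds, assay = "count_post",
                 true_mean = g$count_pre_mean * unname(g$adherent_ratio_true),
                 noise_sd = sqrt(g$count_pre_mean * unname(g$adherent_ratio_true))))
    cnt <- gen_plate_readouts(design, cnt_truth, n_replicates = g$n_replicates,
                              seed = derive_seed(config$seed, 17L))$wells
    pre <- cnt[cnt$assay == "count_pre", ]
    post <- cnt[cnt$assay == "count_post", ]
    ratio <- data.frame(well = pre$well, condition = pre$condition,
                        value = adherent_ratio(pre$value, post$value))
    s <- summarize_conditions(ratio, conds, control_condition = conds[1],
                              reference_condition = if (length(conds) >= 3) conds[3])
    write_condition_summary(s, path_csv = note(file.path(out, "summary_adherent.csv")))
    report$summary_adherent <- s$table
  }
  report
}
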