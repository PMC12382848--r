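test_that("generators are deterministic for identical config and seed", {
  cfg <- sim_config(seed = 17, field_px = 96)
  a <- gen_calcein_timelapse(cfg, 4, diameter_um = 1.5)
  b <- gen_calcein_timelapse(cfg, 4, diameter_um = 1.5)
  expect_identical(a$bundle$frames, b$bundle$frames)
  expect_identical(a$manifest$objects, b$manifest$objects)

  za <- gen_transmittance_zstacks(cfg, 2, timepoints_min = c(0, 5))
  zb <- gen_transmittance_zstacks(cfg, 2, timepoints_min = c(0, 5))
  expect_identical(za$stacks[[2]]$frames, zb$stacks[[2]]$frames)

  pa <- gen_plate_readouts(data.frame(condition = "a", n_wells = 4),
                           data.frame(condition = "a", assay = "DH",
                                      true_mean = 1, noise_sd = 0.1),
                           seed = 5)
  pb <- gen_plate_readouts(data.frame(condition = "a", n_wells = 4),
                           data.frame(condition = "a", assay = "DH",
                                      true_mean = 1, noise_sd = 0.1),
                           seed = 5)
  expect_identical(pa$wells, pb$wells)
})

test_that("empty fields give blank output and empty manifests", {
  cfg <- sim_config(seed = 1, field_px = 64)
  sim <- gen_calcein_timelapse(cfg, 0)
  expect_equal(nrow(manifest_objects(sim$manifest)), 0)
  expect_true(all(vapply(sim$bundle$frames, function(f) all(f == 0), logical(1))))

  z <- gen_transmittance_zstacks(cfg, 0, timepoints_min = 0)
  expect_true(all(abs(z$stacks[[1]]$frames[[1]] - 1) < 1e-12))
})

test_that("calcein events drop integrated intensity by the specified fraction", {
  sim <- small_calcein_sim(seed = 9, n_mito = 5, n_event = 4, drop = 0.6)
  det <- detect_with_blank(sim$bundle)
  expect_length(det$rois, 5)
  truth <- manifest_objects(sim$manifest)
  for (r in det$rois) {
    tr <- extract_trace(sim$bundle, r, det$blank)
    i <- which.min((truth$x - r$centroid["x"])^2 + (truth$y - r$centroid["y"])^2)
    if (is.na(truth$mpt_event_frame[i])) {
      expect_equal(diff(range(tr$values)), 0, tolerance = 1e-9)
    } else {
      post <- tr$values[truth$mpt_event_frame[i]]
      expect_equal(post / tr$values[1], 1 - truth$drop_fraction[i],
                   tolerance = 1e-9)
    }
  }
  calls <- lapply(det$rois, function(r) call_mpt(extract_trace(sim$bundle, r, det$blank)))
  expect_equal(mpt_fraction(calls), 80)
})

test_that("calcein generator rejects invalid event specs and overlapping centers", {
  cfg <- sim_config(seed = 1, field_px = 96)
  expect_error(gen_calcein_timelapse(cfg, 1,
    data.frame(event_frame = 99L, drop_fraction = 0.5)), "2..n_frames")
  expect_error(gen_calcein_timelapse(cfg, 1,
    data.frame(event_frame = 5L, drop_fraction = 1.4)), "drop_fraction")
  expect_error(gen_calcein_timelapse(cfg, 2, diameter_um = 2,
    centers = data.frame(x = c(40, 42), y = c(40, 40))), "closer than one diameter")
})

test_that("slow-decline traces are a negative control for the per-interval rule", {
  cfg <- sim_config(seed = 21, field_px = 96)
  sim <- gen_calcein_timelapse(cfg, 1,
    data.frame(event_frame = 2L, drop_fraction = 0.5),
    diameter_um = 1.5, event_shape = "ramp")
  det <- detect_with_blank(sim$bundle)
  tr <- extract_trace(sim$bundle, det$rois[[1]], det$blank)
  expect_lt(tr$values[11] / tr$values[1], 0.55)   # 50% total loss happened
  expect_false(call_mpt(tr)$underwent_mpt)        # but gradually
})

test_that("transmittance forward model is exactly invertible at zero noise", {
  cfg <- sim_config(seed = 8, field_px = 128)
  spec <- data.frame(baseline = c(0.6, 0.75), post = c(0.8, 0.75),
                     onset_min = c(4, NA))
  sim <- gen_transmittance_zstacks(cfg, 2, spec, timepoints_min = c(0, 5, 10))
  truth <- manifest_objects(sim$manifest)
  px <- sim$stacks[[1]]$pixel_size_um
  for (i in 1:2) {
    r <- roi_window(truth$x[i], truth$y[i],
                    floor(truth$diameter_um[i] / 2 / px), c(128, 128), px)
    blank <- roi_window(10, 10, 5, c(128, 128), px)
    s <- transmittance_series(sim$stacks, r, blank, sim$timepoints_min)
    expected <- ifelse(!is.na(truth$swelling_onset_min[i]) &
                         sim$timepoints_min >= truth$swelling_onset_min[i],
                       truth$transmittance_post[i],
                       truth$transmittance_baseline[i])
    expect_equal(s$transmittance, expected, tolerance = 1e-9)
  }
})

test_that("transmittance above 1 is rejected", {
  cfg <- sim_config(seed = 1, field_px = 64)
  expect_error(gen_transmittance_zstacks(cfg, 1,
    data.frame(baseline = 0.9, post = 1.2, onset_min = 2)), "transmittance > 1")
})

test_that("uptake field renders requested counts and the gate-able diameters", {
  cfg <- sim_config(seed = 13, field_px = 320)
  field <- gen_uptake_field(cfg, n_cells = 2, per_cell_counts = c(0, 4),
                            n_free_particles = 6, cell_radius_um = 12)
  truth <- manifest_objects(field$manifest)
  expect_equal(sum(truth$type == "implanted" & truth$cell_id == 2), 4)
  expect_equal(sum(truth$type == "free"), 6)
  # free particles outside the 0.5-3 um gate are rejected downstream
  f2 <- gen_uptake_field(sim_config(seed = 13, field_px = 320), n_cells = 0,
                         per_cell_counts = integer(0), n_free_particles = 8,
                         free_diameter_um = 0.3)
  rois <- detect_particles(f2$gfp$frames[[1]], cfg$pixel_size_um,
                           d_range = c(0.5, 3), threshold = "otsu")
  expect_length(rois, 0)
})

test_that("plate generator recovers stated group structure at zero noise", {
  design <- data.frame(condition = c("ctl", "trt"), n_wells = 3)
  truth <- data.frame(condition = c("ctl", "trt"), assay = "DH",
                      true_mean = c(0.5, 0.6), noise_sd = 0)
  wells <- gen_plate_readouts(design, truth, seed = 2)$wells
  norm <- normalize_to_control(wells, "ctl")
  expect_equal(mean(norm$value[norm$condition == "ctl"]), 100)
  expect_equal(unique(norm$value[norm$condition == "trt"]), 120)
  expect_error(gen_plate_readouts(design,
    data.frame(condition = "zz", assay = "DH", true_mean = 1, noise_sd = 0)),
    "unknown condition")
})

test_that("recovery error of measured transmittance is non-decreasing in noise", {
  mae <- vapply(c(0, 0.02, 0.1), function(ns) {
    cfg <- sim_config(seed = 31, noise_sd = ns, field_px = 200)
    spec <- data.frame(baseline = runif(12, 0.5, 0.7), post = runif(12, 0.5, 0.7),
                       onset_min = NA_real_)
    sim <- gen_transmittance_zstacks(cfg, 12, spec, timepoints_min = 0)
    truth <- manifest_objects(sim$manifest)
    px <- sim$stacks[[1]]$pixel_size_um
    err <- vapply(seq_len(nrow(truth)), function(i) {
      r <- roi_window(truth$x[i], truth$y[i],
                      floor(truth$diameter_um[i] / 2 / px), c(200, 200), px)
      blank <- roi_window(8, 8, 5, c(200, 200), px)
      abs(compute_transmittance(sim$stacks[[1]], r, blank) -
            truth$transmittance_baseline[i])
    }, numeric(1))
    mean(err)
  }, numeric(1))
  expect_true(all(diff(mae) >= -1e-12))
})
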