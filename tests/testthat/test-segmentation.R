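test_that("blank and invalid images are handled", {
  expect_length(detect_particles(matrix(0, 32, 32), 0.325), 0)
  expect_length(detect_particles(matrix(5, 32, 32), 0.325), 0)  # constant
  expect_error(detect_particles(array(0, c(4, 4, 2)), 0.325), "2-D")
  expect_error(detect_particles(matrix(c(1, NA, 1, 1), 2, 2), 0.325), "finite")
})

test_that("rendered spots are detected with sub-pixel-accurate centroids", {
  cfg <- sim_config(seed = 41, field_px = 160, noise_sd = 2)  # peak ~40, SNR 20
  sim <- gen_calcein_timelapse(cfg, 5, diameter_um = 1.5)
  truth <- manifest_objects(sim$manifest)
  f1 <- sim$bundle$frames[[1]]
  rois <- detect_particles(f1, cfg$pixel_size_um, threshold = 0.4 * max(f1))
  expect_length(rois, 5)
  for (r in rois) {
    d <- sqrt(min((truth$x - r$centroid["x"])^2 + (truth$y - r$centroid["y"])^2))
    expect_lt(d, 1)
  }
})

test_that("equivalent-diameter gate rejects out-of-range particles inclusively", {
  cfg <- sim_config(seed = 5, field_px = 200)
  px <- cfg$pixel_size_um
  # one spot below and one far above the gate, thresholded at half peak so the
  # mask diameter tracks the FWHM (= rendered diameter)
  img <- matrix(0, 200, 200)
  k1 <- mitoquant:::spot_kernel(0.3, px, 1); k1 <- k1 / max(k1)
  k2 <- mitoquant:::spot_kernel(5, px, 1);   k2 <- k2 / max(k2)
  img <- mitoquant:::add_kernel(img, 40, 40, k1)
  img <- mitoquant:::add_kernel(img, 130, 130, k2)
  expect_length(detect_particles(img, px, d_range = c(0.5, 3), threshold = 0.5), 0)
  # an in-range spot passes at the same threshold
  img2 <- mitoquant:::add_kernel(matrix(0, 200, 200), 100, 100, {
    k <- mitoquant:::spot_kernel(1.5, px, 1); k / max(k)
  })
  expect_length(detect_particles(img2, px, d_range = c(0.5, 3), threshold = 0.5), 1)
})

test_that("detected diameter calibrates to truth within one pixel-equivalent", {
  px <- 0.1625   # transmitted-light pixel scale resolves the small end
  for (d in c(0.8, 1.5, 2.2, 3.0)) {
    k <- mitoquant:::spot_kernel(d, px, 1); k <- k / max(k)
    img <- mitoquant:::add_kernel(matrix(0, 128, 128), 64, 64, k)
    rois <- detect_particles(img, px, d_range = c(0.1, 10), threshold = 0.5)
    expect_length(rois, 1)
    expect_lt(abs(rois[[1]]$equivalent_diameter_um - d), px * 2)
  }
})

test_that("traces are constant on constant stacks and zero on background", {
  frames <- replicate(4, matrix(7, 48, 48), simplify = FALSE)
  b <- image_bundle(frames, "calcein", timepoints_min = c(0, 2, 4, 6),
                    pixel_size_um = 0.325)
  r <- roi_window(10, 10, 3, c(48, 48), 0.325)
  blank <- roi_window(36, 36, 3, c(48, 48), 0.325)
  tr <- extract_trace(b, r, blank)
  expect_equal(tr$values, rep(0, 4))  # uniform field: background-subtracted

  sim <- small_calcein_sim(seed = 2, n_mito = 1, n_event = 0)
  det <- detect_with_blank(sim$bundle)
  far <- roi_window(20, 130, 3, dim(sim$bundle$frames[[1]]), 0.325)
  tr2 <- extract_trace(sim$bundle, far, det$blank)
  expect_equal(max(abs(tr2$values)), 0, tolerance = 1e-9)
})

test_that("trace extraction validates geometry", {
  sim <- small_calcein_sim(seed = 2, n_mito = 1, n_event = 0)
  det <- detect_with_blank(sim$bundle)
  expect_error(extract_trace(sim$bundle, det$rois[[1]], det$rois[[1]]),
               "disjoint")
  small <- roi_window(5, 5, 2, c(8, 8), 0.325)
  expect_error(extract_trace(sim$bundle, small, det$blank), "bounds")
})

test_that("integrated intensity is additive over disjoint ROIs", {
  sim <- small_calcein_sim(seed = 12, n_mito = 3, n_event = 0)
  det <- detect_with_blank(sim$bundle)
  parts <- vapply(det$rois, function(r) {
    extract_trace(sim$bundle, r, det$blank)$values[1]
  }, numeric(1))
  union_roi <- roi(unlist(lapply(det$rois, function(r) r$pixels)),
                   det$rois[[1]]$dim, 0.325)
  whole <- extract_trace(sim$bundle, union_roi, det$blank)$values[1]
  expect_equal(whole, sum(parts), tolerance = 1e-9)
})

test_that("background-subtracted outputs are invariant to a constant offset", {
  sim <- small_calcein_sim(seed = 14, n_mito = 2, n_event = 1)
  det <- detect_with_blank(sim$bundle)
  shifted <- sim$bundle
  shifted$frames <- lapply(shifted$frames, function(f) f + 123.4)
  for (r in det$rois) {
    t0 <- extract_trace(sim$bundle, r, det$blank)$values
    t1 <- extract_trace(shifted, r, det$blank)$values
    expect_equal(t0, t1, tolerance = 1e-8)
  }
})

test_that("per-cell fluorescence subtracts in-cell background exactly", {
  dim <- c(96, 96)
  cell_px <- which(matrix(seq_len(96), 96, 96) %in% 20:70 &
                     matrix(seq_len(96), 96, 96, byrow = TRUE) %in% 20:70)
  img <- matrix(0, 96, 96)
  img[cell_px] <- 40
  cell <- roi(cell_px, dim, 0.325, id = "cell")
  bg <- roi_window(25, 25, 3, dim, 0.325)
  expect_equal(measure_cell_fluorescence(img, cell, bg)$total, 0)

  # four unit-intensity puncta -> integrated total of exactly 4
  for (pos in list(c(40, 40), c(55, 40), c(40, 55), c(55, 55))) {
    img <- mitoquant:::add_kernel(img, pos[1], pos[2],
                                  mitoquant:::spot_kernel(1, 0.325, 1))
  }
  rec <- measure_cell_fluorescence(img, cell, bg)
  expect_equal(rec$total, 4, tolerance = 1e-9)
  expect_false(rec$clipped)

  # negative totals clip to zero and flag
  img2 <- matrix(10, 96, 96); img2[bg$pixels] <- 50
  rec2 <- measure_cell_fluorescence(img2, cell, bg)
  expect_equal(rec2$total, 0)
  expect_true(rec2$clipped)

  outside <- roi_window(5, 5, 2, dim, 0.325)
  expect_error(measure_cell_fluorescence(img, cell, outside), "inside the cell")
})
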