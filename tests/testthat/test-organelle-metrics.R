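test_that("MPT caller applies the per-interval 20% rule", {
  expect_false(call_mpt(rep(100, 11))$underwent_mpt)

  tr <- c(100, 100, 75, 74, 74, 74, 74, 74, 74, 74, 74)
  call <- call_mpt(tr)
  expect_true(call$underwent_mpt)
  expect_equal(call$event_interval, c(2L, 3L))  # drop 25 > 20% of 100

  # linear 30% total decline never drops >20% in one interval
  expect_false(call_mpt(seq(100, 70, by = -3))$underwent_mpt)

  # boundary: a drop of exactly 20% does not qualify ("more than 20%")
  expect_false(call_mpt(c(100, 80, 80))$underwent_mpt)
  expect_true(call_mpt(c(100, 79.9, 79.9))$underwent_mpt)
})

test_that("the current-value reading is available as a switch", {
  # 100 -> 90 -> 71: second drop is 19 (<20 of initial) but >20% of 90
  tr <- c(100, 90, 71)
  expect_false(call_mpt(tr, relative_to = "initial")$underwent_mpt)
  expect_true(call_mpt(tr, relative_to = "current")$underwent_mpt)
})

test_that("MPT caller validates its inputs", {
  expect_error(call_mpt(c(100)), "at least 2")
  expect_error(call_mpt(c(0, 50)), "positive")
  expect_error(call_mpt(c(-5, 50)), "positive")
})

test_that("MPT call is invariant to intensity rescaling", {
  set.seed(77)
  for (i in 1:50) {
    v <- random_trace()
    base <- call_mpt(v)$underwent_mpt
    for (c_scale in c(0.01, 3, 1000)) {
      expect_identical(call_mpt(v * c_scale)$underwent_mpt, base)
    }
  }
})

test_that("mpt_fraction is simple percentage arithmetic with an empty guard", {
  flags <- c(rep(TRUE, 40), rep(FALSE, 10))
  expect_equal(mpt_fraction(flags), 80)
  expect_equal(mpt_fraction(rep(FALSE, 5)), 0)
  expect_error(mpt_fraction(list()), "empty")
})

test_that("transmittance computation normalizes by the blank", {
  dim <- c(64, 64)
  px <- 0.1625
  mkstack <- function(vals) {
    image_bundle(lapply(vals, function(v) {
      img <- matrix(100, dim[1], dim[2])
      img[roi_window(32, 32, 4, dim, px)$pixels] <- v
      img
    }), "transmitted", pixel_size_um = px)
  }
  r <- roi_window(32, 32, 4, dim, px)
  blank <- roi_window(10, 10, 4, dim, px)
  # darkest in-focus region 60, blank 100 -> 0.60 (min over slices)
  expect_equal(compute_transmittance(mkstack(c(90, 60, 85)), r, blank), 0.60)
  # uniform field: ratio 1
  uni <- image_bundle(list(matrix(100, dim[1], dim[2])), "transmitted",
                      pixel_size_um = px)
  expect_equal(compute_transmittance(uni, r, blank), 1)
  # global illumination scaling cancels out
  scaled <- mkstack(c(90, 60, 85))
  scaled$frames <- lapply(scaled$frames, function(f) f * 3.7)
  expect_equal(compute_transmittance(scaled, r, blank), 0.60, tolerance = 1e-12)
  # zero blank errors
  zero <- image_bundle(list(matrix(0, dim[1], dim[2])), "transmitted",
                       pixel_size_um = px)
  expect_error(compute_transmittance(zero, r, blank), "blank mean")
})

test_that("swelling rule thresholds the change from baseline at 0.16", {
  expect_true(call_swelling(c(0.60, 0.80))$swollen)    # change 0.20
  expect_false(call_swelling(c(0.60, 0.70))$swollen)   # change 0.10
  expect_false(call_swelling(c(0.60, 0.60, 0.60))$swollen)
  # the rule is strict: a change exactly at the threshold does not qualify
  # (representable values so the comparison is exact in floating point)
  expect_false(call_swelling(c(0.5, 0.625), threshold = 0.125)$swollen)
  expect_equal(call_swelling(c(0.60, 0.55, 0.80))$change, 0.20)
  expect_error(call_swelling(0.6), "at least 2")
})

test_that("polarization classification is a background-ratio rule", {
  # intensity equal to background -> ratio 1 -> depolarized
  expect_false(classify_polarization(50 * 10, 50, 10)$polarized)
  # 5x background at threshold 2 -> polarized
  call <- classify_polarization(5 * 50 * 10, 50, 10, ratio_threshold = 2)
  expect_true(call$polarized)
  expect_equal(call$tmre_over_background, 5)
  expect_error(classify_polarization(100, 0, 10), "positive")
})

test_that("polarized cohort fraction is recovered from a zero-noise field", {
  cfg <- sim_config(seed = 19, field_px = 256)
  field <- gen_uptake_field(cfg, n_cells = 0, per_cell_counts = integer(0),
                            n_free_particles = 50,
                            polarized_fraction_free = 0.9)
  q <- mitoquant:::quantify_polarization_field(
    field, experiment_config("polarization_timecourse")$analysis)
  expect_equal(q$fraction, 90)
  expect_equal(q$truth_fraction, 90)
})

test_that("ETC response is post- minus pre-malate plateau, normalized to control", {
  expect_equal(etc_response(rep(100, 10))$increase, 0)
  s <- c(100, 100, 100, 125, 150, 150, 150, 150, 150, 150)
  r <- etc_response(s, malate_frame = 3)
  expect_equal(r$increase, 50)            # frames 1-3 vs 5-10, frame 4 skipped
  expect_equal(r$pre_frames, 1:3)
  expect_equal(r$post_frames, 5:10)
  expect_equal(etc_response(s, control_increase = 100)$normalized_increase, 50)
  # treated increase 30 vs untreated 60 -> 50% of control
  treated <- c(100, 100, 100, 115, 130, 130, 130, 130, 130, 130)
  expect_equal(etc_response(treated, control_increase = 60)$normalized_increase, 50)
  expect_error(etc_response(s, control_increase = 0), "positive")
  expect_error(etc_response(c(1, 2, 3), malate_frame = 3), "too short")
})
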