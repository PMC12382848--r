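test_that("normalization rescales the control mean to exactly 100", {
  w <- data.frame(well = sprintf("W%02d", 1:6),
                  condition = rep(c("ctl", "trt"), each = 3),
                  value = c(0.5, 0.5, 0.5, 0.6, 0.6, 0.6))
  n1 <- normalize_to_control(w, "ctl")
  expect_equal(mean(n1$value[n1$condition == "ctl"]), 100)
  expect_equal(unique(n1$value[n1$condition == "trt"]), 120)
  # idempotence
  n2 <- normalize_to_control(n1, "ctl")
  expect_equal(n1$value, n2$value)
  # control-only table self-normalizes
  ctl <- w[w$condition == "ctl", ]
  expect_equal(mean(normalize_to_control(ctl, "ctl")$value), 100)
  expect_error(normalize_to_control(w, "missing"), "no wells")
  w$value <- -w$value
  expect_error(normalize_to_control(w, "ctl"), "positive")
})

test_that("adherent-cell ratio is post over pre with a zero guard", {
  expect_equal(adherent_ratio(100, 100), 1)
  expect_equal(adherent_ratio(80, 100), 1.25)
  expect_equal(adherent_ratio(c(80, 100), c(100, 90)), c(1.25, 0.9))
  expect_error(adherent_ratio(0, 10), "positive")
})

test_that("calibration fit is exact on noiseless linear standards", {
  std <- data.frame(concentration = c(0, 5, 10, 15), signal = 10 * c(0, 5, 10, 15) + 100)
  curve <- fit_calibration(std)
  expect_equal(curve$slope, 10)
  expect_equal(curve$intercept, 100)
  expect_equal(curve$r_squared, 1)
  # signal 250 with 5-fold dilution -> (250-100)/10 * 5 = 75
  expect_equal(as.numeric(invert_calibration(curve, 250, dilution_factor = 5)), 75)
  # round trip is the identity
  conc <- c(2, 7, 12)
  sig <- curve$slope * conc + curve$intercept
  expect_equal(as.numeric(invert_calibration(curve, sig)), conc, tolerance = 1e-12)
  expect_error(fit_calibration(data.frame(concentration = c(3, 3), signal = 1:2)),
               "singular")
})

test_that("noisy calibration matches the closed-form least-squares solution", {
  set.seed(8)
  conc <- seq(0, 12, by = 2)
  sig <- 220 * conc + 150 + rnorm(length(conc), sd = 20)
  curve <- fit_calibration(data.frame(concentration = conc, signal = sig))
  X <- cbind(1, conc)
  beta <- solve(t(X) %*% X, t(X) %*% sig)
  expect_equal(curve$intercept, beta[1], tolerance = 1e-10)
  expect_equal(curve$slope, beta[2], tolerance = 1e-10)
})

test_that("extrapolation beyond the standards is flagged", {
  curve <- fit_calibration(data.frame(concentration = 0:5, signal = 0:5 * 2))
  expect_warning(out <- invert_calibration(curve, 100), "extrapolating")
  expect_true(attr(out, "extrapolated"))
})

test_that("dose arithmetic conserves analyte amount", {
  mix <- dose_mix(c(10, 100, 10), c(720, 0, 0))
  expect_equal(mix$final_volume, 120)
  expect_equal(mix$final_concentration, 60)
  expect_equal(mix$total_amount, 7200)
  # equal volumes of equal concentrations: concentration unchanged
  expect_equal(dose_mix(c(50, 50), c(8, 8))$final_concentration, 8)
  # conservation under arbitrary splits
  set.seed(2)
  for (i in 1:20) {
    v <- runif(4, 1, 100); conc <- runif(4, 0, 50)
    m <- dose_mix(v, conc)
    expect_equal(m$final_concentration * m$final_volume, sum(v * conc),
                 tolerance = 1e-12)
  }
  expect_error(dose_mix(c(0, 10), c(1, 1)), "positive")
})
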