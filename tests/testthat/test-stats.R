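test_that("one-way ANOVA matches the closed-form sums-of-squares oracle", {
  g <- list(a = c(10.1, 11.2, 9.8, 10.5),
            b = c(12.0, 12.4, 11.7, 12.9, 12.1),
            c = c(9.1, 9.5, 8.8))
  res <- anova_oneway(g)
  # independent oracle: explicit between/within decomposition
  y <- unlist(g); n <- lengths(g); N <- length(y); k <- length(g)
  gm <- mean(y)
  ss_b <- sum(n * (vapply(g, mean, numeric(1)) - gm)^2)
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  F_oracle <- (ss_b / (k - 1)) / (ss_w / (N - k))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(F_oracle, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df_between, k - 1)
  expect_equal(res$df_within, N - k)
  expect_equal(res$ms_within, ss_w / (N - k), tolerance = 1e-12)
})

test_that("ANOVA handles separation and degenerate input", {
  far <- list(a = rep(10, 5) + rnorm(5, sd = 1e-3),
              b = rep(50, 5) + rnorm(5, sd = 1e-3))
  expect_lt(anova_oneway(far)$p, 1e-6)
  expect_error(anova_oneway(list(a = rep(1, 3), b = rep(1, 3))), "identical")
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("studentized-range quantiles match published tables to 2 decimals", {
  # standard upper-5% q tables, k = 2..6
  expected <- list(
    `10` = c(3.15, 3.88, 4.33, 4.65, 4.91),
    `20` = c(2.95, 3.58, 3.96, 4.23, 4.45),
    `60` = c(2.83, 3.40, 3.74, 3.98, 4.16))
  for (df in c(10, 20, 60)) {
    got <- vapply(2:6, function(k) snk_critical_q(0.05, k, df), numeric(1))
    expect_equal(round(got, 2), expected[[as.character(df)]], tolerance = 0.011)
  }
})

test_that("SNK flags an outlying mean and spares the close pair", {
  g <- list(ctl = c(100.2, 99.5, 100.9, 99.9, 100.4),
            trtA = c(101.0, 100.1, 100.7, 99.6, 100.8),
            trtB = c(130.4, 129.2, 131.0, 130.1, 129.8))
  res <- snk_posthoc(g)
  expect_true(snk_significant(res, "trtB", "ctl"))
  expect_true(snk_significant(res, "trtB", "trtA"))
  expect_false(snk_significant(res, "ctl", "trtA"))
  # oracle for the widest range statistic: direct arithmetic
  mse <- res$ms_within
  q_expected <- (mean(g$trtB) - mean(g$ctl)) / sqrt(mse / 2 * (1/5 + 1/5))
  widest <- res$pairwise[res$pairwise$span == 3, ]
  expect_equal(widest$q, q_expected, tolerance = 1e-12)
  expect_equal(widest$q_crit, qtukey(0.95, 3, 12), tolerance = 1e-12)
})

test_that("two identical groups yield no significant pairs", {
  set.seed(5)
  x <- rnorm(8, 100, 5)
  res <- snk_posthoc(list(a = x, b = x + 1e-9))
  expect_false(any(res$pairwise$significant))
})

test_that("with two groups SNK reduces to the pooled t-test decision", {
  set.seed(42)
  for (i in 1:50) {
    a <- rnorm(6, 100, 10); b <- rnorm(6, 100 + sample(c(0, 8, 15), 1), 10)
    snk <- snk_posthoc(list(a = a, b = b), alpha = 0.05)
    t_dec <- t.test(a, b, var.equal = TRUE)$p.value < 0.05
    expect_identical(any(snk$pairwise$significant), t_dec)
  }
})

test_that("SNK decisions are invariant under affine rescaling", {
  set.seed(9)
  g <- list(a = rnorm(6, 10), b = rnorm(6, 11), c = rnorm(6, 14))
  base <- snk_posthoc(g)$pairwise$significant
  for (tr in list(c(3, 0), c(0.01, 5), c(120, -40))) {
    g2 <- lapply(g, function(x) tr[1] * x + tr[2])
    expect_identical(snk_posthoc(g2)$pairwise$significant, base)
  }
})

test_that("stepwise logic never tests a pair inside a non-significant range", {
  set.seed(31)
  for (i in 1:30) {
    g <- lapply(1:4, function(j) rnorm(5, 100 + sample(0:6, 1), 8))
    names(g) <- letters[1:4]
    pw <- snk_posthoc(g)$pairwise
    for (r in which(!pw$significant & pw$span < 4)) {
      enclosing <- pw[pw$span > pw$span[r], ]
      # if any enclosing range containing this pair failed, it must be untested
      lab <- names(sort(snk_posthoc(g)$group_means, decreasing = TRUE))
      pos <- match(c(pw$group1[r], pw$group2[r]), lab)
      blocked <- any(!enclosing$significant &
                       match(enclosing$group1, lab) <= min(pos) &
                       match(enclosing$group2, lab) >= max(pos))
      if (blocked) expect_false(pw$tested[r])
    }
  }
})

test_that("condition summaries report mean, SEM and annotations", {
  set.seed(12)
  w <- data.frame(
    well = sprintf("W%02d", 1:18),
    condition = rep(c("H2O2", "H2O2+Imit", "H2O2+Hmit"), each = 6),
    value = c(rnorm(6, 0.5, 0.02), rnorm(6, 0.8, 0.02), rnorm(6, 0.65, 0.02)))
  s <- summarize_conditions(w, c("H2O2", "H2O2+Imit", "H2O2+Hmit"),
                            control_condition = "H2O2",
                            reference_condition = "H2O2+Hmit")
  tab <- s$table
  expect_equal(tab$normalized_mean[tab$condition == "H2O2"], 100)
  one <- w$value[w$condition == "H2O2+Imit"]
  expect_equal(tab$sem[tab$condition == "H2O2+Imit"], sd(one) / sqrt(6))
  expect_equal(tab$sig_vs_control[tab$condition == "H2O2+Imit"], "**")
  expect_equal(tab$sig_vs_reference[tab$condition == "H2O2+Imit"], "##")
  expect_equal(tab$sig_vs_reference[tab$condition == "H2O2+Hmit"], "")
  # a mislabeled well is an error naming the well
  w2 <- w; w2$condition[7] <- "typo"
  expect_error(summarize_conditions(w2, unique(w$condition), "H2O2"), "W07")
})
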