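# Condition-level statistics: SEM, one-way ANOVA, and the
# Student-Newman-Keuls stepwise multiple-comparison procedure.

#' One-way analysis of variance over condition groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test). The
#' "two-tailed" qualifier of the reference protocol is read as this standard
#' procedure: the F test is inherently one-sided on the variance-ratio scale.
#'
#' @param groups Named list of numeric vectors, one per condition; at least
#'   two groups with at least two observations each.
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`,
#'   `ms_within`, `group_means`, `group_n`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))$p
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  if (length(unique(y)) == 1L) stop("all observations identical: F undefined")
  g <- factor(rep(seq_along(groups), n))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  ms_within <- sum(vapply(groups, function(x) (length(x) - 1) * stats::var(x),
                          numeric(1))) / (length(y) - length(groups))
  nm <- names(groups) %||% as.character(seq_along(groups))
  structure(
    list(F = unname(ft$statistic),
         df_between = unname(ft$parameter[1]),
         df_within = unname(ft$parameter[2]),
         p = unname(ft$p.value),
         ms_within = ms_within,
         group_means = stats::setNames(vapply(groups, mean, numeric(1)), nm),
         group_n = stats::setNames(n, nm)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Critical studentized-range value
#'
#' Upper quantile of the studentized range distribution used by the
#' Student-Newman-Keuls procedure.
#'
#' @param alpha Significance level.
#' @param nmeans Number of means spanned by the range.
#' @param df Error degrees of freedom.
#' @return The critical q value.
#' @export
snk_critical_q <- function(alpha, nmeans, df) {
  stats::qtukey(1 - alpha, nmeans, df)
}

#' Student-Newman-Keuls post hoc procedure
#'
#' Stepwise multiple comparison over ordered group means using studentized-
#' range statistics with the pooled within-group mean square. Means are
#' sorted in descending order; ranges are tested from the widest inward, and
#' a pair is tested only if every enclosing range was significant — a pair
#' inside a non-significant range is declared non-significant without
#' testing. For a pair spanning `r` ordered means the statistic is
#' `q = (m_i - m_j) / sqrt(MSE/2 * (1/n_i + 1/n_j))` (the Kramer form, which
#' reduces to the textbook `q = diff / sqrt(MSE/n)` for balanced groups),
#' compared with the upper-`alpha` studentized-range quantile for `r` means.
#'
#' @param groups Named list of numeric vectors; every group needs n >= 2.
#' @param alpha Familywise significance level (default 0.05).
#' @return An `snk_result`: `group_means` (sorted descending), `group_n`,
#'   `pairwise` (data frame: `group1`, `group2`, `span`, `q`, `q_crit`,
#'   `tested`, `significant`), `alpha`, `df_within`, `ms_within`.
#' @export
snk_posthoc <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2, alpha > 0, alpha < 1)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs at least 2 observations")
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  means <- vapply(groups, mean, numeric(1))
  df <- sum(n) - k
  mse <- sum(vapply(groups, function(x) (length(x) - 1) * stats::var(x),
                    numeric(1))) / df
  if (!is.finite(mse) || mse <= 0) {
    stop("pooled within-group variance must be positive")
  }
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; ni <- n[ord]; lab <- nm[ord]

  sig <- matrix(NA, k, k)      # significant decision
  tested <- matrix(FALSE, k, k)
  rows <- list()
  for (span in k:2) {
    for (p in 1:(k - span + 1)) {
      q_pos <- p + span - 1
      blocked <- FALSE
      if (span < k) {
        left <- if (p > 1) !isTRUE(sig[p - 1, q_pos]) else FALSE
        right <- if (q_pos < k) !isTRUE(sig[p, q_pos + 1]) else FALSE
        blocked <- left || right
      }
      q_crit <- snk_critical_q(alpha, span, df)
      q_stat <- (m[p] - m[q_pos]) /
        sqrt(mse / 2 * (1 / ni[p] + 1 / ni[q_pos]))
      if (blocked) {
        sig[p, q_pos] <- FALSE
      } else {
        tested[p, q_pos] <- TRUE
        sig[p, q_pos] <- q_stat > q_crit
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lab[p], group2 = lab[q_pos], span = span,
        q = q_stat, q_crit = q_crit,
        tested = tested[p, q_pos], significant = sig[p, q_pos],
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(group_means = stats::setNames(m, lab),
         group_n = stats::setNames(ni, lab),
         pairwise = do.call(rbind, rows),
         alpha = alpha, df_within = df, ms_within = mse),
    class = "snk_result"
  )
}

#' @export
print.snk_result <- function(x, ...) {
  cat(sprintf("Student-Newman-Keuls (alpha = %g, df = %g)\n", x$alpha, x$df_within))
  print(x$pairwise[, c("group1", "group2", "span", "q", "q_crit", "significant")],
        row.names = FALSE)
  invisible(x)
}

#' Is a pair significant in an SNK result?
#'
#' @param snk An `snk_result`.
#' @param a,b Group labels.
#' @return Logical.
#' @export
snk_significant <- function(snk, a, b) {
  pw <- snk$pairwise
  hit <- (pw$group1 == a & pw$group2 == b) | (pw$group1 == b & pw$group2 == a)
  if (!any(hit)) stop("pair not found: ", a, " vs ", b)
  isTRUE(pw$significant[hit])
}

#' Standard error of the mean
#'
#' @param x Numeric vector (n >= 1).
#' @return `sd(x) / sqrt(length(x))`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Condition-level summary with significance annotations
#'
#' Assembles the per-condition report used for plate-style figures: mean,
#' SEM, mean normalized to control = 100, and significance annotations from
#' the ANOVA + Student-Newman-Keuls pipeline — `*`/`**` versus the control
#' condition (p < 0.05 / p < 0.01) and `#`/`##` versus an optional second
#' reference condition.
#'
#' @param wells Data frame with columns `well`, `condition`, `value` (a
#'   single assay).
#' @param design Character vector of the expected condition labels; any well
#'   with a condition outside `design` raises an error naming the well.
#' @param control_condition Condition normalized to 100 and used for `*`
#'   annotations.
#' @param reference_condition Optional second comparator for `#` annotations.
#' @return A `condition_summary`: `table` (condition, n, mean, sem,
#'   normalized_mean, normalized_sem, sig_vs_control, sig_vs_reference),
#'   `anova`, `snk_05`, `snk_01`.
#' @export
summarize_conditions <- function(wells, design, control_condition,
                                 reference_condition = NULL) {
  stopifnot(is.data.frame(wells),
            all(c("well", "condition", "value") %in% names(wells)),
            control_condition %in% design)
  bad <- !(wells$condition %in% design)
  if (any(bad)) {
    stop("wells with unknown condition: ",
         paste(sprintf("%s ('%s')", wells$well[bad], wells$condition[bad]),
               collapse = ", "))
  }
  groups <- split(wells$value, factor(wells$condition, levels = design))
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  ctrl_mean <- mean(groups[[control_condition]])
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) stop("control mean must be positive")

  aov_res <- NULL; snk05 <- NULL; snk01 <- NULL
  pooled_var <- sum(vapply(groups, function(x) (length(x) - 1) * stats::var(x),
                           numeric(1)))
  if (length(groups) >= 2 && all(vapply(groups, length, integer(1)) >= 2) &&
      is.finite(pooled_var) && pooled_var > 0) {
    aov_res <- anova_oneway(groups)
    snk05 <- snk_posthoc(groups, alpha = 0.05)
    snk01 <- snk_posthoc(groups, alpha = 0.01)
  }

  star <- function(cond, ref, s05, s01) {
    if (is.null(s05) || cond == ref) return("")
    if (snk_significant(s01, cond, ref)) return("**")
    if (snk_significant(s05, cond, ref)) return("*")
    ""
  }
  tab <- do.call(rbind, lapply(names(groups), function(cond) {
    x <- groups[[cond]]
    data.frame(
      condition = cond, n = length(x), mean = mean(x),
      sem = if (length(x) > 1) sem(x) else NA_real_,
      normalized_mean = 100 * mean(x) / ctrl_mean,
      normalized_sem = if (length(x) > 1) 100 * sem(x) / ctrl_mean else NA_real_,
      sig_vs_control = star(cond, control_condition, snk05, snk01),
      sig_vs_reference = if (is.null(reference_condition)) "" else {
        s <- star(cond, reference_condition, snk05, snk01)
        chartr("*", "#", s)
      },
      stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, anova = aov_res, snk_05 = snk05, snk_01 = snk01,
                 control_condition = control_condition,
                 reference_condition = reference_condition),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  if (!is.null(x$anova)) print(x$anova)
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a condition summary as CSV and JSON
#'
#' @param summary A `condition_summary`.
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, the summary.
#' @export
write_condition_summary <- function(summary, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(summary, "condition_summary"))
  if (!is.null(path_csv)) {
    utils::write.csv(summary$table, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    payload <- list(
      table = summary$table,
      anova = if (is.null(summary$anova)) NULL else unclass(summary$anova),
      control_condition = summary$control_condition,
      reference_condition = summary$reference_condition)
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(summary)
}
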