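# Well-level computations: normalization to control = 100, adherent-cell
# ratios, linear calibration curves with inversion, and dose/mixing
# arithmetic.

#' Normalize well values so the control condition averages 100
#'
#' Every value is multiplied by `100 / mean(control values)` within each
#' assay, so the control mean becomes exactly 100 — the convention used for
#' reporting plate-level effects relative to untreated cells. Normalizing an
#' already-normalized table is a no-op.
#'
#' @param wells Data frame with at least `condition` and `value` columns;
#'   an `assay` column, when present, is normalized within.
#' @param control_condition Label of the control condition.
#' @return The table with `value` rescaled.
#' @export
normalize_to_control <- function(wells, control_condition) {
  stopifnot(is.data.frame(wells), all(c("condition", "value") %in% names(wells)))
  groups <- if ("assay" %in% names(wells)) unique(wells$assay) else NA_character_
  out <- wells
  for (a in groups) {
    sel <- if (is.na(a)) rep(TRUE, nrow(wells)) else wells$assay == a
    ctrl <- out$value[sel & out$condition == control_condition]
    if (!length(ctrl)) stop("control condition '", control_condition,
                            "' has no wells", if (!is.na(a)) paste0(" for assay ", a))
    m <- mean(ctrl)
    if (!is.finite(m) || m <= 0) stop("control mean must be positive")
    out$value[sel] <- out$value[sel] * 100 / m
  }
  out
}

#' Ratio of post- to pre-incubation adherent cell counts
#'
#' @param pre_count Pre-incubation adherent cell count(s), > 0.
#' @param post_count Post-incubation count(s) (dead and non-adherent cells
#'   already excluded).
#' @return `post_count / pre_count`, vectorized.
#' @export
adherent_ratio <- function(pre_count, post_count) {
  if (any(pre_count <= 0)) stop("pre-incubation count must be positive")
  post_count / pre_count
}

#' Fit a linear calibration curve to standards
#'
#' Ordinary least squares of signal on concentration, as used for the
#' Amplex Red hydrogen-peroxide standard curve. The kit response is linear
#' over the working range, so a straight line through a fitted intercept is
#' the model; the fit must be invertible (non-zero slope).
#'
#' @param standards Data frame with columns `concentration` and `signal`;
#'   at least two distinct concentrations.
#' @return A `calibration_curve`: `slope`, `intercept`, `r_squared`,
#'   `standards`, `signal_range`.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "signal") %in% names(standards)))
  if (length(unique(standards$concentration)) < 2) {
    stop("singular fit: need at least two distinct standard concentrations")
  }
  fit <- stats::lm(signal ~ concentration, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop("zero slope: curve not invertible")
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         standards = standards,
         signal_range = range(standards$signal)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> signal = %.6g * conc + %.6g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a calibration curve to recover concentrations
#'
#' Returns `(signal - intercept) / slope * dilution_factor`, so a sample
#' diluted before the assay (5-fold with PBS in the reference protocol) is
#' reported at its pre-dilution concentration. Signals outside the calibrated
#' range are extrapolations: they are still computed but flagged with a
#' warning and in the `extrapolated` attribute.
#'
#' @param curve A `calibration_curve`.
#' @param signal Numeric signal value(s).
#' @param dilution_factor Fold-dilution applied to the sample before
#'   measurement.
#' @return Concentration(s), with attribute `extrapolated`.
#' @export
invert_calibration <- function(curve, signal, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"), dilution_factor > 0)
  conc <- (signal - curve$intercept) / curve$slope * dilution_factor
  extra <- signal < curve$signal_range[1] | signal > curve$signal_range[2]
  if (any(extra)) {
    warning("signal outside the calibrated range: extrapolating")
  }
  attr(conc, "extrapolated") <- extra
  conc
}

#' Dose and mixing arithmetic for well contents
#'
#' Conservation of analyte amount over mixed components: the final
#' concentration is `sum(v_i * c_i) / sum(v_i)` and each component delivers
#' `v_i * c_i` of analyte. Units are the caller's (e.g. uL and uM give amounts
#' in pmol; uL and ug/mL give ug when volumes are expressed in mL — use
#' consistent units).
#'
#' @param volumes Component volumes, all > 0.
#' @param concentrations Component analyte concentrations (0 for diluent).
#' @return A list: `final_volume`, `final_concentration`, `amounts` (per
#'   component), `total_amount`.
#' @examples
#' # 10 uL of 720 uM into 110 uL of diluent -> 60 uM in 120 uL
#' dose_mix(c(10, 100, 10), c(720, 0, 0))$final_concentration
#' @export
dose_mix <- function(volumes, concentrations) {
  stopifnot(length(volumes) == length(concentrations), length(volumes) >= 1)
  if (any(volumes <= 0)) stop("volumes must be positive")
  v_tot <- sum(volumes)
  amounts <- volumes * concentrations
  list(final_volume = v_tot,
       final_concentration = sum(amounts) / v_tot,
       amounts = amounts,
       total_amount = sum(amounts))
}
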