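#' Generate synthetic plate-reader well tables with ground truth
#'
#' Emits per-well raw values for the plate-level assays used downstream:
#' dehydrogenase absorbance (`DH`), ATP luminescence (`ATP`), Amplex Red
#' fluorescence (`Amplex`), total NAD(H) absorbance (`NADtotal`), and pre/post
#' adherent-cell counts (`count_pre`, `count_post`). Each condition/assay pair
#' has a stated true mean and Gaussian well-to-well noise; the emitted
#' manifest is the truth table itself, so downstream normalization and
#' statistics can be checked exactly at zero noise.
#'
#' @param design Data frame with columns `condition` and `n_wells` (wells per
#'   condition per replicate).
#' @param truth Data frame with columns `condition`, `assay`, `true_mean`,
#'   `noise_sd` (all `noise_sd >= 0`).
#' @param n_replicates Number of independent replicate plates.
#' @param seed Integer seed.
#' @param dead_fraction Fraction of wells in which the `count_post` field also
#'   records shrunken dead / non-adherent cells that a counter must exclude;
#'   the emitted `value` is always the count of adherent live cells, and the
#'   excluded number is carried in `excluded_dead`.
#' @return A list with `wells` (data frame: `well`, `condition`, `replicate`,
#'   `assay`, `value`, `excluded_dead`) and `manifest`.
#' @export
gen_plate_readouts <- function(design, truth, n_replicates = 1, seed = 1,
                               dead_fraction = 0) {
  stopifnot(is.data.frame(design), nrow(design) >= 1,
            all(c("condition", "n_wells") %in% names(design)),
            is.data.frame(truth),
            all(c("condition", "assay", "true_mean", "noise_sd") %in% names(truth)),
            all(truth$noise_sd >= 0))
  bad <- setdiff(truth$condition, design$condition)
  if (length(bad)) stop("truth rows for unknown condition(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  rows <- list()
  wid <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (ti in seq_len(nrow(truth))) {
      cond <- truth$condition[ti]
      n_w <- design$n_wells[match(cond, design$condition)]
      for (w in seq_len(n_w)) {
        wid <- wid + 1L
        v <- truth$true_mean[ti] +
          if (truth$noise_sd[ti] > 0) stats::rnorm(1, sd = truth$noise_sd[ti]) else 0
        excl <- 0L
        if (grepl("^count", truth$assay[ti])) {
          v <- max(0, round(v))
          if (truth$assay[ti] == "count_post" && dead_fraction > 0) {
            excl <- stats::rpois(1, dead_fraction * v)
          }
        }
        rows[[wid]] <- data.frame(
          well = sprintf("W%04d", wid), condition = cond,
          replicate = rep_i, assay = truth$assay[ti], value = v,
          excluded_dead = excl, stringsAsFactors = FALSE)
      }
    }
  }
  wells <- do.call(rbind, rows)
  list(wells = wells,
       manifest = new_manifest("plate_readouts", truth,
                               sim_config(seed = seed),
                               extra = list(design = design,
                                            n_replicates = n_replicates)))
}
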