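#' Paired matched and mismatch-adjusted delta-TEC at considered sites
#'
#' For every site considered in the pausing analysis (valid delta-TEC,
#' restricted to `positions` when given), returns the matched delta-TEC and
#' the delta-TEC recomputed assuming a transcriptional error at the
#' penultimate 3' ribonucleobase (see [mismatch_adjusted_dtec()]). Only the
#' four mismatch identities covered by the parameter table (rA.dA, rC.dC,
#' rG.dG, rU.dT - one per template base) are modeled.
#'
#' @param tx A `concat_transcriptome`.
#' @param profile An `energy_profile`.
#' @param mm_table An `nn_energy_table` of kind "RNA:DNA-mismatch".
#' @param mode "dst1" (default) or "wt".
#' @param positions Sites to include (default all).
#' @return data.frame with position, dtec, dtec_mm (rows with either NA are
#'   dropped).
#' @export
mismatch_dtec_distribution <- function(tx, profile, mm_table, mode = "dst1",
                                       positions = seq_len(tx$n)) {
  dtec <- if (mode == "dst1") profile$dtec_dst1 else profile$dtec_wt
  dtec_mm <- mismatch_adjusted_dtec(tx, profile, mm_table, mode = mode)
  keep <- positions[!is.na(dtec[positions]) & !is.na(dtec_mm[positions])]
  data.frame(position = keep, dtec = dtec[keep], dtec_mm = dtec_mm[keep])
}

#' Predicted fold changes in pausing and backtracking upon a mismatch
#'
#' Under a logistic dependence of pause (or long-backtrack) odds on delta-TEC,
#' the per-site odds ratio of the mismatched versus matched state is
#' exp(beta * (dtec_mm - dtec)) - independent of the intercept. Folds are
#' summarized as the mean of per-site odds ratios (median and the ratio of
#' mean odds are also reported); the combined fold is the mean per-site
#' product of the pause and backtrack odds ratios.
#'
#' @param pairs data.frame from [mismatch_dtec_distribution()].
#' @param pause_fit `odds_fit` of pause labels on delta-TEC (dst1 mode).
#' @param backtrack_fit `odds_fit` of long-vs-short backtrack labels on
#'   delta-TEC.
#' @return Object of class `mismatch_report`: list with per-site odds ratios
#'   and summary folds (`pause_fold`, `backtrack_fold`, `combined_fold`, plus
#'   medians and alternative summaries).
#' @export
predicted_fold_changes <- function(pairs, pause_fit, backtrack_fit) {
  if (missing(pause_fit) || is.null(pause_fit)) stop("pause_fit required")
  if (missing(backtrack_fit) || is.null(backtrack_fit)) stop("backtrack_fit required")
  delta <- pairs$dtec_mm - pairs$dtec
  or_pause <- exp(pause_fit$beta * delta)
  or_bt <- exp(backtrack_fit$beta * delta)
  odds_ratio_of_means <- function(beta, x, x_mm) {
    mean(exp(beta * x_mm)) / mean(exp(beta * x))
  }
  out <- list(
    n_sites = nrow(pairs),
    delta_dtec_mean = mean(delta),
    pause_fold = mean(or_pause),
    pause_fold_median = stats::median(or_pause),
    pause_fold_ratio_of_mean_odds =
      odds_ratio_of_means(pause_fit$beta, pairs$dtec, pairs$dtec_mm),
    backtrack_fold = mean(or_bt),
    backtrack_fold_median = stats::median(or_bt),
    backtrack_fold_ratio_of_mean_odds =
      odds_ratio_of_means(backtrack_fit$beta, pairs$dtec, pairs$dtec_mm),
    combined_fold = mean(or_pause * or_bt),
    combined_fold_median = stats::median(or_pause * or_bt),
    composition = "combined = mean over sites of (pause OR * backtrack OR)")
  class(out) <- "mismatch_report"
  out
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf(paste0(
    "mismatch_report over %d sites (mean delta-TEC shift %.2f kJ/mol):\n",
    "  pause fold %.2f (median %.2f)\n",
    "  long-backtrack fold %.2f (median %.2f)\n",
    "  combined cleavage fold %.2f (median %.2f)\n"),
    x$n_sites, x$delta_dtec_mean, x$pause_fold, x$pause_fold_median,
    x$backtrack_fold, x$backtrack_fold_median,
    x$combined_fold, x$combined_fold_median))
  invisible(x)
}
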