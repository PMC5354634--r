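#' ROC curve and AUC by threshold sweep
#'
#' Thresholds are taken at unique score values (tied scores collapse to one
#' threshold), so the trapezoidal area equals the Mann-Whitney U statistic
#' scaled by n+ * n-, with half credit for ties. NA scores are dropped with
#' their labels.
#'
#' @param scores Numeric predictor values (higher = more pause-like).
#' @param labels Logical or 0/1 pause labels.
#' @return Object of class `roc_result`: list with `thresholds`, `fpr`, `tpr`
#'   (from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (any(!is.finite(scores))) stop("non-finite scores")
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) stop("need at least one positive and one negative label")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # collapse ties: cumulative counts at the end of each tie group
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  out <- list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr, auc = auc,
              n_pos = npos, n_neg = nneg)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d pos, %d neg)\n", x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pause fraction (and odds) binned by a score
#'
#' Groups sites into score bins and reports the fraction that are pauses,
#' with per-bin counts; the odds f/(1-f) are reported only for occupied bins
#' with 0 < f < 1. Empty bins are omitted.
#'
#' @param scores Per-site score (e.g. delta-TEC, kJ/mol).
#' @param labels Pause labels.
#' @param bin_width Bin width on the score axis (default 1).
#' @return data.frame with bin (center), n, n_pause, fraction, odds (NA when
#'   undefined).
#' @export
pause_fraction_by_score <- function(scores, labels, bin_width = 1) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  bin <- floor(scores / bin_width)
  agg <- tapply(labels, bin, function(x) c(n = length(x), k = sum(x)))
  m <- do.call(rbind, agg)
  f <- m[, "k"] / m[, "n"]
  data.frame(bin = (as.numeric(rownames(m)) + 0.5) * bin_width,
             n = as.integer(m[, "n"]), n_pause = as.integer(m[, "k"]),
             fraction = f,
             odds = ifelse(f > 0 & f < 1, f / (1 - f), NA_real_),
             row.names = NULL)
}

#' Per-site logistic fit of pause odds on a score
#'
#' Maximum-likelihood logistic regression of the binary label on the unbinned
#' per-site score: log-odds(pause) = alpha + beta * score. This is the fit
#' used for downstream mismatch fold predictions.
#'
#' @param scores Per-site score.
#' @param labels Binary labels.
#' @return Object of class `odds_fit`: list with `alpha`, `beta`, `se_beta`,
#'   `converged`, `n`.
#' @export
fit_log_odds <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  x <- scores[keep]
  y <- as.integer(as.logical(labels[keep]))
  if (length(unique(y)) < 2L) stop("both classes required for a logistic fit")
  fit <- stats::glm(y ~ x, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge (n = ", length(y), ")")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- list(alpha = unname(co[1]), beta = unname(co[2]),
              se_beta = unname(se[2]), converged = fit$converged, n = length(y))
  class(out) <- "odds_fit"
  out
}

#' @export
print.odds_fit <- function(x, ...) {
  cat(sprintf("odds_fit: log-odds = %.3f + %.4f * score (se %.4f, n = %d)\n",
              x$alpha, x$beta, x$se_beta, x$n))
  invisible(x)
}

#' Average a per-position track around aligned sites
#'
#' Aligns each site and averages the track value at every offset
#' -halfwidth..+halfwidth separately over sites. Sites whose flank contains
#' any NA (or leaves the track) are dropped.
#'
#' @param values Per-position numeric track.
#' @param sites 1-based site positions.
#' @param halfwidth Flank half-width (default 30).
#' @return List with `offsets`, `mean` (per-offset average), `n_sites` used.
#' @export
average_profile <- function(values, sites, halfwidth = 30L) {
  offs <- -halfwidth:halfwidth
  sites <- as.integer(sites)
  ok <- sites - halfwidth >= 1L & sites + halfwidth <= length(values)
  idx <- outer(sites[ok], offs, `+`)
  m <- matrix(values[idx], nrow = sum(ok))
  usable <- !apply(is.na(m), 1, any)
  if (!any(usable)) stop("no site with fully valid flanks")
  list(offsets = offs, mean = colMeans(m[usable, , drop = FALSE]),
       n_sites = sum(usable))
}

#' Centered sliding-window sum over a profile
#'
#' For even width w the window at offset j spans j - w/2 .. j + w/2 - 1 (the
#' 8-bp hybrid convention); ends where the window leaves the profile are NA.
#'
#' @param profile Numeric vector (per-offset values).
#' @param width Window width (default 8).
#' @return Vector of the same length, NA-masked at the ends.
#' @export
running_sum <- function(profile, width = 8L) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  n <- length(profile)
  left <- floor(width / 2)
  out <- rep(NA_real_, n)
  cs <- cumsum(c(0, profile))
  j <- seq_len(n)
  lo <- j - left
  hi <- lo + width - 1L
  ok <- lo >= 1L & hi <= n
  out[ok] <- cs[hi[ok] + 1L] - cs[lo[ok]]
  out
}

#' Resampling null band for an averaged profile
#'
#' Draws `n_sites` random candidate positions, computes their average profile,
#' and repeats `n_resamples` times; the pointwise extremes over resamples form
#' the p < 1/n_resamples band (p < 0.001 at the default 1000 repetitions).
#'
#' @param values Per-position track.
#' @param n_sites Number of sites per resample (match the observed set).
#' @param candidates Candidate positions to draw from (all valid positions of
#'   the considered genes).
#' @param halfwidth Flank half-width.
#' @param n_resamples Number of resamples (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param transform Optional function applied to each resampled profile before
#'   taking extremes (e.g. an 8-bp running sum), also applied to the observed
#'   profile by the caller.
#' @return Object of class `profile_null`: list with `offsets`, `lower`,
#'   `upper`, `n_sites`, `n_resamples`, `seed`.
#' @export
null_band <- function(values, n_sites, candidates, halfwidth = 30L,
                      n_resamples = 1000L, seed, transform = identity) {
  if (n_sites > length(candidates)) stop("n_sites exceeds candidate positions")
  set.seed(seed)
  offs <- -halfwidth:halfwidth
  lower <- rep(Inf, length(offs))
  upper <- rep(-Inf, length(offs))
  for (r in seq_len(n_resamples)) {
    sites <- sample(candidates, n_sites, replace = FALSE)
    prof <- transform(average_profile(values, sites, halfwidth)$mean)
    lower <- pmin(lower, prof, na.rm = FALSE)
    upper <- pmax(upper, prof, na.rm = FALSE)
  }
  out <- list(offsets = offs, lower = lower, upper = upper, n_sites = n_sites,
              n_resamples = n_resamples, seed = seed)
  class(out) <- "profile_null"
  out
}

#' Retain genes with above-average read density
#'
#' Per-gene density is total reads over gene length; genes with density
#' strictly greater than the unweighted mean density across genes are kept.
#' This is the expression filter applied before predictor evaluation, so
#' untranscribed regions (where a pause cannot be observed) do not dilute
#' the negatives.
#'
#' @param track Coverage track.
#' @param tx A `concat_transcriptome`.
#' @return List with `gene_ids` (retained rows of `tx$genes`), `density`
#'   (per-gene), `positions` (concatenated positions in retained genes).
#' @export
expression_filter <- function(track, tx) {
  g <- tx$genes
  total <- tapply(as.numeric(track), tx$gene_id, sum)
  density <- as.numeric(total) / g$length
  keep <- which(density > mean(density))
  if (length(keep) == 0L) warning("no gene exceeds the mean read density")
  positions <- unlist(lapply(keep, function(k) {
    seq(g$offset[k] + 1L, g$offset[k] + g$length[k])
  }), use.names = FALSE)
  list(gene_ids = keep, density = density,
       positions = as.integer(positions %||% integer(0)))
}
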