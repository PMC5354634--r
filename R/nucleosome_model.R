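#' Signed distance to the nearest nucleosome center
#'
#' For each concatenated position, the genomic distance to the nearest center
#' on its chromosome, signed by transcription direction: positive when the
#' position lies downstream of the nucleosome (the polymerase has passed it),
#' negative when upstream (the nucleosome lies ahead). Ties between two
#' equidistant centers resolve toward the downstream center. Chromosomes with
#' no centers yield +Inf.
#'
#' @param tx A `concat_transcriptome`.
#' @param centers Named list of sorted 0-based centers per chromosome
#'   (see [read_nucleosome_table()]).
#' @param pos Positions to score (default all).
#' @return Numeric vector of signed distances.
#' @export
distance_to_nearest <- function(tx, centers, pos = seq_len(tx$n)) {
  gen <- concat_to_genomic(tx, pos)
  out <- rep(Inf, length(pos))
  for (chrom in unique(gen$chrom)) {
    cen <- centers[[chrom]]
    sel <- gen$chrom == chrom
    if (is.null(cen) || length(cen) == 0L) next
    g <- gen$gpos[sel]
    idx <- findInterval(g, cen)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(cen))
    d_lo <- abs(g - cen[lo])
    d_hi <- abs(cen[hi] - g)
    nearest <- ifelse(d_hi <= d_lo, cen[hi], cen[lo])   # tie -> larger coordinate
    dist_genomic <- g - nearest                         # + means right of center
    # transcription-direction sign: flip on minus-strand genes; a genomic tie
    # toward the larger coordinate is "downstream" only on the plus strand, so
    # re-resolve ties downstream for minus-strand positions
    minus <- gen$strand[sel] == "-"
    tie <- d_lo == d_hi & lo != hi
    dist_genomic[tie & minus] <- g[tie & minus] - cen[lo][tie & minus]
    out[sel] <- ifelse(minus, -dist_genomic, dist_genomic)
  }
  out
}

#' Pause probability as a function of nucleosome distance
#'
#' Computes, at single-base resolution, the fraction of scored positions that
#' are pauses at each signed distance to the nearest nucleosome (|d| <= 500 bp
#' by default), and uses that empirical function as a per-position score.
#' Positions farther than `max_dist` from any nucleosome (or on chromosomes
#' without centers) are assigned the mean pause probability over all scored
#' positions.
#'
#' @param pauses A `pause_set` or integer positions.
#' @param centers Nucleosome centers, as in [distance_to_nearest()].
#' @param tx A `concat_transcriptome`.
#' @param max_dist Lookup range in bp (default 500).
#' @param absolute Collapse the lookup to |distance| (default FALSE: signed).
#' @param pos Positions to include (default all).
#' @param loo Leave-one-out scoring (default TRUE): each position's score
#'   excludes its own pause label from the tally it is scored with. At
#'   genome scale this is indistinguishable from the plain in-sample fit
#'   (a O(1/bin-count) correction), but it removes the self-labelling bias
#'   that otherwise inflates the AUC of an uninformative predictor when bins
#'   hold few sites. `loo = FALSE` reproduces the plain fit.
#' @return Object of class `nucleosome_score`: list with `lookup` (plain
#'   per-distance pause fraction, for plotting), `fallback`, `max_dist`,
#'   `absolute`, and `score` (per-position probabilities aligned with `pos`)
#'   plus `pos`.
#' @export
fit_pause_probability_by_distance <- function(pauses, centers, tx, max_dist = 500L,
                                              absolute = FALSE, pos = seq_len(tx$n),
                                              loo = TRUE) {
  sites <- if (inherits(pauses, "pause_set")) pauses$positions else as.integer(pauses)
  is_pause <- logical(tx$n)
  is_pause[sites] <- TRUE
  d <- distance_to_nearest(tx, centers, pos)
  if (absolute) d <- abs(d)
  in_range <- is.finite(d) & abs(d) <= max_dist
  if (!any(in_range)) stop("no positions within ", max_dist, " bp of a nucleosome")
  y <- is_pause[pos]
  fallback <- mean(y)
  db <- d[in_range]
  lab <- y[in_range]
  bin_n <- tapply(lab, db, length)
  bin_k <- tapply(lab, db, sum)
  lookup <- as.numeric(bin_k / bin_n)
  names(lookup) <- names(bin_n)
  score <- numeric(length(pos))
  key <- as.character(db)
  if (loo) {
    n_tot <- length(y)
    k_tot <- sum(y)
    score[!in_range] <- (k_tot - y[!in_range]) / max(n_tot - 1L, 1L)
    nb <- as.numeric(bin_n[key])
    kb <- as.numeric(bin_k[key])
    s <- (kb - lab) / (nb - 1L)
    # singleton bins leave no peers; fall back to the LOO global mean
    single <- nb == 1L
    s[single] <- (k_tot - lab[single]) / max(n_tot - 1L, 1L)
    score[in_range] <- s
  } else {
    score[!in_range] <- fallback
    score[in_range] <- lookup[key]
  }
  out <- list(lookup = lookup, fallback = fallback, max_dist = max_dist,
              absolute = absolute, loo = loo, score = score, pos = pos)
  class(out) <- "nucleosome_score"
  out
}

#' Running average for display
#'
#' Centered running mean of odd width, truncated at the ends (the usual
#' 61-bp trendline). Used for plotting only, never for scoring.
#'
#' @param values Numeric vector.
#' @param width Odd window width (default 61).
#' @return Smoothed vector of the same length.
#' @export
smooth_profile <- function(values, width = 61L) {
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("smoothing width must be odd")
  n <- length(values)
  h <- width %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
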