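#' Classify dst1 pauses by their nearest upstream WT pause
#'
#' Each initial (dst1) pause is matched to the closest WT pause 0-15 bases
#' upstream in transcript coordinates, within the same gene. Offset 0-1 is
#' "short" (no/short backtrack), 2-15 is "long" (long backtrack), and pauses
#' with no WT pause in range are "excluded" from the backtracking analysis.
#'
#' @param dst1_pauses,wt_pauses `pause_set`s (or integer positions) on the
#'   same concatenated coordinates.
#' @param tx A `concat_transcriptome`.
#' @param max_offset Upstream search range (default 15).
#' @param long_min Smallest offset called long (default 2).
#' @return data.frame of class `backtrack_calls`: dst1_position, wt_offset
#'   (NA when excluded), class in {short, long, excluded}.
#' @export
classify_backtracks <- function(dst1_pauses, wt_pauses, tx, max_offset = 15L,
                                long_min = 2L) {
  d <- if (inherits(dst1_pauses, "pause_set")) dst1_pauses$positions else as.integer(dst1_pauses)
  w <- if (inherits(wt_pauses, "pause_set")) wt_pauses$positions else as.integer(wt_pauses)
  is_wt <- logical(tx$n)
  is_wt[w] <- TRUE
  offset <- rep(NA_integer_, length(d))
  for (k in 0:max_offset) {
    cand <- d - k                      # k bases upstream in transcript orientation
    hit <- is.na(offset) & cand >= 1L & is_wt[pmax(cand, 1L)] &
      tx$gene_id[pmax(cand, 1L)] == tx$gene_id[d]
    offset[hit] <- k
  }
  cls <- ifelse(is.na(offset), "excluded",
                ifelse(offset < long_min, "short", "long"))
  out <- data.frame(dst1_position = d, wt_offset = offset, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("backtrack_calls", "data.frame")
  out
}

#' Fraction of long backtracks per delta-TEC bin
#'
#' Excluded pauses are omitted; within each occupied delta-TEC bin the
#' fraction long / (long + short) is reported with counts.
#'
#' @param calls A `backtrack_calls` data.frame.
#' @param dtec Per-position delta-TEC track (dst1 convention).
#' @param bin_width Bin width in kJ/mol (default 1).
#' @return data.frame: bin center, n, n_long, fraction_long.
#' @export
long_fraction_by_dtec <- function(calls, dtec, bin_width = 1) {
  keep <- calls$class != "excluded" & !is.na(dtec[calls$dst1_position])
  x <- dtec[calls$dst1_position[keep]]
  long <- calls$class[keep] == "long"
  bin <- floor(x / bin_width)
  agg <- tapply(long, bin, function(v) c(n = length(v), k = sum(v)))
  m <- do.call(rbind, agg)
  data.frame(bin = (as.numeric(rownames(m)) + 0.5) * bin_width,
             n = as.integer(m[, "n"]), n_long = as.integer(m[, "k"]),
             fraction_long = m[, "k"] / m[, "n"], row.names = NULL)
}

#' Class fractions of a backtrack call set
#' @param calls A `backtrack_calls` data.frame.
#' @return Named numeric vector: fraction short, long, excluded of all dst1
#'   pauses (sums to 1).
#' @export
backtrack_class_fractions <- function(calls) {
  n <- nrow(calls)
  c(short = sum(calls$class == "short") / n,
    long = sum(calls$class == "long") / n,
    excluded = sum(calls$class == "excluded") / n)
}
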