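#' Local mean and standard deviation of a coverage track
#'
#' Centered window of `width` positions around each focal position (focal
#' position included), truncated at gene boundaries so a window never spans
#' the join between two concatenated genes. Population (divide-by-n) standard
#' deviation. Set `truncate_at_genes = FALSE` to compute on the raw
#' concatenated track, windows crossing joins included.
#'
#' @param track Integer coverage track on concatenated coordinates.
#' @param tx A `concat_transcriptome` (required unless
#'   `truncate_at_genes = FALSE`).
#' @param width Odd window width in bp (default 201).
#' @param truncate_at_genes Truncate windows at gene boundaries (default TRUE).
#' @return List with numeric vectors `mean` and `sd`.
#' @export
local_stats <- function(track, tx = NULL, width = 201L, truncate_at_genes = TRUE) {
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("window width must be odd")
  if (width < 3L) stop("window width must be >= 3")
  n <- length(track)
  h <- width %/% 2L
  x <- as.numeric(track)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  if (truncate_at_genes) {
    if (is.null(tx)) stop("tx required when truncating windows at gene boundaries")
    g <- tx$genes[tx$gene_id, ]
    lo <- pmax(i - h, g$offset + 1L)
    hi <- pmin(i + h, g$offset + g$length)
  } else {
    lo <- pmax(i - h, 1L)
    hi <- pmin(i + h, n)
  }
  m <- hi - lo + 1L
  s1 <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  mu <- s1 / m
  v <- pmax(s2 / m - mu^2, 0)       # population variance; clamp fp negatives
  list(mean = mu, sd = sqrt(v))
}

#' Call pause sites as local coverage outliers
#'
#' A position is a pause when its count strictly exceeds the local mean plus
#' `nsd` local standard deviations (width-201 window by default). Windows with
#' zero variance call nothing, so flat regions are never called.
#'
#' @param track Coverage track.
#' @param tx A `concat_transcriptome`.
#' @param nsd Standard-deviation multiplier (default 4; 2 and 6 are the usual
#'   sensitivity presets).
#' @param width Odd local-window width (default 201).
#' @param truncate_at_genes See [local_stats()].
#' @return Object of class `pause_set`: list with sorted integer `positions`,
#'   the calling `params`, and the track's strain label.
#' @export
call_pauses <- function(track, tx, nsd = 4, width = 201L, truncate_at_genes = TRUE) {
  stopifnot(nsd > 0)
  ls <- local_stats(track, tx, width = width, truncate_at_genes = truncate_at_genes)
  called <- which(ls$sd > 0 & track > ls$mean + nsd * ls$sd)
  out <- list(positions = as.integer(called),
              params = list(width = as.integer(width), nsd = nsd,
                            truncate_at_genes = truncate_at_genes,
                            sd_kind = "population", focal_included = TRUE),
              strain = attr(track, "strain"))
  class(out) <- "pause_set"
  out
}

#' @export
print.pause_set <- function(x, ...) {
  cat("pause_set:", length(x$positions), "pauses (nsd =", x$params$nsd,
      ", width =", x$params$width, ", strain =", x$strain %||% "unknown", ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pause set as BED3 + z-score
#' @param pauses A `pause_set`.
#' @param tx A `concat_transcriptome`.
#' @param track The coverage track the pauses were called on.
#' @param path Output path.
#' @export
write_pauses_bed <- function(pauses, tx, track, path) {
  ls <- local_stats(track, tx, width = pauses$params$width,
                    truncate_at_genes = pauses$params$truncate_at_genes)
  p <- pauses$positions
  gen <- concat_to_genomic(tx, p)
  z <- (track[p] - ls$mean[p]) / ls$sd[p]
  out <- data.frame(gen$chrom, gen$gpos, gen$gpos + 1L, round(z, 3))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
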