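pwm_symbols <- function(alphabet) {
  if (alphabet == "mono") VALID_BASES
  else as.vector(outer(VALID_BASES, VALID_BASES, paste0))
}

# symbol observed at (site + offset): a base for mono, the dinucleotide
# (offset, offset+1) for di; NA when the window leaves the gene or hits non-ACGT
symbol_matrix <- function(sites, tx, offsets, alphabet) {
  span <- if (alphabet == "di") c(offsets, max(offsets) + 1L) else offsets
  pos <- outer(sites, span, `+`)
  ok <- pos >= 1L & pos <= tx$n
  base <- matrix(NA_character_, nrow(pos), ncol(pos))
  gid <- matrix(NA_integer_, nrow(pos), ncol(pos))
  base[ok] <- tx$bases[pos[ok]]
  gid[ok] <- tx$gene_id[pos[ok]]
  base[!base %in% VALID_BASES] <- NA
  same_gene <- gid == tx$gene_id[sites]            # compare to the site's own gene
  base[!same_gene | is.na(same_gene)] <- NA
  if (alphabet == "mono") return(base)
  k <- length(offsets)
  di <- matrix(paste0(base[, 1:k], base[, 1:k + 1L]), nrow(base), k)
  di[is.na(base[, 1:k]) | is.na(base[, 1:k + 1L])] <- NA
  di
}

#' Position frequency matrix around pause sites
#'
#' Aggregates and aligns the sequences around each pause site and counts the
#' frequency of each symbol (base, or dinucleotide starting at the offset) at
#' each offset. Sites whose window leaves their gene or covers a non-ACGT
#' base are dropped and tallied.
#'
#' @param pauses A `pause_set` or integer vector of 1-based positions.
#' @param tx A `concat_transcriptome`.
#' @param offsets Inclusive offset range relative to the pause (default -10:5).
#' @param alphabet "mono" or "di".
#' @return Matrix of counts, offsets x symbols, with attributes `n_used` and
#'   `n_dropped`.
#' @export
build_pfm <- function(pauses, tx, offsets = -10:5, alphabet = c("mono", "di")) {
  alphabet <- match.arg(alphabet)
  sites <- if (inherits(pauses, "pause_set")) pauses$positions else as.integer(pauses)
  if (length(sites) == 0L) stop("no pause sites supplied")
  sym <- symbol_matrix(sites, tx, offsets, alphabet)
  usable <- !apply(is.na(sym), 1, any)
  if (!any(usable)) stop("no pause with fully valid flanking sequence")
  sym <- sym[usable, , drop = FALSE]
  symbols <- pwm_symbols(alphabet)
  counts <- t(apply(sym, 2, function(col) table(factor(col, levels = symbols))))
  dimnames(counts) <- list(offset = offsets, symbol = symbols)
  attr(counts, "n_used") <- sum(usable)
  attr(counts, "n_dropped") <- sum(!usable)
  counts
}

#' Background symbol frequencies over the considered genes
#'
#' @param tx A `concat_transcriptome`.
#' @param alphabet "mono" or "di". Dinucleotide frequencies count only stacks
#'   internal to one gene.
#' @return Named frequency vector summing to 1.
#' @export
background_frequencies <- function(tx, alphabet = c("mono", "di")) {
  alphabet <- match.arg(alphabet)
  symbols <- pwm_symbols(alphabet)
  if (alphabet == "mono") {
    obs <- tx$bases[tx$bases %in% VALID_BASES]
  } else {
    i <- 2:tx$n
    ok <- tx$gene_id[i] == tx$gene_id[i - 1L] &
      tx$bases[i] %in% VALID_BASES & tx$bases[i - 1L] %in% VALID_BASES
    obs <- paste0(tx$bases[i - 1L][ok], tx$bases[i][ok])
  }
  tab <- table(factor(obs, levels = symbols))
  as.numeric(tab) / sum(tab) -> f
  names(f) <- symbols
  f
}

#' Position weight matrix from a frequency matrix
#'
#' Log-ratio of the position-specific symbol frequency to the background
#' frequency. A pseudocount of `pseudocount` is added to every cell of the
#' count matrix before normalization so unobserved symbols stay finite.
#'
#' @param pfm Count matrix from [build_pfm()].
#' @param background Background frequencies from [background_frequencies()].
#' @param pseudocount Added to every count (default 1).
#' @return Object of class `pwm_model`: list with `weights` (offsets x
#'   symbols, natural log), `offsets`, `alphabet`, `background`.
#' @export
pfm_to_pwm <- function(pfm, background, pseudocount = 1) {
  if (any(background == 0 & colSums(pfm) > 0)) {
    stop("background frequency of 0 for an observed symbol")
  }
  counts <- pfm + pseudocount
  freq <- counts / rowSums(counts)
  w <- log(sweep(freq, 2, background, "/"))
  out <- list(weights = w,
              offsets = as.integer(rownames(pfm)),
              alphabet = if (ncol(pfm) == 4L) "mono" else "di",
              background = background, pseudocount = pseudocount)
  class(out) <- "pwm_model"
  out
}

#' Train a PWM on pause sites in one call
#' @inheritParams build_pfm
#' @inheritParams pfm_to_pwm
#' @return A `pwm_model`.
#' @export
train_pwm <- function(pauses, tx, offsets = -10:5, alphabet = c("mono", "di"),
                      pseudocount = 1) {
  alphabet <- match.arg(alphabet)
  pfm <- build_pfm(pauses, tx, offsets, alphabet)
  pfm_to_pwm(pfm, background_frequencies(tx, alphabet), pseudocount)
}

#' Score every transcriptome position with a PWM
#'
#' score(i) = sum over offsets of weight(offset, symbol at i + offset).
#' Positions whose window leaves the gene (or covers non-ACGT) are NA.
#'
#' @param pwm A `pwm_model`.
#' @param tx A `concat_transcriptome`.
#' @return Numeric score track of length `tx$n`.
#' @export
score_positions <- function(pwm, tx) {
  n <- tx$n
  i <- seq_len(n)
  score <- numeric(n)
  valid <- rep(TRUE, n)
  di <- pwm$alphabet == "di"
  for (j in seq_along(pwm$offsets)) {
    src <- i + pwm$offsets[j]
    last <- if (di) src + 1L else src
    ok <- src >= 1L & last <= n
    sym <- rep(NA_character_, n)
    if (di) {
      sym[ok] <- paste0(tx$bases[src[ok]], tx$bases[last[ok]])
    } else {
      sym[ok] <- tx$bases[src[ok]]
    }
    ok[ok] <- tx$gene_id[src[ok]] == tx$gene_id[i[ok]] &
      tx$gene_id[last[ok]] == tx$gene_id[i[ok]] &
      sym[ok] %in% colnames(pwm$weights)
    w <- rep(NA_real_, n)
    w[ok] <- pwm$weights[j, ][sym[ok]]
    valid <- valid & ok
    score <- score + ifelse(ok, w, 0)
  }
  score[!valid] <- NA_real_
  score
}
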