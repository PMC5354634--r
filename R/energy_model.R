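KCAL_TO_KJ <- 4.184

#' Nearest-neighbor melting-energy table
#'
#' Loads one of the bundled nearest-neighbor parameter sets and evaluates the
#' per-stack melting free energy at the requested temperature. Entries are
#' stored as positive melting energies in kJ/mol: the free energy required to
#' melt the stack, `-(dH - T*dS)` converted from kcal/mol. Only stack terms
#' are used; duplex initiation and terminal corrections are omitted because
#' window differences cancel any constant terms.
#'
#' Tables:
#' \describe{
#'   \item{DNA:DNA}{SantaLucia 1998 unified parameters, keyed by coding-strand
#'     dinucleotide; reverse-complement symmetric.}
#'   \item{RNA:DNA}{Sugimoto 1995 hybrid parameters; the coding strand is the
#'     RNA strand, so keys are coding dinucleotides read as RNA (T->U).}
#'   \item{RNA:DNA-mismatch}{Synthetic stand-in stacks for an internal
#'     mismatched RNA base (rA.dA, rC.dC, rG.dG, rU.dT), keyed by flanking
#'     neighbor and mismatch identity; see the data file header.}
#' }
#'
#' @param kind One of "DNA:DNA", "RNA:DNA", "RNA:DNA-mismatch".
#' @param temperature Temperature in kelvin (default 303).
#' @return An `nn_energy_table`: list with `kind`, `temperature`, and either
#'   `entries` (named by DNA-alphabet coding dinucleotide) or, for the
#'   mismatch table, `mm5`/`mm3` 4x4 matrices (rows/cols named by DNA-alphabet
#'   neighbor and coding base at the error site).
#' @export
build_energy_table <- function(kind = c("DNA:DNA", "RNA:DNA", "RNA:DNA-mismatch"),
                               temperature = 303) {
  kind <- match.arg(kind)
  stopifnot(temperature > 0)
  file <- switch(kind,
    "DNA:DNA" = "nn_dna_dna_santalucia1998.tsv",
    "RNA:DNA" = "nn_rna_dna_sugimoto1995.tsv",
    "RNA:DNA-mismatch" = "nn_rna_dna_mismatch_synthetic.tsv")
  path <- system.file("extdata", file, package = "tecpause")
  if (path == "") stop("bundled parameter file not found: ", file)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  melt <- function(dH, dS) -(dH - temperature * dS / 1000) * KCAL_TO_KJ
  out <- list(kind = kind, temperature = temperature)
  if (kind == "RNA:DNA-mismatch") {
    e <- melt(tab$dH_kcal_mol, tab$dS_cal_mol_K)
    # index by DNA alphabet: neighbor U->T; mismatch id mapped to the coding
    # (correct) base at the error site, which determines it uniquely
    coding_of_mm <- c(A = "T", C = "G", G = "C", U = "A")
    nb <- sub("U", "T", tab$neighbor)
    site <- coding_of_mm[tab$mismatch]
    mm5 <- matrix(NA_real_, 4, 4, dimnames = list(VALID_BASES, VALID_BASES))
    mm3 <- mm5
    sel5 <- tab$context == "5p"
    mm5[cbind(nb[sel5], site[sel5])] <- e[sel5]
    mm3[cbind(site[!sel5], nb[!sel5])] <- e[!sel5]
    if (anyNA(mm5) || anyNA(mm3)) stop("missing mismatch stack parameter")
    out$mm5 <- mm5
    out$mm3 <- mm3
  } else {
    keys <- gsub("U", "T", tab$dinucleotide)
    entries <- melt(tab$dH_kcal_mol, tab$dS_cal_mol_K)
    names(entries) <- keys
    expected <- as.vector(outer(VALID_BASES, VALID_BASES, paste0))
    missing <- setdiff(expected, keys)
    if (length(missing)) stop("missing dinucleotide parameter(s): ",
                              paste(missing, collapse = ", "))
    out$entries <- entries[expected]
  }
  class(out) <- "nn_energy_table"
  out
}

#' @export
print.nn_energy_table <- function(x, ...) {
  cat("nn_energy_table:", x$kind, "at", x$temperature, "K\n")
  invisible(x)
}

#' Melting energy of a duplex by nearest-neighbor summation
#'
#' Sums the table entry of every consecutive dinucleotide stack in `seq`
#' (coding strand, 5'->3'). A single base has no stack and returns 0.
#'
#' @param seq Sequence string over A/C/G/T, length >= 1.
#' @param table An `nn_energy_table` of kind "DNA:DNA" or "RNA:DNA".
#' @return Melting free energy in kJ/mol (positive = stable duplex).
#' @export
duplex_melting_energy <- function(seq, table) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(b) == 0L) stop("empty sequence")
  if (!all(b %in% VALID_BASES)) {
    stop("unknown character in sequence: ", b[!b %in% VALID_BASES][1])
  }
  if (length(b) == 1L) return(0)
  stacks <- paste0(b[-length(b)], b[-1])
  sum(table$entries[stacks])
}

#' Per-position stack energies on the concatenated transcriptome
#'
#' The energy of stack (i-1, i) is assigned to the more 3' position i. A
#' position is invalid (NA) at the first base of each gene, or when either
#' base of its stack is not A/C/G/T.
#'
#' @param tx A `concat_transcriptome`.
#' @param table An `nn_energy_table` (matched kinds only).
#' @return Numeric vector of length `tx$n`; NA where invalid.
#' @export
per_position_energies <- function(tx, table) {
  n <- tx$n
  e <- rep(NA_real_, n)
  if (n < 2L) return(e)
  i <- 2:n
  same_gene <- tx$gene_id[i] == tx$gene_id[i - 1L]
  b1 <- tx$bases[i - 1L]
  b2 <- tx$bases[i]
  ok <- same_gene & b1 %in% VALID_BASES & b2 %in% VALID_BASES
  e[i[ok]] <- table$entries[paste0(b1[ok], b2[ok])]
  e
}

#' Full per-position energy profile
#'
#' Computes RNA:DNA and DNA:DNA per-position stack energies, their difference
#' d = e_rna - e_dna (the per-stack TEC stability contribution), and the
#' translocation energy difference delta-TEC under both window conventions.
#'
#' @param tx A `concat_transcriptome`.
#' @param temperature Kelvin, default 303.
#' @param stacks_per_window "internal" (7 stacks for an 8-base window; default)
#'   or "leading" (8 stacks including the stack entering the window).
#' @return List of class `energy_profile` with numeric vectors `e_rna`,
#'   `e_dna`, `d`, `dtec_dst1`, `dtec_wt`, the tables used, and the windowing
#'   convention.
#' @export
energy_profile <- function(tx, temperature = 303,
                           stacks_per_window = c("internal", "leading")) {
  stacks_per_window <- match.arg(stacks_per_window)
  t_rna <- build_energy_table("RNA:DNA", temperature)
  t_dna <- build_energy_table("DNA:DNA", temperature)
  e_rna <- per_position_energies(tx, t_rna)
  e_dna <- per_position_energies(tx, t_dna)
  d <- e_rna - e_dna
  prof <- list(e_rna = e_rna, e_dna = e_dna, d = d,
               dtec_dst1 = delta_tec_track(d, "dst1", stacks_per_window),
               dtec_wt = delta_tec_track(d, "wt", stacks_per_window),
               temperature = temperature, stacks_per_window = stacks_per_window,
               table_rna = t_rna, table_dna = t_dna)
  class(prof) <- "energy_profile"
  prof
}

# rolling sum of d over `w` consecutive stacks ending at i; NA if any stack NA
roll_sum_right <- function(d, w) {
  n <- length(d)
  isna <- is.na(d)
  cs <- cumsum(c(0, ifelse(isna, 0, d)))
  cn <- cumsum(c(0L, as.integer(isna)))
  out <- rep(NA_real_, n)
  i <- w:n
  good <- (cn[i + 1L] - cn[i + 1L - w]) == 0L
  out[i[good]] <- (cs[i + 1L] - cs[i + 1L - w])[good]
  out
}

#' TEC stability of one hybrid window
#'
#' The TEC stability of a window of 8 consecutive bases \code{[a, b]} is the
#' RNA:DNA melting energy of that substring minus its DNA:DNA melting energy.
#' Under the default "internal" convention this equals the sum of the
#' per-stack difference d over stack positions a+1..b.
#'
#' @param a,b 1-based inclusive window bounds on the concatenated coordinate.
#' @param profile An `energy_profile`.
#' @return kJ/mol, or NA if any contributing stack is invalid.
#' @export
tec_stability <- function(a, b, profile) {
  stopifnot(b >= a)
  from <- if (identical(profile$stacks_per_window, "leading")) a else a + 1L
  if (from > b) return(0)
  if (from < 1L || b > length(profile$d)) return(NA_real_)
  s <- profile$d[from:b]
  if (anyNA(s)) return(NA_real_)
  sum(s)
}

#' Per-position delta-TEC track
#'
#' delta-TEC at position i is the TEC stability of the current hybrid window
#' minus that of the window one translocation register away, with the 8-bp
#' hybrid register direction depending on the dataset:
#' \describe{
#'   \item{dst1}{forward-translocating polymerase: current window
#'     \code{[i-10, i-3]} minus prospective window \code{[i-3, i+4]}.}
#'   \item{wt}{backtracking polymerase: current window \code{[i-7, i]} minus
#'     prospective window \code{[i-14, i-7]}.}
#' }
#' Positive delta-TEC means the move is thermodynamically unfavorable, i.e.
#' the position is pause-prone.
#'
#' @param d Per-position stack-energy difference track (e_rna - e_dna).
#' @param mode "dst1" or "wt".
#' @param stacks_per_window Window-sum convention, see [energy_profile()].
#' @return Numeric vector, NA near gene boundaries or invalid stacks.
#' @export
delta_tec_track <- function(d, mode = c("dst1", "wt"),
                            stacks_per_window = c("internal", "leading")) {
  mode <- match.arg(mode)
  stacks_per_window <- match.arg(stacks_per_window)
  n <- length(d)
  w <- if (stacks_per_window == "internal") 7L else 8L
  # window [a,b]: internal -> stacks a+1..b (right edge b); leading -> a..b
  s <- roll_sum_right(d, w)
  shift <- function(x, k) {        # value at i comes from x[i + k]
    out <- rep(NA_real_, n)
    src <- seq_len(n) + k
    ok <- src >= 1L & src <= n
    out[ok] <- x[src[ok]]
    out
  }
  if (mode == "dst1") {
    # current [i-10, i-3] ends at i-3; prospective [i-3, i+4] ends at i+4
    shift(s, -3L) - shift(s, +4L)
  } else {
    # current [i-7, i] ends at i; prospective [i-14, i-7] ends at i-7
    shift(s, 0L) - shift(s, -7L)
  }
}

#' delta-TEC at single positions (reference implementation)
#'
#' Direct window-difference computation used as the readable reference for
#' [delta_tec_track()]; the two agree exactly on valid positions.
#'
#' @param i 1-based position.
#' @param mode "dst1" or "wt".
#' @param profile An `energy_profile`.
#' @return kJ/mol or NA.
#' @export
delta_tec <- function(i, mode = c("dst1", "wt"), profile) {
  mode <- match.arg(mode)
  if (mode == "dst1") {
    cur <- tec_stability(i - 10L, i - 3L, profile)
    pro <- tec_stability(i - 3L, i + 4L, profile)
  } else {
    cur <- tec_stability(i - 7L, i, profile)
    pro <- tec_stability(i - 14L, i - 7L, profile)
  }
  cur - pro
}

#' Mismatch-adjusted delta-TEC track
#'
#' Models a transcriptional error at the penultimate 3' ribonucleobase: for a
#' polymerase whose 3' end sits at position i, the erroneous RNA base occupies
#' position i-1 and forms an internal mismatch with the template. The two
#' stacks flanking the error, assigned to positions i-1 and i, have their
#' RNA:DNA energies replaced by mismatch-table stacks, and delta-TEC is
#' recomputed in whichever window(s) of the chosen mode contain them (both
#' fall in the prospective window for dst1 mode, in the current window for wt
#' mode). The covered mismatch identity is fixed by the template base at i-1
#' (rA.dA, rC.dC, rG.dG or rU.dT).
#'
#' @param tx A `concat_transcriptome`.
#' @param profile An `energy_profile` for `tx`.
#' @param mm_table An `nn_energy_table` of kind "RNA:DNA-mismatch".
#' @param mode "dst1" (default) or "wt".
#' @param adjust "both" (default: both flanking stacks replaced) or "3p"
#'   (only the stack 3' of the error).
#' @return Numeric vector of mismatch-adjusted delta-TEC; NA where the
#'   unadjusted delta-TEC or either flanking stack is invalid.
#' @export
mismatch_adjusted_dtec <- function(tx, profile, mm_table, mode = c("dst1", "wt"),
                                   adjust = c("both", "3p")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  n <- tx$n
  dtec <- if (mode == "dst1") profile$dtec_dst1 else profile$dtec_wt
  out <- rep(NA_real_, n)
  i <- 3:n
  b_site <- tx$bases[i - 1L]                      # coding base at the error site
  b5 <- tx$bases[i - 2L]                          # 5' neighbor
  b3 <- tx$bases[i]                               # 3' neighbor
  ok <- !is.na(dtec[i]) & b_site %in% VALID_BASES &
    b5 %in% VALID_BASES & b3 %in% VALID_BASES &
    tx$gene_id[i] == tx$gene_id[i - 2L]
  ii <- i[ok]
  mm_left <- mm_table$mm5[cbind(b5[ok], b_site[ok])]    # replaces e_rna at i-1
  mm_right <- mm_table$mm3[cbind(b_site[ok], b3[ok])]   # replaces e_rna at i
  delta_left <- mm_left - profile$e_rna[ii - 1L]
  delta_right <- mm_right - profile$e_rna[ii]
  if (adjust == "3p") delta_left <- 0
  total <- delta_left + delta_right
  # dst1: both stacks lie in the subtracted prospective window [i-3, i+4]
  # (stacks i-2..i+4), so destabilization raises delta-TEC.
  # wt: both lie in the current window [i-7, i] (stacks i-6..i), lowering it.
  sign <- if (mode == "dst1") -1 else +1
  out[ii] <- dtec[ii] + sign * total
  out
}
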