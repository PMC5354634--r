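#' Specification for a synthetic NET-seq dataset
#'
#' Collects every knob of the generator with defaults that emulate a
#' yeast-scale NET-seq experiment at desk scale: ~60 genes of ~1.5 kb
#' (about 1e5 transcribed positions), lognormal gene-to-gene expression,
#' Poisson background coverage, pause occurrence log-linear in the dst1
#' delta-TEC, pause spikes 30-fold enriched over background, long-vs-short
#' backtrack class log-linear in delta-TEC, WT pauses offset 0-15 nt upstream
#' of their dst1 parent, and nucleosome centers at ~165 +/- 15 bp spacing,
#' placed independently of pausing (so the nucleosome predictor is planted
#' uninformative).
#'
#' @param seed RNG seed (mandatory; one stream drives the whole dataset).
#' @param n_genes Number of genes.
#' @param gene_length_meanlog,gene_length_sdlog Lognormal gene length (bp).
#' @param gap Intergenic gap (bp).
#' @param gc GC content of the i.i.d. genome.
#' @param expr_meanlog,expr_sdlog Lognormal per-gene expression rate.
#' @param depth Sequencing depth multiplier; background counts are
#'   Poisson(rate * depth) per position.
#' @param alpha,beta Pause model: P(pause at i) = plogis(alpha + beta *
#'   dtec_dst1(i)); beta in 1/(kJ/mol). The default intercept is calibrated so
#'   that, under the realized delta-TEC distribution of the bundled energy
#'   tables (sd ~6.8 kJ/mol), the marginal latent pause rate is ~1.5% -
#'   the sparse-spike regime NET-seq tracks show; see the methods vignette.
#' @param enrichment Pause spike factor E: spike counts add Poisson(E * rate *
#'   depth).
#' @param alpha_b,beta_b Backtrack model: P(long | pause) = plogis(alpha_b +
#'   beta_b * dtec_dst1). Because pauses are themselves delta-TEC-selected
#'   (typical pause delta-TEC ~ +10 kJ/mol under the defaults), the default
#'   intercept is calibrated so the long-backtrack share among pauses is
#'   ~35-40%, the share seen in NET-seq, and the long-fraction curve is not
#'   saturated; see the methods vignette.
#' @param short_offsets,long_offsets Upstream WT offset supports.
#' @param nuc_spacing_mean,nuc_spacing_sd Nucleosome center spacing (bp).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 60L,
                           gene_length_meanlog = log(1500), gene_length_sdlog = 0.25,
                           gap = 200L, gc = 0.40,
                           expr_meanlog = 0, expr_sdlog = 0.75, depth = 2,
                           alpha = -8.5, beta = 0.5, enrichment = 30,
                           alpha_b = -5.4, beta_b = 0.3,
                           short_offsets = 0:1, long_offsets = 2:15,
                           nuc_spacing_mean = 165, nuc_spacing_sd = 15) {
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic genome and gene annotation
#'
#' i.i.d. bases at the requested GC content; genes tiled along two
#' chromosomes with intergenic gaps, alternating strand so both orientations
#' are exercised.
#'
#' @param spec A `synthetic_spec`. The caller controls the RNG stream (see
#'   [generate_dataset()]); this function draws from the current stream.
#' @return List with `genome` (named sequences) and `genes` (BED-style
#'   data.frame).
#' @export
generate_genome <- function(spec) {
  n_genes <- spec$n_genes
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
             T = (1 - spec$gc) / 2)
  lens <- pmax(250L, as.integer(round(
    rlnorm(n_genes, spec$gene_length_meanlog, spec$gene_length_sdlog))))
  chrom_of <- rep(c("chrI", "chrII"), length.out = max(n_genes, 1L))
  genes <- NULL
  genome <- list()
  for (chrom in c("chrI", "chrII")) {
    idx <- which(chrom_of == chrom & seq_len(max(n_genes, 1L)) <= n_genes)
    total <- sum(lens[idx]) + spec$gap * (length(idx) + 1L)
    genome[[chrom]] <- paste(sample(names(probs), max(total, spec$gap),
                                    replace = TRUE, prob = probs), collapse = "")
    at <- spec$gap
    for (k in idx) {
      genes <- rbind(genes, data.frame(
        chrom = chrom, start = at, end = at + lens[k],
        name = sprintf("gene%04d", k), strand = if (k %% 2L) "+" else "-",
        stringsAsFactors = FALSE))
      at <- at + lens[k] + spec$gap
    }
  }
  if (is.null(genes)) {
    genes <- data.frame(chrom = character(), start = integer(), end = integer(),
                        name = character(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  list(genome = genome, genes = genes[order(match(genes$chrom, names(genome)),
                                            genes$start), ])
}

#' Simulate nucleosome centers at roughly regular spacing
#'
#' Centers are laid down per chromosome at cumulative normal(spacing_mean,
#' spacing_sd) intervals, independent of gene content and pausing.
#'
#' @param spec A `synthetic_spec`.
#' @param genome Named list of chromosome sequences.
#' @return Named list of sorted 0-based centers per chromosome.
#' @export
simulate_nucleosomes <- function(spec, genome) {
  out <- list()
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    n_max <- ceiling(len / max(spec$nuc_spacing_mean - 5 * spec$nuc_spacing_sd, 1)) + 2L
    gaps <- rnorm(n_max, spec$nuc_spacing_mean, spec$nuc_spacing_sd)
    centers <- as.integer(round(cumsum(gaps)))
    centers <- centers[centers >= 0L & centers < len]
    out[[chrom]] <- sort(unique(centers))
  }
  out
}

#' Simulate WT and dst1 NET-seq coverage with planted truth
#'
#' Initial (dst1) pauses occur independently per position with probability
#' plogis(alpha + beta * dtec_dst1). Background coverage is Poisson(rate *
#' depth) per position; pause positions receive an additional Poisson(E *
#' rate * depth) spike. Each pause is long with probability plogis(alpha_b +
#' beta_b * dtec_dst1); its WT (backtracked/cleaved) partner is planted
#' uniformly 2-15 nt upstream for long, 0-1 nt for short, truncated so the
#' partner stays in the gene. WT coverage is fresh background plus spikes at
#' the partner positions.
#'
#' @param spec A `synthetic_spec`.
#' @param tx A `concat_transcriptome` built from [generate_genome()] output.
#' @param profile An `energy_profile` for `tx`.
#' @return List with `wt` and `dst1` coverage tracks, `truth` (data.frame:
#'   dst1_position, class, wt_offset, wt_position, dtec), and `rates`
#'   (per-gene expression rates).
#' @export
simulate_netseq <- function(spec, tx, profile) {
  n <- tx$n
  g <- tx$genes
  rates <- rlnorm(nrow(g), spec$expr_meanlog, spec$expr_sdlog)
  lambda <- rates[tx$gene_id] * spec$depth
  dtec <- profile$dtec_dst1
  p_pause <- ifelse(is.na(dtec), 0, plogis(spec$alpha + spec$beta * dtec))
  is_pause <- rbinom(n, 1L, p_pause) == 1L
  pause_pos <- which(is_pause)

  dst1 <- rpois(n, lambda)
  dst1[pause_pos] <- dst1[pause_pos] +
    rpois(length(pause_pos), spec$enrichment * lambda[pause_pos])

  p_long <- plogis(spec$alpha_b + spec$beta_b * dtec[pause_pos])
  is_long <- rbinom(length(pause_pos), 1L, p_long) == 1L
  offset <- integer(length(pause_pos))
  offset[is_long] <- sample(spec$long_offsets, sum(is_long), replace = TRUE)
  offset[!is_long] <- sample(spec$short_offsets, sum(!is_long), replace = TRUE)
  # keep the WT partner inside the parent gene; the planted class is read off
  # the realized offset so truth classes always match truth offsets
  gene_start <- g$offset[tx$gene_id[pause_pos]] + 1L
  offset <- pmin(offset, pause_pos - gene_start)
  offset <- pmax(offset, 0L)
  is_long <- offset >= min(spec$long_offsets)
  wt_pos <- pause_pos - offset

  wt <- rpois(n, lambda)
  wt[wt_pos] <- wt[wt_pos] + rpois(length(wt_pos), spec$enrichment * lambda[wt_pos])

  attr(wt, "strain") <- "WT"
  attr(dst1, "strain") <- "dst1"
  truth <- data.frame(dst1_position = pause_pos,
                      class = ifelse(is_long, "long", "short"),
                      wt_offset = offset, wt_position = wt_pos,
                      dtec = dtec[pause_pos])
  list(wt = wt, dst1 = dst1, truth = truth, rates = rates)
}

#' Generate a complete synthetic dataset
#'
#' Seeds a single RNG stream from `spec$seed`, then generates the genome,
#' gene set, energy profile, nucleosome centers, and the WT/dst1 coverage
#' tracks with truth tables. Optionally writes everything in standard formats
#' (FASTA, BED6, per-strand bedGraph, nucleosome TSV, truth TSV) to `dir`.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Optional output directory.
#' @param temperature Passed to [energy_profile()].
#' @return List: spec, genome, genes, tx, profile, nucleosomes, wt, dst1,
#'   truth, rates.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL,
                             temperature = 303) {
  set.seed(spec$seed)
  gg <- generate_genome(spec)
  tx <- build_concatenated_transcriptome(gg$genome, gg$genes)
  profile <- energy_profile(tx, temperature = temperature)
  nucs <- simulate_nucleosomes(spec, gg$genome)
  sim <- simulate_netseq(spec, tx, profile)
  out <- c(list(spec = spec, genome = gg$genome, genes = gg$genes, tx = tx,
                profile = profile, nucleosomes = nucs), sim)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(gg$genome, file.path(dir, "genome.fa"))
    write_bed_genes(gg$genes, file.path(dir, "genes.bed"))
    write_bedgraph(sim$wt, tx, file.path(dir, "wt_plus.bedgraph"),
                   file.path(dir, "wt_minus.bedgraph"))
    write_bedgraph(sim$dst1, tx, file.path(dir, "dst1_plus.bedgraph"),
                   file.path(dir, "dst1_minus.bedgraph"))
    write_nucleosome_table(nucs, file.path(dir, "nucleosomes.tsv"))
    data.table::fwrite(sim$truth, file.path(dir, "truth_pauses.tsv"), sep = "\t")
    data.table::fwrite(data.frame(gene = gg$genes$name, rate = sim$rates),
                       file.path(dir, "truth_expression.tsv"), sep = "\t")
  }
  out
}
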