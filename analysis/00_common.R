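# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the tecpause package: run them in order from the repository
# root, e.g.  Rscript analysis/01_simulate.R
suppressPackageStartupMessages(library(tecpause))

ANALYSIS_SEED <- 2024L
DATA_DIR <- "results/data"
OUT_DIR <- "results/analysis"
FIG_DIR <- "results/figures"

for (d in c(DATA_DIR, OUT_DIR, FIG_DIR)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}

# every script rebuilds the transcriptome and energy profile from the files
# script 01 wrote, so the full chain of io readers is exercised
load_dataset <- function() {
  need <- file.path(DATA_DIR, "genome.fa")
  if (!file.exists(need)) stop("run analysis/01_simulate.R first")
  genome <- read_fasta(file.path(DATA_DIR, "genome.fa"))
  genes <- read_bed_genes(file.path(DATA_DIR, "genes.bed"))
  tx <- build_concatenated_transcriptome(genome, genes)
  list(
    tx = tx,
    profile = energy_profile(tx),
    wt = read_bedgraph(file.path(DATA_DIR, "wt_plus.bedgraph"), tx, "+", "WT") +
      read_bedgraph(file.path(DATA_DIR, "wt_minus.bedgraph"), tx, "-", "WT"),
    dst1 = read_bedgraph(file.path(DATA_DIR, "dst1_plus.bedgraph"), tx, "+", "dst1") +
      read_bedgraph(file.path(DATA_DIR, "dst1_minus.bedgraph"), tx, "-", "dst1"),
    nucleosomes = read_nucleosome_table(file.path(DATA_DIR, "nucleosomes.tsv")),
    truth = utils::read.delim(file.path(DATA_DIR, "truth_pauses.tsv"))
  )
}
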