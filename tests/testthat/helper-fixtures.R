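# shared fixtures: tiny transcriptomes built in code, plus a memoised default
# synthetic dataset so the slower suites reuse one generation

.fixture_cache <- new.env(parent = emptyenv())

# one plus-strand and one minus-strand gene over a random genome
toy_transcriptome <- function(seed = 42, len_plus = 400L, len_minus = 300L,
                              gap = 50L) {
  set.seed(seed)
  n <- gap + len_plus + gap + len_minus + gap
  chr <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  genome <- list(chrT = chr)
  genes <- data.frame(
    chrom = "chrT",
    start = c(gap, gap + len_plus + gap),
    end = c(gap + len_plus, gap + len_plus + gap + len_minus),
    name = c("gplus", "gminus"),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  list(genome = genome, genes = genes,
       tx = build_concatenated_transcriptome(genome, genes))
}

# transcriptome from an explicit single plus-strand gene sequence
seq_transcriptome <- function(seq, name = "g1") {
  genome <- list(chrS = seq)
  genes <- data.frame(chrom = "chrS", start = 0L, end = nchar(seq),
                      name = name, strand = "+", stringsAsFactors = FALSE)
  build_concatenated_transcriptome(genome, genes)
}

default_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    .fixture_cache$ds <- generate_dataset(synthetic_spec(seed = 101))
  }
  .fixture_cache$ds
}

# independent hand-summed duplex energy straight from the shipped TSV
nn_table_raw <- function(file) {
  path <- system.file("extdata", file, package = "tecpause")
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  e <- -(tab$dH_kcal_mol - 303 * tab$dS_cal_mol_K / 1000) * 4.184
  names(e) <- gsub("U", "T", tab$dinucleotide)
  e
}

oracle_duplex_energy <- function(seq, entries) {
  b <- strsplit(seq, "")[[1]]
  if (length(b) < 2) return(0)
  tot <- 0
  for (k in 2:length(b)) tot <- tot + entries[[paste0(b[k - 1], b[k])]]
  tot
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# pairwise Mann-Whitney AUC with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# identity "mismatch" table: mismatch stacks equal the matched RNA:DNA stacks
identity_mismatch_table <- function(temperature = 303) {
  rna <- build_energy_table("RNA:DNA", temperature)
  b <- c("A", "C", "G", "T")
  mm5 <- matrix(NA_real_, 4, 4, dimnames = list(b, b))
  mm3 <- mm5
  for (x in b) for (s in b) {
    mm5[x, s] <- rna$entries[[paste0(x, s)]]
    mm3[s, x] <- rna$entries[[paste0(s, x)]]
  }
  structure(list(kind = "RNA:DNA-mismatch", temperature = temperature,
                 mm5 = mm5, mm3 = mm3), class = "nn_energy_table")
}
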