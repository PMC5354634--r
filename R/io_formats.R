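#' @importFrom data.table fread fwrite
#' @importFrom stats rnorm rpois rbinom runif rlnorm sd plogis qlogis
#' @importFrom utils head tail
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Read a FASTA file
#'
#' Reads a genome FASTA into a named list of upper-case sequences. Record ids
#' are the token before the first whitespace in each header.
#'
#' @param path Path to a FASTA file with sequences over A/C/G/T/N.
#' @return Named list of single sequence strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw strings: DNAStringSet would silently drop non-IUPAC letters,
  # and the contract is to report them
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(names(set), function(x) strsplit(x, "\\s+")[[1]][1], "")
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", names(seqs)[nchar(seqs) == 0L][1])
  }
  for (nm in names(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[nm]])
    if (bad > 0) {
      stop("non-IUPAC character in record '", nm, "' at position ", bad)
    }
  }
  as.list(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named list or character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene intervals from BED
#'
#' BED6 (or BED4+) with 0-based half-open genomic coordinates. Returns a
#' data.frame with 0-based `start`, exclusive `end`, and `strand` in +/-.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
read_bed_genes <- function(path) {
  bed <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(bed) < 4) stop("gene BED needs at least 4 columns (chrom,start,end,name)")
  strand <- if (ncol(bed) >= 6) bed[[6]] else rep("+", nrow(bed))
  genes <- data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
                      end = as.integer(bed[[3]]), name = as.character(bed[[4]]),
                      strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(genes$start >= genes$end)) stop("gene interval with start >= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  genes
}

#' Write gene intervals to BED6
#' @param genes data.frame as returned by [read_bed_genes()].
#' @param path Output path.
#' @export
write_bed_genes <- function(genes, path) {
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$name, 0L, genes$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build the concatenated transcription-oriented transcriptome
#'
#' Concatenates the coding-strand sequence of every gene, in input order, into
#' one coordinate system on which coverage, energies and scores are computed.
#' Minus-strand genes are reverse-complemented so every position reads 5'->3'
#' in the direction of transcription.
#'
#' @param genome Named list of chromosome sequences (see [read_fasta()]).
#' @param genes Gene interval data.frame (see [read_bed_genes()]).
#' @return Object of class `concat_transcriptome`: list with `bases` (character
#'   vector of single bases), `genes` (gene table with concatenated `offset`
#'   and `length`), `n` (total length), and `gene_id` (per-position gene index).
#' @export
build_concatenated_transcriptome <- function(genome, genes) {
  seqs <- character(nrow(genes))
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    chrom <- genome[[g$chrom]]
    if (is.null(chrom)) stop("gene ", g$name, ": chromosome ", g$chrom, " not in genome")
    if (g$start < 0 || g$end > nchar(chrom)) {
      stop("gene ", g$name, " exceeds chromosome bounds")
    }
    s <- substr(chrom, g$start + 1L, g$end)
    if (g$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    seqs[k] <- s
  }
  len <- nchar(seqs)
  offset <- cumsum(c(0L, len[-length(len)]))
  genes2 <- genes
  genes2$offset <- as.integer(offset)
  genes2$length <- as.integer(len)
  bases <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  tx <- list(bases = bases,
             genes = genes2,
             n = length(bases),
             gene_id = rep(seq_len(nrow(genes2)), len))
  class(tx) <- "concat_transcriptome"
  tx
}

#' @export
print.concat_transcriptome <- function(x, ...) {
  cat("concat_transcriptome:", x$n, "bases over", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Gene index of concatenated positions
#' @param tx A `concat_transcriptome`.
#' @param pos 1-based concatenated positions.
#' @return Integer gene indices (row of `tx$genes`).
#' @export
gene_of <- function(tx, pos) {
  stopifnot(all(pos >= 1L & pos <= tx$n))
  tx$gene_id[pos]
}

#' Map concatenated positions to genomic coordinates
#'
#' @param tx A `concat_transcriptome`.
#' @param pos 1-based concatenated positions.
#' @return data.frame with chrom, gpos (0-based genomic), strand.
#' @export
concat_to_genomic <- function(tx, pos) {
  gid <- gene_of(tx, pos)
  g <- tx$genes[gid, ]
  k <- pos - g$offset            # 1-based offset within gene, transcript orientation
  gpos <- ifelse(g$strand == "+", g$start + k - 1L, g$end - k)
  data.frame(chrom = g$chrom, gpos = as.integer(gpos), strand = g$strand,
             stringsAsFactors = FALSE)
}

#' Map genomic coordinates to concatenated positions
#'
#' Positions outside every gene interval (or on a chromosome with no genes)
#' map to NA. When `strand` is given, only genes on that strand are matched.
#'
#' @param tx A `concat_transcriptome`.
#' @param chrom Chromosome names.
#' @param gpos 0-based genomic positions.
#' @param strand Optional strand filter (+/-), recycled.
#' @return Integer vector of 1-based concatenated positions (NA when unmapped).
#' @export
genomic_to_concat <- function(tx, chrom, gpos, strand = NULL) {
  n <- length(gpos)
  chrom <- rep_len(chrom, n)
  if (!is.null(strand)) strand <- rep_len(strand, n)
  out <- rep(NA_integer_, n)
  for (k in seq_len(nrow(tx$genes))) {
    g <- tx$genes[k, ]
    hit <- chrom == g$chrom & gpos >= g$start & gpos < g$end
    if (!is.null(strand)) hit <- hit & strand == g$strand
    if (!any(hit)) next
    p <- gpos[hit]
    within <- if (g$strand == "+") p - g$start + 1L else g$end - p
    out[hit] <- g$offset + within
  }
  out
}

#' Read a strand-specific bedGraph coverage file onto the transcriptome
#'
#' Four-column bedGraph (chrom, start, end, value; 0-based half-open) holding
#' non-negative single-base 3'-end read counts. Counts are placed on
#' concatenated coordinates; minus-strand genes are mirrored into transcript
#' orientation. Positions outside gene intervals on the file's strand are
#' dropped and tallied in the `dropped` attribute.
#'
#' @param path bedGraph path.
#' @param tx A `concat_transcriptome`.
#' @param strand_of_file "+" or "-": the strand whose reads the file holds.
#' @param strain Strain label stored on the track ("WT", "dst1", or other).
#' @return Integer vector of length `tx$n` with attributes `strain` and
#'   `dropped` (count mass outside genes).
#' @export
read_bedgraph <- function(path, tx, strand_of_file, strain = "unknown") {
  stopifnot(strand_of_file %in% c("+", "-"))
  bg <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  counts <- integer(tx$n)
  dropped <- 0
  if (nrow(bg) > 0) {
    if (ncol(bg) < 4) stop("bedGraph needs 4 columns")
    if (any(bg[[4]] < 0)) stop("negative bedGraph value")
    if (any(bg[[3]] <= bg[[2]])) stop("bedGraph interval with end <= start")
    width <- bg[[3]] - bg[[2]]
    chrom <- rep(as.character(bg[[1]]), width)
    gpos <- unlist(lapply(seq_len(nrow(bg)), function(i) seq(bg[i, 2], bg[i, 3] - 1L)))
    val <- rep(bg[[4]], width)
    cpos <- genomic_to_concat(tx, chrom, gpos, strand = strand_of_file)
    ok <- !is.na(cpos)
    dropped <- sum(val[!ok])
    if (anyDuplicated(cpos[ok])) {
      dup <- cpos[ok][duplicated(cpos[ok])]
      v <- val[ok]
      for (d in unique(dup)) {
        vv <- v[cpos[ok] == d]
        if (length(unique(vv)) > 1) stop("overlapping bedGraph intervals with conflicting values")
      }
      # identical duplicates collapse
      keep <- !duplicated(cpos[ok])
      counts[cpos[ok][keep]] <- as.integer(v[keep])
    } else {
      counts[cpos[ok]] <- as.integer(val[ok])
    }
  }
  attr(counts, "strain") <- strain
  attr(counts, "dropped") <- dropped
  counts
}

#' Write a coverage track as one bedGraph per strand
#'
#' Inverse of [read_bedgraph()]: non-zero counts are mapped back to genomic
#' coordinates and written as single-base intervals, split by gene strand.
#'
#' @param counts Coverage track on concatenated coordinates.
#' @param tx A `concat_transcriptome`.
#' @param plus_path,minus_path Output paths for the two strands.
#' @export
write_bedgraph <- function(counts, tx, plus_path, minus_path) {
  nz <- which(counts > 0)
  gen <- if (length(nz)) concat_to_genomic(tx, nz) else
    data.frame(chrom = character(), gpos = integer(), strand = character())
  for (s in c("+", "-")) {
    path <- if (s == "+") plus_path else minus_path
    sel <- gen$strand == s
    out <- data.frame(chrom = gen$chrom[sel], start = gen$gpos[sel],
                      end = gen$gpos[sel] + 1L, value = counts[nz[sel]])
    out <- out[order(out$chrom, out$start), ]
    fwrite(out, path, sep = "\t", col.names = FALSE)
  }
  invisible(c(plus_path, minus_path))
}

#' Read a nucleosome-center table
#'
#' Tab-separated chromosome + center position. Brogaard-style tables are
#' 1-based (the default); set `one_based = FALSE` for 0-based input. Centers
#' are returned 0-based, sorted and unique per chromosome.
#'
#' @param path TSV path (no header by default).
#' @param one_based Whether input positions are 1-based.
#' @param header Whether the file has a header line.
#' @return Named list: chromosome -> sorted integer vector of 0-based centers.
#' @export
read_nucleosome_table <- function(path, one_based = TRUE, header = FALSE) {
  tab <- tryCatch(fread(path, header = header, sep = "\t", data.table = FALSE),
                  error = function(e) stop("unparseable nucleosome table: ", conditionMessage(e)))
  if (ncol(tab) < 2) stop("nucleosome table needs 2 columns (chrom, center)")
  pos <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(pos)) {
    stop("unparseable nucleosome center at line ", which(is.na(pos))[1] + as.integer(header))
  }
  if (one_based) pos <- pos - 1L
  split_pos <- split(pos, as.character(tab[[1]]))
  lapply(split_pos, function(p) sort(unique(p)))
}

#' Write a nucleosome-center table (1-based, Brogaard dialect)
#' @param centers Named list of 0-based centers per chromosome.
#' @param path Output path.
#' @export
write_nucleosome_table <- function(centers, path) {
  out <- data.frame(chrom = rep(names(centers), lengths(centers)),
                    center = unlist(centers, use.names = FALSE) + 1L)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
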