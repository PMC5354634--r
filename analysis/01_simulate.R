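# Generate the synthetic NET-seq dataset every later script analyzes:
# a two-chromosome genome with 60 genes on both strands, WT and dst1
# (TFIIS-deletion) 3'-end coverage with planted, delta-TEC-driven pauses and
# backtracks, and pausing-independent nucleosome centers.
source("analysis/00_common.R")

spec <- synthetic_spec(seed = ANALYSIS_SEED)
ds <- generate_dataset(spec, dir = DATA_DIR)

cat("dataset written to", DATA_DIR, "\n")
cat(sprintf("  transcriptome: %d positions across %d genes\n",
            ds$tx$n, nrow(ds$genes)))
cat(sprintf("  planted dst1 pauses: %d (%.1f%% of positions)\n",
            nrow(ds$truth), 100 * nrow(ds$truth) / ds$tx$n))
cat(sprintf("  planted long backtracks: %.1f%% of pauses\n",
            100 * mean(ds$truth$class == "long")))
cat(sprintf("  nucleosome centers: %d (placed independently of pausing)\n",
            length(unlist(ds$nucleosomes))))
cat(sprintf("  dst1 delta-TEC: mean %.2f, sd %.2f kJ/mol\n",
            mean(ds$profile$dtec_dst1, na.rm = TRUE),
            sd(ds$profile$dtec_dst1, na.rm = TRUE)))
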