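# Call pause sites in both strains as local coverage outliers (counts above
# the local 201-bp mean by 4 SD; 2 and 6 SD reported as sensitivity presets)
# and check the caller against the planted truth.
source("analysis/00_common.R")

ds <- load_dataset()

for (nsd in c(2, 4, 6)) {
  p <- call_pauses(ds$dst1, ds$tx, nsd = nsd)
  cat(sprintf("dst1 pauses at %d SD: %d\n", nsd, length(p$positions)))
}

pauses_dst1 <- call_pauses(ds$dst1, ds$tx)
pauses_wt <- call_pauses(ds$wt, ds$tx)
write_pauses_bed(pauses_dst1, ds$tx, ds$dst1,
                 file.path(OUT_DIR, "pauses_dst1.bed"))
write_pauses_bed(pauses_wt, ds$tx, ds$wt, file.path(OUT_DIR, "pauses_wt.bed"))

recall <- mean(ds$truth$dst1_position %in% pauses_dst1$positions)
precision <- mean(pauses_dst1$positions %in% ds$truth$dst1_position)
cat(sprintf("dst1 caller at 4 SD: recall of planted pauses %.1f%%, precision %.1f%%\n",
            100 * recall, 100 * precision))
cat(sprintf("WT pauses at 4 SD: %d\n", length(pauses_wt$positions)))
cat("pause BED files written to", OUT_DIR, "\n")
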