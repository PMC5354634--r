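# Benchmark four per-position pause predictors by ROC/AUC on the highly
# expressed genes: nucleosome distance, mono- and dinucleotide PWMs trained on
# the called pauses, and the parameter-free delta-TEC energy model. Also fits
# the per-site logistic of pause odds on delta-TEC used later for mismatch
# predictions.
source("analysis/00_common.R")

ds <- load_dataset()
pauses <- call_pauses(ds$dst1, ds$tx)
labels <- logical(ds$tx$n)
labels[pauses$positions] <- TRUE

ef <- expression_filter(ds$dst1, ds$tx)
pos <- ef$positions
cat(sprintf("expression filter: %d of %d genes (%.0f%% of positions) retained\n",
            length(ef$gene_ids), nrow(ds$tx$genes),
            100 * length(pos) / ds$tx$n))

scores <- list(
  nucleosome = fit_pause_probability_by_distance(pauses, ds$nucleosomes,
                                                 ds$tx, pos = pos)$score,
  pwm_mono = score_positions(train_pwm(pauses, ds$tx, alphabet = "mono"),
                             ds$tx)[pos],
  pwm_di = score_positions(train_pwm(pauses, ds$tx, alphabet = "di"),
                           ds$tx)[pos],
  energy = prof_dtec <- ds$profile$dtec_dst1[pos])

roc_tab <- data.frame(
  model = names(scores),
  auc = vapply(scores, function(s) roc_auc(s, labels[pos])$auc, 0))
write.table(roc_tab, file.path(OUT_DIR, "roc_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("AUC by model:\n")
print(roc_tab, row.names = FALSE)

curve <- pause_fraction_by_score(scores$energy, labels[pos], bin_width = 1)
write.table(curve, file.path(OUT_DIR, "pause_fraction_by_dtec.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
fit <- fit_log_odds(scores$energy, labels[pos])
saveRDS(fit, file.path(OUT_DIR, "pause_fit.rds"))
cat(sprintf("pause odds vs delta-TEC: log-odds = %.2f + %.3f x (kJ/mol)\n",
            fit$alpha, fit$beta))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  occ <- curve[curve$n >= 100 & !is.na(curve$odds), ]
  gg <- ggplot(occ, aes(bin, odds)) +
    geom_point() + scale_y_log10() +
    geom_abline(slope = fit$beta / log(10), intercept = fit$alpha / log(10),
                color = "steelblue") +
    labs(x = "delta-TEC (kJ/mol)", y = "odds of pausing",
         title = "Pause odds grow exponentially with delta-TEC") +
    theme_minimal()
  ggsave(file.path(FIG_DIR, "pause_odds_by_dtec.png"), gg,
         width = 6, height = 4, dpi = 150)
}
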