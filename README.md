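# tecpause

Thermodynamic analysis of RNA polymerase II pausing and backtracking from
NET-seq-style 3'-end coverage.

NET-seq reports the genomic position of the nascent-RNA 3' end at single-base
resolution: in a TFIIS-deletion (*dst1*) yeast strain it captures the initial
pause register of a forward-moving polymerase, in wild type the backtracked,
post-cleavage register. `tecpause` asks how much of that pausing is explained
by nucleic-acid thermodynamics alone. For every transcribed position it
computes a parameter-free score from nearest-neighbor melting energies:

* **TEC stability** of an 8-bp window = RNA:DNA hybrid melting energy −
  DNA:DNA duplex melting energy of the same coding-strand sequence
  (stack sums of ΔG = ΔH − T·ΔS at 303 K, SantaLucia 1998 DNA:DNA and
  Sugimoto 1995 RNA:DNA parameters);
* **ΔTEC(i)** = TEC(current hybrid window) − TEC(window one translocation
  register away): `TEC[i−10,i−3] − TEC[i−3,i+4]` for forward movement
  (*dst1*), `TEC[i−7,i] − TEC[i−14,i−7]` for backtracking (WT). Positive
  ΔTEC = translocation is thermodynamically uphill = pause-prone.

Around that score the package provides the full analysis pipeline: standard
format I/O (FASTA, BED, strand-specific bedGraph, nucleosome tables) onto a
concatenated transcription-oriented coordinate system; pause calling as local
4σ coverage outliers (201-bp windows); mono- and dinucleotide position weight
matrices; a nucleosome-distance benchmark predictor; ROC/AUC evaluation with
exact Mann–Whitney tie handling; backtrack classification from paired WT and
*dst1* pause sets (0–1 nt short / 2–15 nt long upstream offsets);
pause-odds-versus-ΔTEC logistic fits; resampling null bands for averaged
profiles; predicted fold changes in pausing and backtracking upon an RNA:DNA
mismatch at the penultimate 3' base; and a seeded synthetic NET-seq generator
with planted, recoverable structure so every stage is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
dataset; each is a thin driver over exported functions.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_pauses.R
Rscript analysis/04_predictors.R
Rscript analysis/05_backtracks.R
```

prints (seed 2024):

```
  transcriptome: 90048 positions across 60 genes
  planted dst1 pauses: 1359 (1.5% of positions)
...
dst1 caller at 4 SD: recall of planted pauses 93.0%, precision 99.1%
...
AUC by model:
      model       auc
 nucleosome 0.5118143
   pwm_mono 0.9557682
     pwm_di 0.9734365
     energy 0.9779247
pause odds vs delta-TEC: log-odds = -8.16 + 0.464 x (kJ/mol)
...
of 1276 dst1 pauses: 66.8% short, 31.3% long, 1.9% excluded
long-backtrack odds vs delta-TEC: log-odds = -4.37 + 0.216 x
long fraction rises with delta-TEC (Spearman rho = 0.96 over 16 bins)
planted classes recovered for 100.0% of 664 unambiguous pauses
```

Read: the 4σ caller recovers planted pauses nearly perfectly; the
parameter-free ΔTEC score ranks pauses essentially optimally on data whose
pausing was generated from ΔTEC (AUC 0.98), the planted-uninformative
nucleosome predictor sits at chance, and the fitted slope of pause log-odds
per kJ/mol (0.46 here, from called pauses; 0.5 planted) is recovered. The
same machinery applied to real genome/coverage inputs is exercised by
`full_run()` with `synthetic = FALSE` and file paths.

In R, the core objects are plain:

```r
library(tecpause)
ds <- generate_dataset(synthetic_spec(seed = 1))
prof <- ds$profile                     # e_rna, e_dna, d, dtec_dst1, dtec_wt
pauses <- call_pauses(ds$dst1, ds$tx)  # pause_set
roc_auc(prof$dtec_dst1, seq_len(ds$tx$n) %in% pauses$positions)
```

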