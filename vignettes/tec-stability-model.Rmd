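---
title: "A thermodynamic model of RNA polymerase II pausing and backtracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thermodynamic model of RNA polymerase II pausing and backtracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecpause)
```

## The model

During elongation, RNA polymerase II holds an RNA:DNA hybrid of roughly 8 bp
inside the transcription bubble while the flanking genomic DNA:DNA duplex is
melted ahead of it and reforms behind it. Because both duplex kinds have
sequence-dependent stabilities, every translocation step trades one set of
basepair stacks for another, and the polymerase should dwell where its current
register is thermodynamically favored over the next one. NET-seq gives the
single-base position of the nascent-RNA 3' end: in a TFIIS-deletion strain
(*dst1*) it reports the initial, pre-backtrack pause register of a
forward-moving polymerase, while in wild type it reports the backtracked,
post-cleavage register of a polymerase that moved upstream.

`tecpause` quantifies this with nearest-neighbor melting energies. For a
window of 8 consecutive coding-strand bases the **TEC stability** is

> TEC = E_melt(RNA:DNA hybrid of the window) − E_melt(DNA:DNA duplex of the window)

with each duplex energy the sum of its dinucleotide stack energies,
E = −(ΔH − T·ΔS) at T = 303 K, expressed as a positive melting free energy in
kJ/mol. The **translocation energy difference** at position *i* is the TEC
stability of the current hybrid window minus that of the window one register
away in the direction of movement:

* forward movement (*dst1* register): ΔTEC(i) = TEC[i−10, i−3] − TEC[i−3, i+4];
* backtracking (WT register): ΔTEC(i) = TEC[i−7, i] − TEC[i−14, i−7].

Positive ΔTEC means the move is thermodynamically uphill, so the position is
pause-prone. The score involves no fitted parameters; only the published
stack energies enter.

### Energy tables

The DNA:DNA stack table is the SantaLucia (1998) unified parameter set
(reverse-complement symmetric, as published); the RNA:DNA table is the
Sugimoto (1995) hybrid set, keyed by the coding strand read as RNA, which is
not strand symmetric. Both ship as plain TSV files of ΔH/ΔS with the free
energy evaluated at the requested temperature, so any temperature can be used
(303 K is the default throughout). Initiation and terminal corrections are
omitted: window *differences* cancel any constant term, and only stacks vary
between registers.

The RNA:DNA *mismatch* stack table covers the four identities with published
internal-mismatch thermodynamics (rA·dA, rC·dC, rG·dG, rU·dT — exactly one
per template base). The shipped file is a clearly labelled synthetic stand-in:
each matched Sugimoto stack destabilized by a fixed per-stack free-energy
penalty (0.4–1.2 kcal/mol depending on identity, inside the range reported
for internal hybrid mismatches). Every contract of the mismatch module holds
for any table; replacing the file with measured trimer-derived stacks changes
numbers, not code.

### Window-sum convention

An 8-base window contains 7 internal stacks; the stack spanning the window's
upstream edge could arguably be counted too. We sum the 7 internal stacks
(`stacks_per_window = "internal"`), because the two *dst1* windows share base
i−3 and then cover consecutive, non-overlapping stacks i−9…i−3 and i−2…i+4
with no gap. The 8-stack alternative is available behind the configuration
switch and changes ΔTEC only by the two edge stacks.

## Pause calling

A position is a pause when its count strictly exceeds the local mean plus
`nsd` local standard deviations in a 201-bp centered window (`nsd` = 4 by
default; 2 and 6 as sensitivity presets). Choices the definition leaves open,
and our defaults:

* the focal base is included in its own window; population (divide-by-n) SD;
* windows truncate at gene boundaries rather than spanning concatenation
  joins (join-spanning windows relate biologically unrelated counts; the
  concatenated behavior is available via `truncate_at_genes = FALSE`);
* zero-variance windows call nothing, so flat regions never produce calls;
* calling is scale-equivariant: multiplying all counts by c > 0 leaves the
  called set unchanged.

## Predictors and evaluation

Four per-position scores are compared by ROC/AUC against the called pauses,
on genes whose read density exceeds the unweighted mean across genes (an
absent pause is only informative where the gene is transcribed):

1. **energy**: ΔTEC in the *dst1* register, no fitting;
2. **mono-PWM** and **di-PWM**: log(frequency/background) weight matrices
   over offsets −10…+5 around the called pauses (dinucleotide symbols start
   at their offset), pseudocount 1, natural log — trained and evaluated
   in-sample, which mirrors the fitted-upper-bound reading of a PWM
   benchmark;
3. **nucleosome distance**: the empirical pause probability as a function of
   the signed distance (transcription-direction aware, 1-bp resolution, up to
   500 bp) to the nearest nucleosome center, with the mean pause probability
   as fallback beyond 500 bp.

AUC is computed by a trapezoid over unique score thresholds, which equals the
Mann–Whitney statistic with half credit for ties; an independent pairwise
implementation and `pROC` serve as oracles in the tests.

The nucleosome lookup is scored **leave-one-out** by default: each position
is scored with its own label removed from its distance-bin tally. At the
scale the method is normally applied (10^7 positions) this is a no-op of
order 1/bin-count, but at the 10^5-position scale used here it removes a
self-labelling bias that would push an uninformative predictor's in-sample
AUC far above 0.5. The plain fit is available with `loo = FALSE`.

The 61-bp running average exists for display only; scores always come from
the raw distance function.

## Backtrack classification

Each *dst1* pause is matched to the nearest WT pause 0–15 nt upstream within
the same gene: offsets 0–1 are no/short backtracks, 2–15 long backtracks,
and pauses with no WT partner in range are excluded. The three classes
partition the pause set exactly. The long-fraction-versus-ΔTEC curve uses
1 kJ/mol bins with per-bin counts; the per-site logistic fit (not the binned
curve) feeds downstream predictions.

## Transcriptional-error discrimination

A transcription error at the penultimate 3' ribonucleobase (position i−1 for
a 3' end at i) replaces the two RNA:DNA stacks flanking i−1 with mismatch
stacks; ΔTEC is recomputed in whichever window contains them (the prospective
window in the *dst1* register, so destabilization raises ΔTEC and promotes
pausing). With logistic fits of pause odds and long-backtrack odds on ΔTEC,
the per-site odds ratio of the mismatched versus matched state is
exp(β·(ΔTEC_mm − ΔTEC)) — independent of the intercepts. Folds are
summarized as the mean per-site odds ratio (median and ratio-of-mean-odds are
also reported, since the choice of summary is a convention), and the combined
pause-and-cleave fold is the mean per-site product.

## The synthetic-data generator

The generator emulates the four inputs of a real analysis — genome FASTA,
gene BED, strand-specific single-base 3'-end bedGraphs for WT and *dst1*, and
a nucleosome-center table — with planted, recoverable structure:

* i.i.d. genome at GC 0.40 (yeast-like), ~60 genes of ~1.5 kb on both strands
  of two chromosomes (~10^5 transcribed positions by default; larger sizes
  are a parameter);
* lognormal gene expression (sdlog 0.75), Poisson background counts at
  depth × rate per position;
* latent pauses Bernoulli per position with
  P(pause) = logistic(α + β·ΔTEC_dst1), β = 0.5 per kJ/mol; pause positions
  receive an extra Poisson spike of 30 × the gene's background rate, large
  enough to clear the 4σ caller with high but not unit probability;
* each pause is a long backtrack with
  P(long) = logistic(α_b + 0.3·ΔTEC_dst1); its WT partner is planted
  uniformly 2–15 nt (long) or 0–1 nt (short) upstream, truncated at the gene
  start, with the truth class recorded from the realized offset;
* nucleosome centers at normal(165, 15) bp spacings, independent of
  everything else, so the nucleosome predictor is uninformative by
  construction.

Two intercepts required calibration against the realized physics. The
bundled tables give ΔTEC a standard deviation near 6.8 kJ/mol, so with
β = 0.5 an intercept of −4 would make ~14% of all positions latent pauses —
an order of magnitude denser than NET-seq pausing, dense enough that spikes
stop being local outliers and the caller collapses. The default α = −8.5
yields a ~1.5% marginal rate, the sparse-spike regime the generator is meant
to emulate. Likewise, pauses are ΔTEC-selected (typical planted-pause ΔTEC
≈ +16 kJ/mol), so the backtrack intercept is set to α_b = −5.4 to give a
~36–40% long share among pauses rather than a saturated curve. Both values
were fixed once, from this reasoning, and are ordinary parameters of
`synthetic_spec()`.

What the generator does **not** emulate: read-level noise (mappability,
sequencing error), clustered or correlated pausing, nascent-RNA secondary
structure, nucleosome-driven pausing, and any kinetic (dwell-time) structure.
Passing tests therefore demonstrate that the pipeline recovers planted
thermodynamic structure from realistic count noise — not that the
thermodynamic model explains real NET-seq data, which requires the real
datasets.

## Numerical choices and degenerate inputs

* Energies are positive melting free energies; kcal→kJ via 4.184; ΔG linear
  in T.
* All window/rolling statistics are cumulative-sum based with exact NA
  propagation; brute-force O(n·w) recomputations back them in the tests at
  10^−9 kJ/mol or tighter.
* Strict inequality at the pause threshold; sd = 0 windows never call.
* Nearest-nucleosome ties resolve toward the downstream center in
  transcription direction; chromosomes without centers score at the fallback.
* PWM pseudocount 1 per cell before normalization; backgrounds from the
  considered genes; positions whose window leaves the gene are masked, never
  imputed.
* Resampling bands draw `n_sites` positions without replacement from all
  valid candidate positions under a caller-supplied seed; 1000 repetitions
  give pointwise p < 10^−3 extremes.
* Logistic fits use `stats::glm` maximum likelihood; non-convergence is an
  error, never a silent fallback.

## Problem sizes

The default dataset is ~10^5 transcribed positions; the test suite's
parameter-recovery battery uses five replicates of ~5 × 10^5 positions, and
resampling checks use 1000 repetitions. These sizes keep every check
well-powered (slope recovery to a few percent, AUC standard errors below
0.01) while the whole suite runs in minutes on one core.

## Known limitations

* The hybrid length is fixed at 8 bp; variable-length hybrids are not
  modeled.
* Salt/Mg corrections, dangling ends and loop terms are omitted (only stack
  terms enter, and register differences cancel constants).
* Mismatch coverage is limited to the four identities with published
  internal-mismatch data, and the shipped mismatch stacks are synthetic
  stand-ins (see above).
* On synthetic data generated from ΔTEC itself, the energy score is by
  construction the optimal ranking, so PWM predictors cannot beat it there;
  on real data the PWM absorbs sequence effects the energy model lacks, and
  the ordering reverses. Comparisons on synthetic data validate machinery,
  not the relative merit of predictors on real transcriptomes.
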