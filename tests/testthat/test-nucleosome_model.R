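test_that("signed nearest-nucleosome distances follow transcription direction", {
  genome <- list(cz = paste(rep("A", 500), collapse = ""))
  genes <- data.frame(chrom = "cz", start = 0L, end = 500L, name = "g",
                      strand = "+", stringsAsFactors = FALSE)
  tx <- build_concatenated_transcriptome(genome, genes)
  centers <- list(cz = c(100L, 300L))
  expect_equal(distance_to_nearest(tx, centers, 101L), 0)   # at the center
  # position 210 (0-based genomic 210): nearer to 300, which lies ahead -> -90
  expect_equal(distance_to_nearest(tx, centers, 211L), -90)
  expect_equal(distance_to_nearest(tx, centers, 151L), 50)
  # equidistant between 100 and 300 -> tie toward the downstream center
  expect_equal(distance_to_nearest(tx, centers, 201L), -100)
  expect_equal(distance_to_nearest(tx, list(), 10L), Inf)

  # on a minus-strand gene the sign flips with transcription direction
  genes_m <- transform(genes, strand = "-")
  txm <- build_concatenated_transcriptome(genome, genes_m)
  # concatenated position 1 is genomic 499; transcribing toward 0, the
  # nucleosome at 300 still lies ahead -> upstream of it, -199
  expect_equal(distance_to_nearest(txm, centers, 1L), -199)
  # concatenated position 500 is genomic 0; the polymerase has passed the
  # nucleosome at 100 -> downstream, +100
  expect_equal(distance_to_nearest(txm, centers, 500L), 100)
})

test_that("distances match a brute-force linear scan on both strands", {
  fx <- toy_transcriptome(seed = 61)
  set.seed(5)
  centers <- list(chrT = sort(sample(0:800, 12)))
  pos <- sample(fx$tx$n, 1000, replace = TRUE)
  got <- distance_to_nearest(fx$tx, centers, pos)
  gen <- concat_to_genomic(fx$tx, pos)
  for (k in seq_along(pos)) {
    dd <- gen$gpos[k] - centers$chrT
    best <- min(abs(dd))
    cand <- dd[abs(dd) == best]
    # ties resolve toward the downstream center in transcription direction
    signed <- if (gen$strand[k] == "+") min(cand) else -max(cand)
    expect_equal(got[k], signed)
  }
})

test_that("pause probability by distance reproduces planted lookups and fallback", {
  genome <- list(cz = paste(rep("A", 2000), collapse = ""))
  genes <- data.frame(chrom = "cz", start = 0L, end = 2000L, name = "g",
                      strand = "+", stringsAsFactors = FALSE)
  tx <- build_concatenated_transcriptome(genome, genes)
  centers <- list(cz = c(500L, 700L))
  pauses <- c(501L, 701L)          # exactly at the centers
  ns <- fit_pause_probability_by_distance(pauses, centers, tx, loo = FALSE)
  expect_equal(unname(ns$lookup[["0"]]), 1)
  expect_true(all(ns$lookup[names(ns$lookup) != "0"] == 0))
  expect_true(all(ns$score >= 0 & ns$score <= 1))
  expect_equal(ns$fallback, length(pauses) / tx$n)
  # positions beyond max_dist take the fallback
  far <- which(abs(distance_to_nearest(tx, centers)) > 500)
  expect_true(length(far) > 0)
  expect_true(all(ns$score[far] == ns$fallback))

  # lookup equals brute per-distance tallies on random pauses
  set.seed(30)
  pauses2 <- sample(tx$n, 80)
  ns2 <- fit_pause_probability_by_distance(pauses2, centers, tx, loo = FALSE)
  d <- distance_to_nearest(tx, centers)
  lab <- seq_len(tx$n) %in% pauses2
  in_range <- abs(d) <= 500
  for (key in sample(names(ns2$lookup), 25)) {
    sel <- in_range & d == as.numeric(key)
    expect_equal(unname(ns2$lookup[[key]]), mean(lab[sel]))
  }
})

test_that("leave-one-out scoring removes self-labelling and stays near the
           plain fit in aggregate", {
  ds <- default_dataset()
  pauses <- ds$truth$dst1_position
  nuc <- fit_pause_probability_by_distance(pauses, ds$nucleosomes, ds$tx)
  plain <- fit_pause_probability_by_distance(pauses, ds$nucleosomes, ds$tx,
                                             loo = FALSE)
  expect_identical(nuc$lookup, plain$lookup)
  expect_equal(mean(nuc$score), mean(plain$score), tolerance = 1e-3)
})

test_that("nucleosome score is uninformative for nucleosome-independent pausing", {
  # the leave-one-out lookup is unbiased, but bin-tied scores leave an AUC
  # sampling sd near 0.01 per dataset, so the chance-level check averages a
  # small seed battery (a plain in-sample fit sits at ~0.65 on the same data)
  auc_for <- function(ds) {
    labels <- logical(ds$tx$n)
    labels[ds$truth$dst1_position] <- TRUE
    ns <- fit_pause_probability_by_distance(ds$truth$dst1_position,
                                            ds$nucleosomes, ds$tx)
    roc_auc(ns$score, labels)$auc
  }
  aucs <- c(auc_for(default_dataset()),
            vapply(c(202, 303), function(s) {
              auc_for(generate_dataset(synthetic_spec(seed = s)))
            }, 0))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("display smoothing is an exact running mean", {
  expect_equal(smooth_profile(rep(3, 50), 61), rep(3, 50))
  x <- rnorm(40)
  expect_equal(smooth_profile(x, 1), x)
  expect_error(smooth_profile(x, 10), "odd")
  sm <- smooth_profile(x, 7)
  for (i in seq_along(x)) {
    expect_equal(sm[i], mean(x[max(1, i - 3):min(40, i + 3)]), tolerance = 1e-12)
  }
})
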