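test_that("ROC handles perfect, antiperfect and constant scores", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0.0)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "positive")
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("trapezoid AUC equals the Mann-Whitney pairwise statistic with ties", {
  set.seed(19)
  for (k in 1:100) {
    n <- sample(10:500, 1)
    scores <- sample(rnorm(25), n, replace = TRUE)   # heavy ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(roc_auc(scores, labels)$auc + roc_auc(-scores, labels)$auc, 1,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(300)
  labels <- runif(300) < plogis(scores)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("pause fraction bins tally exactly and respect the odds contract", {
  set.seed(3)
  scores <- rnorm(500, 0, 4)
  labels <- runif(500) < 0.3
  curve <- pause_fraction_by_score(scores, labels, bin_width = 2)
  for (r in seq_len(nrow(curve))) {
    sel <- floor(scores / 2) == (curve$bin[r] - 1) / 2
    expect_equal(curve$n[r], sum(sel))
    expect_equal(curve$fraction[r], mean(labels[sel]))
    if (!is.na(curve$odds[r])) {
      expect_equal(curve$odds[r], curve$fraction[r] / (1 - curve$fraction[r]))
    } else {
      expect_true(curve$fraction[r] %in% c(0, 1))
    }
  }
  all_zero <- pause_fraction_by_score(scores, rep(FALSE, 500))
  expect_true(all(all_zero$fraction == 0))
  expect_true(all(is.na(all_zero$odds)))
})

test_that("logistic fit recovers planted parameters and is shift-equivariant", {
  set.seed(41)
  x <- rnorm(2e5, 0, 3)
  y <- runif(2e5) < plogis(-4 + 0.5 * x)
  fit <- fit_log_odds(x, y)
  expect_lt(abs(fit$beta - 0.5) / 0.5, 0.10)

  fit_shift <- fit_log_odds(x + 10, y)
  expect_equal(fit_shift$beta, fit$beta, tolerance = 1e-6)
  expect_equal(fit_shift$alpha, fit$alpha - fit$beta * 10, tolerance = 1e-4)

  # score-independent labels: slope CI covers zero
  y0 <- runif(1e5) < 0.05
  fit0 <- fit_log_odds(rnorm(1e5, 0, 3), y0)
  expect_lt(abs(fit0$beta), 3 * fit0$se_beta + 1e-3)
  expect_error(fit_log_odds(x, rep(TRUE, length(x))), "both classes")
})

test_that("averaged profiles equal brute-force looping over sites", {
  set.seed(15)
  values <- rnorm(2000)
  sites <- sample(100:1900, 30)
  prof <- average_profile(values, sites, halfwidth = 10)
  expect_equal(prof$n_sites, 30L)
  for (j in seq_along(prof$offsets)) {
    expect_equal(prof$mean[j], mean(values[sites + prof$offsets[j]]),
                 tolerance = 1e-12)
  }
  one <- average_profile(values, sites[1], halfwidth = 5)
  expect_equal(one$mean, values[sites[1] + (-5:5)])
  two <- average_profile(values, sites[1:2], halfwidth = 5)
  expect_equal(two$mean, (values[sites[1] + (-5:5)] + values[sites[2] + (-5:5)]) / 2)
  values[sites[3] + 2] <- NA
  expect_equal(average_profile(values, sites, halfwidth = 10)$n_sites, 29L)
})

test_that("running sums use the centered 8-base hybrid window", {
  x <- rnorm(40)
  expect_equal(running_sum(x, 1), x)
  rs <- running_sum(rep(2, 40), 8)
  expect_true(all(rs[5:32] == 16))
  expect_true(all(is.na(rs[1:4])) && is.na(rs[40]))
  rs2 <- running_sum(x, 8)
  for (j in 5:32) expect_equal(rs2[j], sum(x[(j - 4):(j + 3)]), tolerance = 1e-12)
})

test_that("null bands are deterministic under a seed and bracket resamples", {
  set.seed(2)
  values <- rnorm(5000)
  cand <- 50:4950
  b1 <- null_band(values, 40, cand, halfwidth = 10, n_resamples = 50, seed = 9)
  b2 <- null_band(values, 40, cand, halfwidth = 10, n_resamples = 50, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$upper))

  # one resample collapses the band onto that profile
  b3 <- null_band(values, 40, cand, halfwidth = 10, n_resamples = 1, seed = 4)
  expect_equal(b3$lower, b3$upper)
  expect_error(null_band(values, length(cand) + 1, cand, seed = 1), "exceeds")
})

test_that("expression filter keeps genes strictly above mean density", {
  genome <- list(ce = paste(rep("A", 200), collapse = ""))
  genes <- data.frame(chrom = "ce", start = c(0L, 100L), end = c(100L, 200L),
                      name = c("lo", "hi"), strand = "+", stringsAsFactors = FALSE)
  tx <- build_concatenated_transcriptome(genome, genes)
  track <- c(rep(1L, 100), rep(3L, 100))
  ef <- expression_filter(track, tx)
  expect_identical(ef$gene_ids, 2L)
  expect_identical(range(ef$positions), c(101L, 200L))

  expect_warning(ef0 <- expression_filter(rep(2L, 200), tx), "no gene")
  expect_length(ef0$gene_ids, 0L)
})

test_that("retained fraction under lognormal expression matches the analytic
           expectation", {
  # with effect-free coverage the per-gene density estimates the lognormal
  # rate; P(X > E[X]) = 1 - pnorm(sigma/2) for X lognormal(mu, sigma)
  spec <- synthetic_spec(seed = 19, n_genes = 150, beta = 0, enrichment = 0,
                         expr_sdlog = 0.75)
  ds <- generate_dataset(spec)
  ef <- expression_filter(ds$dst1, ds$tx)
  expected <- 1 - pnorm(0.75 / 2)
  se <- sqrt(expected * (1 - expected) / 150)
  expect_lt(abs(length(ef$gene_ids) / 150 - expected), 4 * se + 0.02)
})
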