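test_that("energy tables carry temperature, vary linearly in T, and the DNA table
           is reverse-complement symmetric", {
  tab <- build_energy_table("DNA:DNA")
  expect_equal(tab$temperature, 303)
  expect_length(tab$entries, 16L)

  # dG = dH - T*dS: entries are affine in temperature
  t1 <- build_energy_table("RNA:DNA", 290)$entries
  t2 <- build_energy_table("RNA:DNA", 303)$entries
  t3 <- build_energy_table("RNA:DNA", 316)$entries
  expect_equal(t1 + t3, 2 * t2, tolerance = 1e-12)

  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                 collapse = ""))
  for (key in names(tab$entries)) {
    expect_equal(tab$entries[[key]], tab$entries[[rc(key)]],
                 info = paste("stack", key))
  }
})

test_that("duplex melting energy is the hand-summed stack total", {
  dna <- build_energy_table("DNA:DNA")
  rna <- build_energy_table("RNA:DNA")
  expect_equal(duplex_melting_energy("A", dna), 0)
  expect_equal(duplex_melting_energy("AG", dna), duplex_melting_energy("CT", dna))
  expect_error(duplex_melting_energy("ACGX", dna), "unknown")

  raw_dna <- nn_table_raw("nn_dna_dna_santalucia1998.tsv")
  raw_rna <- nn_table_raw("nn_rna_dna_sugimoto1995.tsv")
  expect_equal(duplex_melting_energy("ACGT", dna),
               raw_dna[["AC"]] + raw_dna[["CG"]] + raw_dna[["GT"]])
  set.seed(31)
  for (k in 1:50) {
    s <- random_seq(sample(2:20, 1))
    expect_equal(duplex_melting_energy(s, dna), oracle_duplex_energy(s, raw_dna))
    expect_equal(duplex_melting_energy(s, rna), oracle_duplex_energy(s, raw_rna))
  }
})

test_that("stack-energy additivity holds across arbitrary splits", {
  dna <- build_energy_table("DNA:DNA")
  set.seed(8)
  for (k in 1:20) {
    s <- random_seq(sample(5:30, 1))
    cut <- sample(2:(nchar(s) - 1), 1)
    s1 <- substr(s, 1, cut)
    s2 <- substr(s, cut, nchar(s))     # shares one base; junction stack counted once
    expect_equal(duplex_melting_energy(s, dna),
                 duplex_melting_energy(s1, dna) + duplex_melting_energy(s2, dna))
  }
})

test_that("per-position energies mask gene starts and follow the 3'-assignment", {
  tx <- seq_transcriptome("AAAA")
  dna <- build_energy_table("DNA:DNA")
  e <- per_position_energies(tx, dna)
  expect_true(is.na(e[1]))
  expect_equal(e[2:4], rep(dna$entries[["AA"]], 3))

  # first base of EVERY gene is invalid, and N masks both adjacent stacks
  genome <- list(c1 = "ACGTACGTNACG")
  genes <- data.frame(chrom = "c1", start = c(0L, 6L), end = c(6L, 12L),
                      name = c("a", "b"), strand = "+", stringsAsFactors = FALSE)
  tx2 <- build_concatenated_transcriptome(genome, genes)
  e2 <- per_position_energies(tx2, dna)
  expect_true(all(is.na(e2[c(1, 7)])))      # gene starts
  expect_true(all(is.na(e2[c(9, 10)])))     # stacks touching the N at pos 9
  expect_false(anyNA(e2[c(2:6, 8, 11:12)]))
})

test_that("TEC stability equals RNA-minus-DNA substring energies", {
  fx <- toy_transcriptome(seed = 77)
  prof <- energy_profile(fx$tx)
  rna <- build_energy_table("RNA:DNA")
  dna <- build_energy_table("DNA:DNA")
  set.seed(12)
  for (k in 1:25) {
    a <- sample(2:(fx$tx$n - 8), 1)
    b <- a + 7L
    sub <- paste(fx$tx$bases[a:b], collapse = "")
    expected <- duplex_melting_energy(sub, rna) - duplex_melting_energy(sub, dna)
    got <- tec_stability(a, b, prof)
    if (!is.na(got)) expect_equal(got, expected, tolerance = 1e-9)
  }
  # homopolymer window: 7 identical stacks
  txa <- seq_transcriptome(strrep("A", 20))
  profa <- energy_profile(txa)
  expect_equal(tec_stability(5, 12, profa),
               7 * (rna$entries[["AA"]] - dna$entries[["AA"]]))
})

test_that("delta-TEC matches the brute-force window difference in both modes", {
  fx <- toy_transcriptome(seed = 13)
  tx <- fx$tx
  prof <- energy_profile(tx)
  rna <- build_energy_table("RNA:DNA")
  dna <- build_energy_table("DNA:DNA")
  sub_d <- function(a, b) {
    s <- paste(tx$bases[a:b], collapse = "")
    duplex_melting_energy(s, rna) - duplex_melting_energy(s, dna)
  }
  set.seed(4)
  probe <- sample(20:(tx$n - 20), 200)
  for (i in probe) {
    expected_dst1 <- sub_d(i - 10, i - 3) - sub_d(i - 3, i + 4)
    expected_wt <- sub_d(i - 7, i) - sub_d(i - 14, i - 7)
    if (!is.na(prof$dtec_dst1[i])) {
      expect_equal(prof$dtec_dst1[i], expected_dst1, tolerance = 1e-9)
      expect_equal(delta_tec(i, "dst1", prof), expected_dst1, tolerance = 1e-9)
    }
    if (!is.na(prof$dtec_wt[i])) {
      expect_equal(prof$dtec_wt[i], expected_wt, tolerance = 1e-9)
      expect_equal(delta_tec(i, "wt", prof), expected_wt, tolerance = 1e-9)
    }
  }
  # homopolymer: both windows identical, delta-TEC is exactly zero
  profa <- energy_profile(seq_transcriptome(strrep("G", 40)))
  expect_equal(max(abs(profa$dtec_dst1), na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(max(abs(profa$dtec_wt), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("delta-TEC is translation covariant", {
  set.seed(55)
  core <- random_seq(120)
  pad <- strrep("T", 10)
  p1 <- energy_profile(seq_transcriptome(paste0(core, pad)))
  p2 <- energy_profile(seq_transcriptome(paste0(pad, core, pad)))
  v1 <- p1$dtec_dst1[15:100]
  v2 <- p2$dtec_dst1[15:100 + 10L]
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("mismatch adjustment reduces to the matched profile for an identity
           table and recomputes exactly for the real one", {
  fx <- toy_transcriptome(seed = 99)
  tx <- fx$tx
  prof <- energy_profile(tx)
  id_tab <- identity_mismatch_table()
  mm_id <- mismatch_adjusted_dtec(tx, prof, id_tab, mode = "dst1")
  ok <- !is.na(mm_id) & !is.na(prof$dtec_dst1)
  expect_equal(mm_id[ok], prof$dtec_dst1[ok], tolerance = 1e-12)

  mm_tab <- build_energy_table("RNA:DNA-mismatch")
  # the shipped table destabilizes every stack, so dst1 delta-TEC never drops
  mm <- mismatch_adjusted_dtec(tx, prof, mm_tab, mode = "dst1")
  ok <- !is.na(mm)
  expect_true(all(mm[ok] >= prof$dtec_dst1[ok] - 1e-12))

  # brute-force recomputation at random sites: substitute the two stacks
  # flanking the error base at i-1 and redo the window difference by hand
  set.seed(2)
  rna_e <- prof$e_rna
  for (i in sample(which(ok), 50)) {
    e_adj <- rna_e
    e_adj[i - 1L] <- mm_tab$mm5[tx$bases[i - 2L], tx$bases[i - 1L]]
    e_adj[i] <- mm_tab$mm3[tx$bases[i - 1L], tx$bases[i]]
    d_adj <- e_adj - prof$e_dna
    cur <- sum(d_adj[(i - 9):(i - 3)])
    pro <- sum(d_adj[(i - 2):(i + 4)])
    expect_equal(mm[i], cur - pro, tolerance = 1e-9)
  }

  # wt mode: the affected stacks sit in the current window instead
  mm_wt <- mismatch_adjusted_dtec(tx, prof, mm_tab, mode = "wt")
  j <- which(!is.na(mm_wt))[25]
  e_adj <- rna_e
  e_adj[j - 1L] <- mm_tab$mm5[tx$bases[j - 2L], tx$bases[j - 1L]]
  e_adj[j] <- mm_tab$mm3[tx$bases[j - 1L], tx$bases[j]]
  d_adj <- e_adj - prof$e_dna
  expect_equal(mm_wt[j], sum(d_adj[(j - 6):j]) - sum(d_adj[(j - 13):(j - 7)]),
               tolerance = 1e-9)
})
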