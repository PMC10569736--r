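test_that("degeneracy classification counts synonymous single-base neighbours", {
  expect_equal(classify_degeneracy("GGG"), c(0L, 0L, 4L))
  expect_equal(classify_degeneracy("ATG"), c(0L, 0L, 0L))  # Met has no synonym
  expect_equal(classify_degeneracy("TTA"), c(2L, 0L, 2L))  # Leu: 1st and 3rd pos twofold
  expect_equal(classify_degeneracy("ATA"), c(0L, 0L, 2L))  # Ile third pos (2 synonyms) is twofold
  expect_error(classify_degeneracy("TAA"), "stop codon")
  expect_error(classify_degeneracy("ANG"), "ambiguous")
  ## every sense codon has classes summing to 3 positions
  tabs <- phagehost:::.codon_tables()
  expect_true(all(rowSums(tabs$sites) == 3))
})

test_that("pathway-averaged difference counts match brute-force enumeration", {
  ## exhaustive check over every 2- and 3-difference sense-codon pair is the
  ## acceptance surface; here spot-check a representative set incl. pairs with
  ## stop-blocked pathways
  tabs <- phagehost:::.codon_tables()
  n <- length(tabs$codons)
  pairs <- list(c("GGA", "GGG"), c("TTA", "CTC"), c("TGT", "TAC"),
                c("TGG", "TAT"),  # one of the two pathways passes through TAG
                c("AAA", "CCC"), c("TCA", "TTG"))
  for (p in pairs) {
    o <- oracle_pathway_counts(p[1], p[2])
    row <- (match(p[1], tabs$codons) - 1L) * n + match(p[2], tabs$codons)
    expect_equal(unname(tabs$diff$S[row, ]), unname(o$S), tolerance = 1e-12,
                 label = paste("S", p[1], p[2]))
    expect_equal(unname(tabs$diff$V[row, ]), unname(o$V), tolerance = 1e-12,
                 label = paste("V", p[1], p[2]))
  }
  ## symmetry of the difference tables in the two codons
  set.seed(1)
  for (k in 1:50) {
    ij <- sample(n, 2)
    expect_equal(tabs$diff$S[(ij[1] - 1) * n + ij[2], ],
                 tabs$diff$S[(ij[2] - 1) * n + ij[1], ], tolerance = 1e-12)
    expect_equal(tabs$diff$V[(ij[1] - 1) * n + ij[2], ],
                 tabs$diff$V[(ij[2] - 1) * n + ij[1], ], tolerance = 1e-12)
  }
})

test_that("pairwise estimates reproduce hand-computed values", {
  ## identical sequences
  p0 <- pairwise_kaks("ATGGGAGGA", "ATGGGAGGA")
  expect_equal(p0$Ka, 0)
  expect_equal(p0$Ks, 0)
  expect_true(p0$valid)
  ## 10 identical codons except one fourfold-site transition GGA <-> GGG:
  ## L4 = 10, one transition at a fourfold site, K2P gives
  ## Ks = 3 * L4 * A4 / (3 * L4) with A4 = -log(1 - 2/10)/2
  a <- paste(rep("GGA", 10), collapse = "")
  b <- paste(c(rep("GGA", 9), "GGG"), collapse = "")
  p <- pairwise_kaks(a, b)
  expect_equal(p$Ka, 0)
  expect_equal(p$Ks, -0.5 * log(1 - 2 * (1 / 10)), tolerance = 1e-12)
  expect_equal(unname(p$sites), c(20, 0, 10))
  ## symmetry in the argument order
  p_rev <- pairwise_kaks(b, a)
  expect_equal(p_rev$Ks, p$Ks)
  expect_equal(p_rev$Ka, p$Ka)
  ## gapped codons are dropped pairwise and never give negative site counts
  pg <- pairwise_kaks("ATG---GGA", "ATGAAAGGA")
  expect_equal(pg$n_codons_compared, 2)
  expect_true(all(pg$sites >= 0))
})

test_that("site counts total three per compared codon", {
  aln <- sim_codon_alignment(sim_config(seed = 3, n_sequences = 4, n_codons = 40))
  p <- pairwise_kaks(aln$sequences[1], aln$sequences[2])
  expect_equal(sum(p$sites), 3 * p$n_codons_compared)
})

test_that("codon alignments are validated", {
  expect_error(codon_alignment(c(a = "ATGC", b = "ATGC")), "divisible by 3")
  expect_error(codon_alignment(c(a = "ATGTAA", b = "ATGAAA")), "stop codon")
  expect_error(codon_alignment(c(a = "ATGNNN", b = "ATGAAA")), "ambiguous")
  expect_error(codon_alignment(c(a = "ATGAAA")), "at least 2")
  ## gapped codons are tolerated and marked missing
  aln <- codon_alignment(c(a = "ATG---", b = "ATGAAA"))
  expect_true(is.na(aln$codon_idx[1, 2]))
})

test_that("the neutrality z-test behaves under purifying and degenerate inputs", {
  ## identical sequences carry no information
  expect_error(codon_ztest(codon_alignment(c(a = "ATGGGAGAT", b = "ATGGGAGAT")),
                           alternative = "two_sided", seed = 1),
               "degenerate|untestable")
  ## alternative direction is an explicit argument
  aln <- sim_codon_alignment(sim_config(seed = 4, n_sequences = 6, n_codons = 120,
                                        omega = 0.2))
  expect_error(codon_ztest(aln, seed = 1), "alternative")
  zt <- codon_ztest(aln, alternative = "dN_lt_dS", seed = 11)
  expect_lt(zt$mean_dN, zt$mean_dS)
  expect_lt(zt$p_value, 0.05)
  expect_lt(zt$z_statistic, 0)
  ## reproducibility under a fixed seed
  zt2 <- codon_ztest(aln, alternative = "dN_lt_dS", seed = 11)
  expect_identical(zt$z_statistic, zt2$z_statistic)
  expect_identical(zt$p_value, zt2$p_value)
  ## the three alternatives are consistent transformations of one z
  za <- codon_ztest(aln, alternative = "dN_gt_dS", seed = 11)
  zb <- codon_ztest(aln, alternative = "two_sided", seed = 11)
  expect_equal(za$p_value, 1 - zt$p_value)
  expect_equal(zb$p_value, 2 * min(zt$p_value, za$p_value))
})
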