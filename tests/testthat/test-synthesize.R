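test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 7, n_sequences = 4, n_codons = 60)
  expect_identical(sim_codon_alignment(cfg)$sequences,
                   sim_codon_alignment(cfg)$sequences)
  cfg2 <- sim_config(seed = 7, congruence_mode = "independent")
  s1 <- sim_cophylo_system(cfg2)
  s2 <- sim_cophylo_system(cfg2)
  expect_identical(s1$host_d, s2$host_d)
  expect_identical(s1$links, s2$links)
  expect_identical(sim_contig_table(sim_config(seed = 7)),
                   sim_contig_table(sim_config(seed = 7)))
})

test_that("codon simulation respects its rate parameters", {
  ## zero branch length: all tips identical to each other
  cfg <- sim_config(seed = 1, n_sequences = 5, n_codons = 50, branch_length = 0)
  aln <- sim_codon_alignment(cfg)
  expect_length(unique(aln$sequences), 1L)
  ## no stop codons ever appear in frame (codon_alignment would reject them)
  cfg2 <- sim_config(seed = 2, n_sequences = 10, n_codons = 200, branch_length = 0.5)
  expect_s3_class(sim_codon_alignment(cfg2), "codon_alignment")
  ## true omega is recorded
  expect_equal(attr(sim_codon_alignment(sim_config(seed = 3, omega = 0.2,
                                                   n_sequences = 3, n_codons = 30)),
                    "omega"), 0.2)
  ## purifying simulations depress dN relative to dS
  aln_pur <- sim_codon_alignment(sim_config(seed = 4, omega = 0.2, n_sequences = 8,
                                            n_codons = 400))
  zt <- codon_ztest(aln_pur, alternative = "dN_lt_dS", seed = 4)
  expect_lt(zt$dN_dS_ratio, 0.5)
  expect_error(sim_codon_alignment(sim_config(seed = 1, n_sequences = 1)), "config error")
})

test_that("transition probability matrices are valid stochastic matrices", {
  P <- phagehost:::.codon_pmatrix(0.5, 2, 0.2)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_equal(dim(P), c(61, 61))
})

test_that("cophylogeny systems carry the requested congruence structure", {
  ## congruent, no noise: identical matrices under one-to-one links
  cfg <- sim_config(seed = 5, n_hosts = 6, n_parasites = 6,
                    congruence_mode = "congruent")
  sys <- sim_cophylo_system(cfg)
  expect_equal(unname(sys$host_d), unname(sys$parasite_d))
  expect_true(all(rowSums(sys$links) == 1))
  expect_equal(sum(sys$links), 6)
  ## noisy mode perturbs but preserves validity
  cfgn <- sim_config(seed = 5, n_hosts = 6, n_parasites = 6,
                     congruence_mode = "noisy", noise_sd = 0.05)
  sysn <- sim_cophylo_system(cfgn)
  expect_false(identical(unname(sysn$parasite_d), unname(sysn$host_d)))
  expect_true(all(sysn$parasite_d >= 0))
  expect_equal(sysn$parasite_d, t(sysn$parasite_d))
  ## congruent mode requires matched sizes
  expect_error(sim_cophylo_system(sim_config(seed = 1, n_hosts = 5, n_parasites = 4,
                                             congruence_mode = "congruent")),
               "config error")
})

test_that("capsid measurement simulation matches its sampling distribution", {
  ## sd = 0 reproduces the true value exactly
  m0 <- sim_capsid_measurements(94, 0, 5, seed = 1)
  expect_equal(m0$diameter_nm, 94)
  ## means concentrate around the truth: |mean - 94| < 3 * 3/sqrt(5) in ~99 % of seeds
  means <- vapply(1:200, function(s) sim_capsid_measurements(94, 3, 5, seed = s)$diameter_nm,
                  numeric(1))
  expect_gt(mean(abs(means - 94) <= 3 * 3 / sqrt(5)), 0.97)
  ## reported SD is consistent with the generating sd at large n
  big <- sim_capsid_measurements(94, 3, 2000, seed = 9)
  expect_equal(big$diameter_sd_nm, 3, tolerance = 0.34)
})

test_that("contig tables plant one recoverable answer among single-violation decoys", {
  cfg <- sim_config(seed = 12, n_samples = 10)
  tab <- sim_contig_table(cfg)
  truth <- attr(tab, "truth")
  expect_length(truth, 10)
  sel <- select_complete_genomes(tab)
  expect_identical(sel[names(truth)], truth)
  ## each decoy violates at most one criterion
  for (s in names(truth)) {
    rows <- tab[tab$sample_id == s & tab$contig_id != truth[[s]], ]
    viol <- (rows$length <= 90000) + (!rows$viral) + (rows$completeness != "complete")
    expect_true(all(viol <= 1))
  }
})

test_that("config validation rejects impossible rates", {
  expect_error(sim_config(omega = 0), "config error")
  expect_error(sim_config(branch_length = -1), "config error")
  expect_error(sim_config(congruence_mode = "sideways"))
})
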