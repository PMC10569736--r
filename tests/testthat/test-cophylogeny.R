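test_that("alignment distances count mismatches over pairwise-complete columns", {
  ## identical sequences
  expect_equal(msa_distance(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))["a", "b"], 0)
  ## 2 mismatches over 10 ungapped columns
  expect_equal(msa_distance(c(a = "ACGTACGTAC", b = "ACGTACGTTT"))["a", "b"], 0.2)
  ## 1 mismatch over 7 comparable columns (pairwise deletion)
  d <- msa_distance(c(a = "ACGTACGT--", b = "ACGAAC-TAC"))
  expect_equal(d["a", "b"], 1 / 7)
  ## 2 mismatches over 8 comparable columns (2 gapped)
  d2 <- msa_distance(c(a = "AC--ACGTAC", b = "ACGTACGTTT"))
  expect_equal(d2["a", "b"], 0.25)
  ## Jukes-Cantor transform
  dj <- msa_distance(c(a = "ACGTACGTAC", b = "ACGTACGTTT"), model = "jukes_cantor")
  expect_equal(dj["a", "b"], -0.75 * log(1 - 4 * 0.2 / 3))
  ## no comparable columns
  expect_error(msa_distance(c(a = "----AAAA", b = "CCCC----")), "undefined distance")
})

test_that("Cailliez correction finds the minimal Euclidifying constant", {
  ## points on a line are already Euclidean
  dl <- as.matrix(dist(cbind(c(0, 1, 3, 7))))
  dimnames(dl) <- list(letters[1:4], letters[1:4])
  expect_equal(cailliez_correction(dl)$constant, 0)
  ## a triangle-inequality-violating matrix needs a positive constant ...
  dn <- matrix(1, 4, 4); diag(dn) <- 0
  dn[1, 2] <- dn[2, 1] <- 3
  dimnames(dn) <- list(letters[1:4], letters[1:4])
  cc <- cailliez_correction(dn)
  expect_gt(cc$constant, 0)
  ## ... after which all PCoA eigenvalues are non-negative (to tolerance)
  expect_gt(min(eigen(phagehost:::.gower_center(-0.5 * cc$distances^2),
                      symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  ## and the constant is minimal: slightly less leaves a negative eigenvalue
  dm <- dn + (cc$constant - 1e-3); diag(dm) <- 0
  expect_lt(min(eigen(phagehost:::.gower_center(-0.5 * dm^2),
                      symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  ## invariance to label permutation
  perm <- c(3, 1, 4, 2)
  expect_equal(cailliez_correction(dn[perm, perm])$constant, cc$constant)
})

test_that("principal coordinates reproduce known configurations", {
  ## single object: zero-dimensional ordination
  d1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(ncol(pcoa(d1)$coordinates), 0)
  ## equilateral triangle: two equal positive eigenvalues of 1/2
  dt <- matrix(1, 3, 3); diag(dt) <- 0
  dimnames(dt) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(dt)
  expect_equal(sort(ord$eigenvalues[1:2]), c(0.5, 0.5))
  ## distances are recovered from coordinates for a Euclidean input
  set.seed(42)
  pts <- matrix(rnorm(24), 8, 3)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(letters[1:8], letters[1:8])
  ord <- pcoa(d)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-9)
  ## eigenvalues agree with the reference implementation
  ref <- ape::pcoa(d)
  expect_equal(ord$eigenvalues[1:3], ref$values$Eigenvalues[1:3], tolerance = 1e-8)
})

test_that("the global congruence statistic matches the reference implementation", {
  sys <- sim_cophylo_system(sim_config(seed = 9, n_hosts = 7, n_parasites = 6,
                                       congruence_mode = "independent"))
  mine <- parafit_global(sys$host_d, sys$parasite_d, sys$links,
                         n_permutations = 9, seed = 1)
  ref <- ape::parafit(sys$host_d, sys$parasite_d, sys$links, nperm = 9,
                      correction = "cailliez", silent = TRUE)
  expect_equal(mine$statistic, ref$ParaFitGlobal, tolerance = 1e-6)
})

test_that("the permutation test is reproducible and label-order invariant", {
  sys <- sim_cophylo_system(sim_config(seed = 5, congruence_mode = "independent"))
  r1 <- parafit_global(sys$host_d, sys$parasite_d, sys$links, 199, seed = 7)
  r2 <- parafit_global(sys$host_d, sys$parasite_d, sys$links, 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$permuted, r2$permuted)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  ## reordering hosts and parasites consistently leaves the statistic unchanged
  hp <- sample(rownames(sys$host_d)); pp <- sample(rownames(sys$parasite_d))
  r3 <- parafit_global(sys$host_d[hp, hp], sys$parasite_d[pp, pp],
                       sys$links[pp, hp], 199, seed = 7)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-9)
})

test_that("association and distance inputs are validated", {
  sys <- sim_cophylo_system(sim_config(seed = 1, congruence_mode = "independent"))
  bad_links <- sys$links
  bad_links[1, ] <- 0
  expect_error(parafit_global(sys$host_d, sys$parasite_d, bad_links, 9, seed = 1),
               "at least one host")
  unlabelled <- sys$links
  colnames(unlabelled)[1] <- "NOPE"
  expect_error(parafit_global(sys$host_d, sys$parasite_d, unlabelled, 9, seed = 1),
               "labelling error")
  expect_error(parafit_global(sys$host_d, sys$parasite_d, sys$links, 9),
               "seed")
  asym <- sys$host_d
  asym[1, 2] <- asym[1, 2] + 1
  expect_error(parafit_global(asym, sys$parasite_d, sys$links, 9, seed = 1),
               "symmetric")
})

test_that("small-system permutation p converges to the exact per-row null", {
  sys <- sim_cophylo_system(sim_config(seed = 5, n_hosts = 4, n_parasites = 4,
                                       congruence_mode = "congruent"))
  ex <- parafit_exact(sys$host_d, sys$parasite_d, sys$links)
  expect_equal(sum(ex$weights), 1, tolerance = 1e-12)
  pf <- parafit_global(sys$host_d, sys$parasite_d, sys$links, 20000, seed = 3)
  mc_sd <- sqrt(ex$p_value * (1 - ex$p_value) / 20000)
  expect_lt(abs(pf$p_value - ex$p_value), 4 * mc_sd + 1e-4)
})
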