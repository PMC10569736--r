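# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: codon alignments evolved at a controlled dN/dS,
# congruent vs independent host/parasite distance systems, noised capsid
# measurements, and contig tables with a planted correct answer.

#' Simulation configuration
#'
#' Bundles the sizes and rates shared by the generators. Defaults describe the
#' package's reference study conditions: 10 sequences of 300 codons evolved on
#' a star tree with branch length 0.1 substitutions/site under an unbiased
#' mutation spectrum (kappa = 1, so the degeneracy-class weighting of the
#' dN/dS estimator is exact), six hosts and six parasites for cophylogeny
#' simulations, and ~100 kb phage genomes.
#'
#' @param seed Integer seed; fixed seed implies identical outputs.
#' @param n_sequences,n_codons Codon-alignment dimensions.
#' @param n_hosts,n_parasites Cophylogeny system sizes.
#' @param n_samples Number of samples for contig tables.
#' @param genome_length Genome length in bp.
#' @param omega dN/dS ratio of the codon process (> 0).
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param branch_length Expected substitutions per site from root to each tip.
#' @param mutation_rate Per-base substitution rate for genome mutagenesis.
#' @param congruence_mode `"congruent"`, `"independent"` or `"noisy"`
#'   (congruent plus Gaussian distance noise).
#' @param noise_sd SD of the Gaussian noise added in `"noisy"` mode.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_sequences = 10L, n_codons = 300L,
                       n_hosts = 6L, n_parasites = 6L, n_samples = 5L,
                       genome_length = 100000L,
                       omega = 1, kappa = 1, branch_length = 0.1,
                       mutation_rate = 0.02,
                       congruence_mode = c("independent", "congruent", "noisy"),
                       noise_sd = 0.02) {
  congruence_mode <- match.arg(congruence_mode)
  if (omega <= 0) stop("config error: 'omega' must be > 0")
  if (kappa < 0 || branch_length < 0 || mutation_rate < 0 || noise_sd < 0) {
    stop("config error: rates must be >= 0")
  }
  structure(list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
                 n_codons = as.integer(n_codons), n_hosts = as.integer(n_hosts),
                 n_parasites = as.integer(n_parasites), n_samples = as.integer(n_samples),
                 genome_length = as.integer(genome_length),
                 omega = omega, kappa = kappa, branch_length = branch_length,
                 mutation_rate = mutation_rate,
                 congruence_mode = congruence_mode, noise_sd = noise_sd),
            class = "sim_config")
}

# codon-substitution transition probability matrix over the 61 sense codons
# after time t (expected substitutions per nucleotide site), computed by
# uniformization; single-nucleotide changes only, transitions scaled by kappa,
# nonsynonymous changes by omega, rates normalised so the uniform-average
# substitution rate per codon is 3 (i.e. 1 per site)
.codon_pmatrix <- function(omega, kappa, t) {
  key <- paste(omega, kappa, t, sep = "_")
  cached <- .phagehost_cache$pmatrix[[key]]
  if (!is.null(cached)) return(cached)
  tabs <- .codon_tables()
  n <- length(tabs$codons)
  chars <- do.call(rbind, strsplit(tabs$codons, "", fixed = TRUE))
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dp <- which(chars[i, ] != chars[j, ])
      if (length(dp) != 1L) next
      r <- 1
      if (.is_transition(chars[i, dp], chars[j, dp])) r <- r * kappa
      if (tabs$aa[i] != tabs$aa[j]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  nu <- mean(-diag(Q))
  Q <- Q * 3 / nu
  ## uniformization: P(t) = sum_k Pois(k; Lambda t) M^k, M = I + Q/Lambda
  lambda <- max(-diag(Q))
  if (lambda == 0 || t == 0) {
    P <- diag(n)
  } else {
    M <- diag(n) + Q / lambda
    mu <- lambda * t
    term <- diag(n)
    P <- exp(-mu) * term
    w <- exp(-mu)
    k <- 0
    while (w > 1e-14 || k < mu) {
      k <- k + 1
      term <- term %*% M
      w <- w * mu / k
      P <- P + w * term
      if (k > mu + 40 * sqrt(mu + 1)) break
    }
    P <- P / rowSums(P)
  }
  if (is.null(.phagehost_cache$pmatrix)) .phagehost_cache$pmatrix <- list()
  .phagehost_cache$pmatrix[[key]] <- P
  P
}

#' Simulate a codon alignment at a controlled dN/dS ratio
#'
#' Evolves sense codons on a star tree: an ancestral sequence is drawn
#' uniformly over the 61 sense codons and each tip evolves independently for
#' `branch_length` expected substitutions per site under a continuous-time
#' Markov process on sense codons in which single-nucleotide transitions are
#' scaled by `kappa` and nonsynonymous changes by `omega`. Stop codons are
#' never generated. The true omega is recorded in the `"omega"` attribute.
#'
#' @param cfg A [sim_config()].
#' @return A [codon_alignment()] with attributes `omega`, `kappa`,
#'   `branch_length`.
#' @examples
#' aln <- sim_codon_alignment(sim_config(seed = 1, n_sequences = 4, n_codons = 50))
#' aln
#' @export
sim_codon_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_sequences < 2L || cfg$n_codons < 1L) {
    stop("config error: need >= 2 sequences and >= 1 codon")
  }
  tabs <- .codon_tables()
  P <- .codon_pmatrix(cfg$omega, cfg$kappa, cfg$branch_length)
  set.seed(cfg$seed)
  anc <- sample.int(length(tabs$codons), cfg$n_codons, replace = TRUE)
  seqs <- character(cfg$n_sequences)
  for (s in seq_len(cfg$n_sequences)) {
    tip <- integer(cfg$n_codons)
    for (state in unique(anc)) {
      pos <- which(anc == state)
      tip[pos] <- sample.int(length(tabs$codons), length(pos), replace = TRUE,
                             prob = P[state, ])
    }
    seqs[s] <- paste(tabs$codons[tip], collapse = "")
  }
  names(seqs) <- sprintf("tip%02d", seq_len(cfg$n_sequences))
  aln <- codon_alignment(seqs)
  attr(aln, "omega") <- cfg$omega
  attr(aln, "kappa") <- cfg$kappa
  attr(aln, "branch_length") <- cfg$branch_length
  aln
}

#' Simulate a host-parasite distance system
#'
#' In `"congruent"` mode the parasite distance matrix equals the host matrix
#' (optionally with symmetric Gaussian noise in `"noisy"` mode, floored at
#' zero) and links are one-to-one, so the system carries a perfect
#' cophylogenetic signal. In `"independent"` mode host and parasite matrices
#' come from independent random configurations (Euclidean distances among
#' Gaussian points in five dimensions) and each parasite is linked to one
#' uniformly chosen host, so there is no signal. Congruent modes require
#' `n_parasites == n_hosts`.
#'
#' @param cfg A [sim_config()].
#' @return List with `host_d`, `parasite_d` (labelled distance matrices) and
#'   `links` (binary parasite x host matrix).
#' @export
sim_cophylo_system <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_hosts < 3L || cfg$n_parasites < 3L) {
    stop("config error: need >= 3 hosts and >= 3 parasites")
  }
  set.seed(cfg$seed)
  hosts <- sprintf("H%02d", seq_len(cfg$n_hosts))
  parasites <- sprintf("P%02d", seq_len(cfg$n_parasites))
  host_d <- .random_point_distances(cfg$n_hosts, hosts)
  if (cfg$congruence_mode %in% c("congruent", "noisy")) {
    if (cfg$n_parasites != cfg$n_hosts) {
      stop("config error: congruent systems need n_parasites == n_hosts")
    }
    parasite_d <- host_d
    dimnames(parasite_d) <- list(parasites, parasites)
    if (cfg$congruence_mode == "noisy" && cfg$noise_sd > 0) {
      n <- nrow(parasite_d)
      noise <- matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
      noise <- (noise + t(noise)) / 2
      parasite_d <- pmax(parasite_d + noise, 0)
      diag(parasite_d) <- 0
    }
    links <- association_matrix(parasites, hosts,
                                parasite_labels = parasites, host_labels = hosts)
  } else {
    parasite_d <- .random_point_distances(cfg$n_parasites, parasites)
    links <- association_matrix(parasites, sample(hosts, cfg$n_parasites, replace = TRUE),
                                parasite_labels = parasites, host_labels = hosts)
  }
  list(host_d = host_d, parasite_d = parasite_d, links = links)
}

.random_point_distances <- function(n, labels, dim = 5L) {
  pts <- matrix(rnorm(n * dim), n, dim)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}

#' Simulate averaged TEM capsid measurements
#'
#' Emulates the measurement protocol in which the reported capsid diameter is
#' the mean of a handful of virions: draws `n` Gaussian diameters and reports
#' their mean and SD rounded to integer nanometres.
#'
#' @param true_diameter True circumscribed diameter (nm).
#' @param sd Per-virion measurement SD (nm).
#' @param n Number of virions averaged.
#' @param seed Integer seed.
#' @param phage_id Identifier for the resulting record.
#' @return A [capsid_measurement()].
#' @export
sim_capsid_measurements <- function(true_diameter, sd, n, seed, phage_id = "sim") {
  if (n < 1) stop("'n' must be >= 1")
  set.seed(as.integer(seed))
  draws <- rnorm(n, true_diameter, sd)
  capsid_measurement(phage_id,
                     diameter_nm = round(mean(draws)),
                     diameter_sd_nm = if (n > 1) round(stats::sd(draws)) else NA_real_,
                     n_virions = n)
}

#' Simulate an assembly contig table with a planted answer
#'
#' For each sample, plants one true complete phage genome (longer than 90 kb,
#' viral, complete, highest coverage) among decoys that each violate exactly
#' one of the selection criteria — too short, non-viral, or not complete (all
#' with *higher* coverage than the truth, so a filter mistake would pick them)
#' — plus one decoy that passes every filter but has lower coverage. The
#' planted truth is recorded in the `"truth"` attribute.
#'
#' @param cfg A [sim_config()]; uses `n_samples`, `genome_length`, `seed`.
#' @return Data frame of contig records with attribute `truth` (named vector
#'   sample_id -> planted contig_id).
#' @export
sim_contig_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- list()
  truth <- character(0)
  for (s in seq_len(cfg$n_samples)) {
    sample_id <- sprintf("S%03d", s)
    true_len <- max(90001, round(cfg$genome_length + rnorm(1, 0, 3000)))
    true_cov <- runif(1, 200, 600)
    hi_cov <- true_cov * runif(3, 1.5, 3)    # tempting decoys: better coverage
    true_id <- sprintf("%s_u1", sample_id)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = c(true_id, sprintf("%s_u%d", sample_id, 2:5)),
      sample_id = sample_id,
      length = c(true_len,
                 round(runif(1, 30000, 85000)),            # too short
                 round(cfg$genome_length * runif(1, 1, 1.2)), # non-viral
                 round(cfg$genome_length * runif(1, 1, 1.2)), # not complete
                 max(90001, round(cfg$genome_length + rnorm(1, 0, 3000)))), # lower coverage
      viral = c(TRUE, TRUE, FALSE, TRUE, TRUE),
      coverage = c(true_cov, hi_cov, true_cov * runif(1, 0.2, 0.8)),
      completeness = c("complete", "complete", "complete", "high", "complete"),
      stringsAsFactors = FALSE
    )
    truth[sample_id] <- true_id
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate a random genome sequence
#'
#' @param length Genome length in bp.
#' @param seed Integer seed.
#' @param gc GC content in \[0, 1\] (default 0.4, Bacteroidota-phage-like).
#' @return A `Biostrings::DNAString`.
#' @export
sim_genome <- function(length, seed, gc = 0.4) {
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Biostrings::DNAString(paste(sample(names(probs), length, replace = TRUE, prob = probs),
                              collapse = ""))
}

#' Apply uniform random substitutions to a genome
#'
#' Substitutes each base independently with probability `rate`, drawing the
#' replacement uniformly from the three alternatives.
#'
#' @param genome `DNAString` or character string.
#' @param rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `Biostrings::DNAString`.
#' @export
mutate_genome <- function(genome, rate, seed) {
  genome <- .as_dna_string(genome, "genome")
  set.seed(as.integer(seed))
  chars <- strsplit(as.character(genome), "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         character(1))
  }
  Biostrings::DNAString(paste(chars, collapse = ""))
}
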