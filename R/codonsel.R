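# Pairwise dN/dS by the Li-Wu-Luo degeneracy-class method and the
# codon-based z-test of strict neutrality with bootstrap variance.

#' Construct an in-frame codon alignment
#'
#' Validates aligned coding sequences: equal lengths divisible by three, at
#' least two sequences, bases in ACGT plus the gap character, and no stop
#' codons in any ungapped codon. Codons containing a gap are treated as missing
#' for that sequence and dropped pairwise in downstream estimates; ambiguity
#' codes are rejected.
#'
#' @param sequences Named character vector of aligned sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return Object of class `codon_alignment` with `ids`, `sequences`,
#'   `codon_idx` (sequences x codons; index into the sense-codon table, NA for
#'   gapped codons) and `length_codons`.
#' @examples
#' codon_alignment(c(s1 = "ATGGGAAAA", s2 = "ATGGGGAAA"))
#' @export
codon_alignment <- function(sequences) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (!is.character(sequences) || length(sequences) < 2L) {
    stop("need at least 2 aligned sequences")
  }
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  if (len %% 3L != 0L) stop("aligned length must be divisible by 3")
  bad <- grepl("[^ACGT-]", sequences)
  if (any(bad)) {
    stop("ambiguous or invalid characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  tabs <- .codon_tables()
  n_codons <- len %/% 3L
  idx <- matrix(NA_integer_, length(sequences), n_codons,
                dimnames = list(names(sequences), NULL))
  for (s in seq_along(sequences)) {
    cods <- substring(sequences[s], 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    gapped <- grepl("-", cods, fixed = TRUE)
    if (any(cods[!gapped] %in% tabs$stop_codons)) {
      stop("stop codon in sequence '", names(sequences)[s], "'")
    }
    idx[s, !gapped] <- match(cods[!gapped], tabs$codons)
  }
  structure(list(ids = names(sequences), sequences = sequences,
                 codon_idx = idx, length_codons = n_codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences x %d codons\n",
              length(x$ids), x$length_codons))
  invisible(x)
}

# per-column 9-row contribution matrix (L0,L2,L4,S0,S2,S4,V0,V2,V4) for one
# sequence pair; columns where either sequence is gapped contribute zero
.pair_contrib <- function(idx_a, idx_b, tabs) {
  n <- length(tabs$codons)
  contrib <- matrix(0, 9, length(idx_a))
  ok <- !is.na(idx_a) & !is.na(idx_b)
  if (!any(ok)) return(contrib)
  ia <- idx_a[ok]; ib <- idx_b[ok]
  contrib[1:3, ok] <- t((tabs$sites[ia, , drop = FALSE] + tabs$sites[ib, , drop = FALSE]) / 2)
  pair_row <- (ia - 1L) * n + ib
  contrib[4:6, ok] <- t(tabs$diff$S[pair_row, , drop = FALSE])
  contrib[7:9, ok] <- t(tabs$diff$V[pair_row, , drop = FALSE])
  contrib
}

# Li-Wu-Luo Ks/Ka from aggregated class counts; `counts` is a 9 x B matrix
# (site means L0,L2,L4; transitions S0,S2,S4; transversions V0,V2,V4).
# Returns list(Ks, Ka, valid) of length-B vectors.
.lwl_from_counts <- function(counts) {
  L <- counts[1:3, , drop = FALSE]
  S <- counts[4:6, , drop = FALSE]
  V <- counts[7:9, , drop = FALSE]
  P <- ifelse(L > 0, S / L, 0)
  Q <- ifelse(L > 0, V / L, 0)
  arg_a <- 1 - 2 * P - Q
  arg_b <- 1 - 2 * Q
  saturated_cl <- (L > 0) & (arg_a <= 0 | arg_b <= 0)
  suppressWarnings({
    A <- -0.5 * log(arg_a) + 0.25 * log(arg_b)
    B <- -0.5 * log(arg_b)
  })
  A[L == 0] <- 0; B[L == 0] <- 0
  den_s <- L[2, ] + 3 * L[3, ]
  den_a <- 3 * L[1, ] + 2 * L[2, ]
  Ks <- ifelse(den_s > 0, 3 * (L[2, ] * A[2, ] + L[3, ] * (A[3, ] + B[3, ])) / den_s, NA_real_)
  Ka <- ifelse(den_a > 0, 3 * (L[1, ] * (A[1, ] + B[1, ]) + L[2, ] * B[2, ]) / den_a, NA_real_)
  valid <- !apply(saturated_cl, 2, any) & is.finite(Ks) & is.finite(Ka)
  Ks <- pmax(Ks, 0)
  Ka <- pmax(Ka, 0)
  list(Ks = Ks, Ka = Ka, valid = valid)
}

#' Pairwise dN/dS estimation (Li-Wu-Luo)
#'
#' Estimates synonymous (Ks, i.e. dS) and nonsynonymous (Ka, i.e. dN)
#' substitutions per site between two in-frame coding sequences. Codon
#' positions are classified as nondegenerate, twofold or fourfold; differences
#' at codons differing at several positions are averaged over all minimal
#' mutational pathways that avoid stop codons; transitional and transversional
#' differences are corrected per class with the Kimura two-parameter formulas,
#' and Ks and Ka assembled with the method's class weighting
#' (Ks = 3(L2 A2 + L4(A4+B4))/(L2+3L4), Ka = 3(L0(A0+B0) + L2 B2)/(3L0+2L2)).
#'
#' @param seq_a,seq_b Aligned in-frame sequences (equal length, ACGT and gaps),
#'   or a [codon_alignment()] passed as `seq_a` with `seq_b` an index pair.
#' @return Object of class `pairwise_kaks`: `sites` (mean L0, L2, L4),
#'   `transitions`, `transversions` (per class), `Ks`, `Ka`, `valid` (FALSE
#'   when a required logarithm is undefined, i.e. saturation), and
#'   `n_codons_compared`.
#' @examples
#' pairwise_kaks("ATGGGAGGAGGA", "ATGGGAGGAGGG")
#' @export
pairwise_kaks <- function(seq_a, seq_b) {
  aln <- codon_alignment(c(a = seq_a, b = seq_b))
  tabs <- .codon_tables()
  contrib <- .pair_contrib(aln$codon_idx[1, ], aln$codon_idx[2, ], tabs)
  counts <- matrix(rowSums(contrib), 9, 1)
  est <- .lwl_from_counts(counts)
  structure(list(
    sites = setNames(counts[1:3, 1], c("L0", "L2", "L4")),
    transitions = setNames(counts[4:6, 1], c("S0", "S2", "S4")),
    transversions = setNames(counts[7:9, 1], c("V0", "V2", "V4")),
    Ks = est$Ks[1], Ka = est$Ka[1], valid = est$valid[1],
    n_codons_compared = sum(!is.na(aln$codon_idx[1, ]) & !is.na(aln$codon_idx[2, ]))
  ), class = "pairwise_kaks")
}

#' @export
print.pairwise_kaks <- function(x, digits = 4, ...) {
  cat("Li-Wu-Luo pairwise estimate\n")
  cat(sprintf("  codons compared: %d; sites L0/L2/L4: %s\n",
              x$n_codons_compared, paste(format(x$sites, digits = digits), collapse = "/")))
  if (x$valid) {
    cat(sprintf("  Ka (dN) = %s, Ks (dS) = %s\n",
                format(x$Ka, digits = digits), format(x$Ks, digits = digits)))
  } else {
    cat("  estimate invalid (saturation)\n")
  }
  invisible(x)
}

#' Codon-based z-test of strict neutrality
#'
#' Tests the null hypothesis dN = dS for a codon alignment. dN and dS are the
#' averages of the Li-Wu-Luo pairwise estimates over all valid sequence pairs;
#' the variance of (dN - dS) is estimated by bootstrapping codon columns with
#' replacement (the same resampled columns for every pair), and
#' z = (mean dN - mean dS) / SE is referred to the standard normal with the
#' chosen alternative. The direction of the alternative is an explicit,
#' required argument.
#'
#' @param aln A [codon_alignment()] (or named character vector coerced to one).
#' @param alternative `"dN_gt_dS"` (positive/diversifying selection),
#'   `"dN_lt_dS"` (purifying selection) or `"two_sided"`. No default.
#' @param n_bootstrap Number of bootstrap replicates (default 100).
#' @param seed Integer seed (required; the bootstrap is fully reproducible).
#' @return Object of class `codon_ztest` with `mean_dN`, `mean_dS`,
#'   `dN_dS_ratio`, `z_statistic`, `p_value`, `se`, `alternative`,
#'   `n_bootstrap`, `seed`, `n_pairs_valid`.
#' @examples
#' aln <- sim_codon_alignment(sim_config(seed = 2, n_sequences = 6, n_codons = 150,
#'                                       omega = 0.2))
#' codon_ztest(aln, alternative = "dN_lt_dS", seed = 2)
#' @export
codon_ztest <- function(aln, alternative, n_bootstrap = 100, seed) {
  if (missing(alternative)) {
    stop("'alternative' must be given explicitly: \"dN_gt_dS\", \"dN_lt_dS\" or \"two_sided\"")
  }
  alternative <- match.arg(alternative, c("dN_gt_dS", "dN_lt_dS", "two_sided"))
  if (missing(seed)) stop("'seed' is required for a reproducible bootstrap")
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  if (n_bootstrap < 2) stop("'n_bootstrap' must be >= 2")
  tabs <- .codon_tables()
  n_seq <- nrow(aln$codon_idx)
  n_cod <- aln$length_codons

  pairs <- utils::combn(n_seq, 2)
  contribs <- lapply(seq_len(ncol(pairs)), function(k) {
    .pair_contrib(aln$codon_idx[pairs[1, k], ], aln$codon_idx[pairs[2, k], ], tabs)
  })

  full <- vapply(contribs, rowSums, numeric(9))
  est <- .lwl_from_counts(full)          # one column per pair
  if (!any(est$valid)) stop("untestable: all sequence pairs are saturated or empty")
  mean_dN <- mean(est$Ka[est$valid])
  mean_dS <- mean(est$Ks[est$valid])

  set.seed(as.integer(seed))
  W <- vapply(seq_len(n_bootstrap),
              function(b) tabulate(sample.int(n_cod, n_cod, replace = TRUE), n_cod),
              numeric(n_cod))
  ka_b <- matrix(NA_real_, ncol(pairs), n_bootstrap)
  ks_b <- matrix(NA_real_, ncol(pairs), n_bootstrap)
  for (k in seq_len(ncol(pairs))) {
    bc <- contribs[[k]] %*% W
    eb <- .lwl_from_counts(bc)
    ka_b[k, eb$valid] <- eb$Ka[eb$valid]
    ks_b[k, eb$valid] <- eb$Ks[eb$valid]
  }
  diff_b <- colMeans(ka_b, na.rm = TRUE) - colMeans(ks_b, na.rm = TRUE)
  diff_b <- diff_b[is.finite(diff_b)]
  if (length(diff_b) < 2) stop("untestable: bootstrap produced no valid replicates")
  se <- sd(diff_b)
  if (!is.finite(se) || se == 0) {
    stop("degenerate variance: bootstrap spread of (dN - dS) is zero (no information)")
  }
  z <- (mean_dN - mean_dS) / se
  p <- switch(alternative,
              dN_gt_dS = pnorm(z, lower.tail = FALSE),
              dN_lt_dS = pnorm(z, lower.tail = TRUE),
              two_sided = 2 * pnorm(-abs(z)))
  structure(list(mean_dN = mean_dN, mean_dS = mean_dS,
                 dN_dS_ratio = if (mean_dS > 0) mean_dN / mean_dS else NA_real_,
                 z_statistic = z, p_value = p, se = se,
                 alternative = alternative, n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), n_pairs_valid = sum(est$valid),
                 n_codons = n_cod),
            class = "codon_ztest")
}

#' @export
print.codon_ztest <- function(x, digits = 4, ...) {
  alt_txt <- switch(x$alternative,
                    dN_gt_dS = "dN > dS (diversifying)",
                    dN_lt_dS = "dN < dS (purifying)",
                    two_sided = "dN != dS")
  cat("Codon-based z-test of strict neutrality (dN = dS)\n")
  cat(sprintf("  %d valid pairs, %d codons, %d bootstrap replicates (seed %d)\n",
              x$n_pairs_valid, x$n_codons, x$n_bootstrap, x$seed))
  cat(sprintf("  mean dN = %s, mean dS = %s, dN/dS = %s\n",
              format(x$mean_dN, digits = digits), format(x$mean_dS, digits = digits),
              format(x$dN_dS_ratio, digits = digits)))
  cat(sprintf("  z = %s, p = %s (alternative: %s)\n",
              format(x$z_statistic, digits = digits), format(x$p_value, digits = digits),
              alt_txt))
  invisible(x)
}
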