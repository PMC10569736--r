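# Host-parasite cophylogeny: alignment distances, Cailliez correction,
# principal coordinates, and the ParaFit-style global permutation test.

# validate a labelled symmetric distance matrix; returns the matrix with
# dimnames, symmetrized exactly
.check_distance_matrix <- function(d, what = "distance matrix") {
  if (!is.matrix(d) || !is.numeric(d)) stop(what, " must be a numeric matrix")
  if (nrow(d) != ncol(d)) stop(what, " must be square")
  if (is.null(rownames(d)) && is.null(colnames(d))) {
    rownames(d) <- colnames(d) <- paste0("obj", seq_len(nrow(d)))
  } else if (is.null(rownames(d))) {
    rownames(d) <- colnames(d)
  } else if (is.null(colnames(d))) {
    colnames(d) <- rownames(d)
  }
  if (!identical(rownames(d), colnames(d))) stop(what, " row/column labels differ")
  if (anyNA(d)) stop(what, " contains missing values")
  if (max(abs(d - t(d))) > 1e-8) stop(what, " is not symmetric")
  if (any(diag(d) != 0)) stop(what, " has a non-zero diagonal")
  if (any(d < 0)) stop(what, " has negative entries")
  (d + t(d)) / 2
}

#' Pairwise distances from a nucleotide multiple sequence alignment
#'
#' Computes pairwise distances over pairwise-complete columns (positions where
#' neither sequence carries a gap or ambiguity), as the proportion of differing
#' sites (`"uncorrected"`, the p-distance) or with the Jukes-Cantor correction
#' \eqn{-\frac34 \ln(1 - \frac43 p)}.
#'
#' @param alignment A `Biostrings::DNAStringSet`, named character vector, or
#'   character matrix of equal-length aligned sequences (>= 2).
#' @param model `"uncorrected"` or `"jukes_cantor"`.
#' @return A labelled symmetric distance matrix.
#' @examples
#' msa_distance(c(a = "ACGTACGTAC", b = "ACGTACGTTT"))
#' @export
msa_distance <- function(alignment, model = c("uncorrected", "jukes_cantor")) {
  model <- match.arg(model)
  mat <- .alignment_to_matrix(alignment)
  n <- nrow(mat)
  if (n < 2L) stop("alignment must contain at least 2 sequences")
  ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0L) {
        stop(sprintf("undefined distance: sequences '%s' and '%s' share no comparable columns",
                     rownames(mat)[i], rownames(mat)[j]))
      }
      p <- sum(mat[i, comp] != mat[j, comp]) / ncomp
      if (model == "jukes_cantor") {
        if (p >= 0.75) {
          stop(sprintf("Jukes-Cantor distance undefined (saturation) for '%s' vs '%s' (p = %.3f)",
                       rownames(mat)[i], rownames(mat)[j], p))
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

# coerce alignment-like input to an upper-case character matrix (rows = seqs)
.alignment_to_matrix <- function(alignment) {
  if (inherits(alignment, "XStringSet")) {
    seqs <- as.character(alignment)
  } else if (is.matrix(alignment) && is.character(alignment)) {
    m <- toupper(alignment)
    if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
    return(m)
  } else if (is.character(alignment)) {
    seqs <- alignment
  } else {
    stop("unsupported alignment input")
  }
  if (length(unique(nchar(seqs))) != 1L) stop("aligned sequences must have equal length")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Cailliez correction of a distance matrix
#'
#' Finds the smallest constant \eqn{c \ge 0} such that adding \eqn{c} to every
#' off-diagonal distance yields a matrix embeddable in Euclidean space (no
#' appreciably negative principal-coordinate eigenvalue). The constant is the
#' largest real eigenvalue of the standard 2n x 2n companion matrix built from
#' the Gower-centred forms of \eqn{-d^2/2} and \eqn{-d/2}.
#'
#' @param d Labelled symmetric distance matrix.
#' @return A list with `distances` (corrected matrix) and `constant`.
#' @export
cailliez_correction <- function(d) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  if (n <= 2L) return(list(distances = d, constant = 0))
  delta1 <- .gower_center(-0.5 * d^2)
  delta2 <- .gower_center(-0.5 * d)
  comp <- rbind(cbind(matrix(0, n, n), 2 * delta1),
                cbind(-diag(n), -4 * delta2))
  ev <- eigen(comp, only.values = TRUE)$values
  c_hat <- max(Re(ev))
  if (c_hat < 1e-8) c_hat <- 0
  dc <- d + c_hat
  diag(dc) <- 0
  list(distances = dc, constant = c_hat)
}

.gower_center <- function(m) {
  n <- nrow(m)
  cm <- diag(n) - matrix(1 / n, n, n)
  cm %*% m %*% cm
}

#' Principal coordinates analysis
#'
#' Gower double-centring of \eqn{-d^2/2} followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their eigenvalue;
#' axes with eigenvalues below `tol` times the leading eigenvalue are dropped.
#'
#' @param d Labelled symmetric distance matrix.
#' @param tol Relative eigenvalue tolerance for retaining axes.
#' @return An object of class `pcoa_ordination` with `coordinates`
#'   (objects x axes), `eigenvalues` (all, decreasing), and `labels`.
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  if (n == 1L) {
    return(structure(list(coordinates = matrix(0, 1, 0, dimnames = list(rownames(d), NULL)),
                          eigenvalues = numeric(0), labels = rownames(d)),
                     class = "pcoa_ordination"))
  }
  g <- .gower_center(-0.5 * d^2)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, eigenvalues = e$values, labels = rownames(d)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("Principal coordinates: %d objects, %d retained axes\n",
              length(x$labels), ncol(x$coordinates)))
  if (length(x$eigenvalues)) {
    cat("  leading eigenvalues:", paste(format(head(x$eigenvalues, 5), digits = 4),
                                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a binary host-parasite association matrix
#'
#' @param parasites,hosts Character vectors of equal length: each element pairs
#'   a parasite with one of its hosts.
#' @param parasite_labels,host_labels Optional full label sets fixing row and
#'   column order (defaults to order of first appearance).
#' @return Binary matrix (parasites x hosts) with dimnames.
#' @examples
#' association_matrix(c("p1", "p2"), c("h1", "h1"))
#' @export
association_matrix <- function(parasites, hosts, parasite_labels = unique(parasites),
                               host_labels = unique(hosts)) {
  stopifnot(length(parasites) == length(hosts), length(parasites) > 0)
  if (!all(parasites %in% parasite_labels)) stop("parasite not in 'parasite_labels'")
  if (!all(hosts %in% host_labels)) stop("host not in 'host_labels'")
  a <- matrix(0L, length(parasite_labels), length(host_labels),
              dimnames = list(parasite_labels, host_labels))
  a[cbind(match(parasites, parasite_labels), match(hosts, host_labels))] <- 1L
  a
}

.check_links <- function(links) {
  if (!is.matrix(links)) stop("'links' must be a matrix (parasites x hosts)")
  if (is.null(rownames(links)) || is.null(colnames(links))) {
    stop("'links' must carry parasite row names and host column names")
  }
  if (!all(links %in% c(0, 1))) stop("'links' entries must be 0 or 1")
  if (any(rowSums(links) < 1)) {
    stop("invalid association: every parasite must be linked to at least one host")
  }
  links
}

#' ParaFit-style global test of host-parasite cophylogenetic congruence
#'
#' Tests whether parasites tend to be associated with hosts in a way that
#' mirrors the two phylogenetic distance structures. Both distance matrices are
#' Cailliez-corrected and ordinated by principal coordinates; with host
#' coordinates \eqn{B}, parasite coordinates \eqn{C} and binary link matrix
#' \eqn{A} (parasites x hosts), the global statistic is the sum of squared
#' entries of \eqn{C^t A B}. The null distribution permutes, independently for
#' each parasite (each row of \eqn{A}), the host assignments; the one-tailed
#' upper p-value uses the add-one estimator \eqn{(1 + \#\{perm \ge obs\})/(1 + N)}.
#'
#' @param host_d,parasite_d Labelled symmetric distance matrices. Labels must
#'   cover the link matrix's hosts and parasites.
#' @param links Binary association matrix (parasites x hosts) with dimnames,
#'   e.g. from [association_matrix()]; every parasite needs >= 1 host.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @return Object of class `parafit_global` with `statistic`, `p_value`,
#'   `n_permutations`, `seed`, and the vector of permuted statistics.
#' @examples
#' sys <- sim_cophylo_system(sim_config(seed = 1, n_hosts = 5, n_parasites = 5,
#'                                      congruence_mode = "congruent"))
#' parafit_global(sys$host_d, sys$parasite_d, sys$links, n_permutations = 99, seed = 1)
#' @export
parafit_global <- function(host_d, parasite_d, links, n_permutations = 999, seed) {
  if (missing(seed)) stop("'seed' is required for a reproducible permutation test")
  links <- .check_links(links)
  host_d <- .check_distance_matrix(host_d, "host distance matrix")
  parasite_d <- .check_distance_matrix(parasite_d, "parasite distance matrix")
  if (!all(colnames(links) %in% rownames(host_d))) {
    stop("labelling error: link hosts missing from the host distance matrix")
  }
  if (!all(rownames(links) %in% rownames(parasite_d))) {
    stop("labelling error: link parasites missing from the parasite distance matrix")
  }
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  host_d <- host_d[colnames(links), colnames(links), drop = FALSE]
  parasite_d <- parasite_d[rownames(links), rownames(links), drop = FALSE]

  b <- pcoa(cailliez_correction(host_d)$distances)$coordinates
  c_par <- pcoa(cailliez_correction(parasite_d)$distances)$coordinates

  stat_fun <- function(a) sum((crossprod(c_par, a %*% b))^2)
  observed <- stat_fun(links)

  n_host <- ncol(links)
  set.seed(as.integer(seed))
  perm_stats <- vapply(seq_len(n_permutations), function(r) {
    a_perm <- links
    for (i in seq_len(nrow(links))) {
      a_perm[i, ] <- links[i, sample.int(n_host)]
    }
    stat_fun(a_perm)
  }, numeric(1))
  p <- (1 + sum(perm_stats >= observed - 1e-12)) / (1 + n_permutations)

  structure(list(statistic = observed, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), permuted = perm_stats,
                 n_hosts = n_host, n_parasites = nrow(links)),
            class = "parafit_global")
}

#' @export
print.parafit_global <- function(x, ...) {
  cat("Global host-parasite congruence permutation test\n")
  cat(sprintf("  %d parasites x %d hosts, %d permutations (seed %d)\n",
              x$n_parasites, x$n_hosts, x$n_permutations, x$seed))
  cat(sprintf("  ParaFitGlobal = %s, p = %s\n",
              format(x$statistic, digits = 4), format(x$p_value, digits = 4)))
  invisible(x)
}

#' Exact null distribution of the global congruence statistic (small systems)
#'
#' Enumerates the exact permutation null of [parafit_global()]: independently
#' for each parasite row, host assignments are permuted uniformly; the distinct
#' images of each row are enumerated with their multiplicities and combined
#' over rows. Feasible only for small systems (the product of distinct row
#' images is capped).
#'
#' @inheritParams parafit_global
#' @param max_configs Safety cap on the number of enumerated configurations.
#' @return List with `p_value` (exact probability that a null draw reaches the
#'   observed statistic), `observed`, `statistics` and `weights` of the
#'   enumerated null configurations.
#' @export
parafit_exact <- function(host_d, parasite_d, links, max_configs = 1e6) {
  links <- .check_links(links)
  host_d <- .check_distance_matrix(host_d, "host distance matrix")
  parasite_d <- .check_distance_matrix(parasite_d, "parasite distance matrix")
  host_d <- host_d[colnames(links), colnames(links), drop = FALSE]
  parasite_d <- parasite_d[rownames(links), rownames(links), drop = FALSE]
  b <- pcoa(cailliez_correction(host_d)$distances)$coordinates
  c_par <- pcoa(cailliez_correction(parasite_d)$distances)$coordinates
  observed <- sum((crossprod(c_par, links %*% b))^2)

  n_host <- ncol(links)
  perms <- .all_permutations(n_host)
  ## distinct images of each row under all host permutations, with weights
  row_images <- lapply(seq_len(nrow(links)), function(i) {
    imgs <- t(apply(perms, 1, function(p) links[i, p]))
    key <- apply(imgs, 1, paste, collapse = "")
    tab <- table(key)
    uniq <- imgs[match(names(tab), key), , drop = FALSE]
    list(images = uniq, weights = as.numeric(tab) / nrow(perms))
  })
  n_total <- prod(vapply(row_images, function(r) nrow(r$images), numeric(1)))
  if (n_total > max_configs) stop("exact enumeration too large (", n_total, " configurations)")

  idx <- rep(1L, length(row_images))
  stats <- numeric(n_total)
  weights <- numeric(n_total)
  a <- links
  for (k in seq_len(n_total)) {
    w <- 1
    for (i in seq_along(row_images)) {
      a[i, ] <- row_images[[i]]$images[idx[i], ]
      w <- w * row_images[[i]]$weights[idx[i]]
    }
    stats[k] <- sum((crossprod(c_par, a %*% b))^2)
    weights[k] <- w
    ## advance mixed-radix counter
    for (i in seq_along(idx)) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= nrow(row_images[[i]]$images)) break
      idx[i] <- 1L
    }
  }
  list(p_value = sum(weights[stats >= observed - 1e-12]),
       observed = observed, statistics = stats, weights = weights)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
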