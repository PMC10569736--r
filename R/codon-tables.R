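# Degeneracy-class lookup tables for the Li-Wu-Luo method, built once from the
# standard genetic code and cached for the session.

.BASES <- c("A", "C", "G", "T")

.is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") & b2 %in% c("A", "G")) | (b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}

# Build (and cache) all codon tables:
#   codons      61 sense codons (names)
#   aa          amino acid per sense codon
#   deg         61 x 3 matrix of degeneracy classes (0, 2, 4)
#   sites       61 x 3 matrix of per-codon site counts (L0, L2, L4 columns)
#   diff_S      3721 x 3 matrix: pathway-averaged transitional differences per
#               class for ordered codon pair (i, j) at row (i-1)*61 + j
#   diff_V      idem for transversions
.codon_tables <- function() {
  if (!is.null(.phagehost_cache$codon_tables)) return(.phagehost_cache$codon_tables)
  code <- Biostrings::GENETIC_CODE
  all_codons <- names(code)
  sense <- all_codons[code != "*"]
  aa <- code[sense]
  n <- length(sense)

  codon_chars <- do.call(rbind, strsplit(sense, "", fixed = TRUE))

  ## degeneracy class of each position: number of synonymous single-base changes
  deg <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    for (p in 1:3) {
      alts <- setdiff(.BASES, codon_chars[i, p])
      neigh <- vapply(alts, function(b) {
        cc <- codon_chars[i, ]; cc[p] <- b; paste(cc, collapse = "")
      }, character(1))
      nsyn <- sum(code[neigh] == aa[i])
      deg[i, p] <- if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
    }
  }
  sites <- cbind(L0 = rowSums(deg == 0L), L2 = rowSums(deg == 2L), L4 = rowSums(deg == 4L))
  rownames(deg) <- rownames(sites) <- sense

  tabs <- list(codons = sense, aa = aa, deg = deg, sites = sites,
               stop_codons = all_codons[code == "*"])
  tabs$diff <- .build_pathway_tables(tabs)
  .phagehost_cache$codon_tables <- tabs
  tabs
}

# average per-class transition/transversion difference counts over all minimal
# stop-free mutational pathways, for every ordered sense-codon pair
.build_pathway_tables <- function(tabs) {
  sense <- tabs$codons
  n <- length(sense)
  chars <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  idx_of <- setNames(seq_len(n), sense)
  is_sense <- function(codon) codon %in% sense

  S <- matrix(0, n * n, 3)
  V <- matrix(0, n * n, 3)
  perms_by_k <- list(matrix(1L, 1, 1), .all_permutations(2L), .all_permutations(3L))

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff_pos <- which(chars[i, ] != chars[j, ])
      k <- length(diff_pos)
      row <- (i - 1L) * n + j
      paths <- perms_by_k[[k]]
      acc_s <- matrix(0, 0, 3); acc_v <- matrix(0, 0, 3)
      for (p in seq_len(nrow(paths))) {
        order_pos <- diff_pos[paths[p, ]]
        cur <- chars[i, ]
        step_s <- c(0, 0, 0); step_v <- c(0, 0, 0)
        ok <- TRUE
        for (pos in order_pos) {
          nxt <- cur
          nxt[pos] <- chars[j, pos]
          nxt_codon <- paste(nxt, collapse = "")
          if (!is_sense(nxt_codon)) { ok <- FALSE; break }
          cur_codon <- paste(cur, collapse = "")
          ## split the difference 1/2-1/2 between the site's class in the two codons
          cl <- c(tabs$deg[idx_of[[cur_codon]], pos], tabs$deg[idx_of[[nxt_codon]], pos])
          w <- c(0, 0, 0)
          for (cc in cl) w[match(cc, c(0L, 2L, 4L))] <- w[match(cc, c(0L, 2L, 4L))] + 0.5
          if (.is_transition(cur[pos], nxt[pos])) step_s <- step_s + w else step_v <- step_v + w
          cur <- nxt
        }
        if (ok) {
          acc_s <- rbind(acc_s, step_s)
          acc_v <- rbind(acc_v, step_v)
        }
      }
      if (nrow(acc_s) == 0L) {
        ## no stop-free pathway (does not occur for sense pairs under the
        ## standard code, kept as a guard): fall back to all pathways
        for (p in seq_len(nrow(paths))) {
          order_pos <- diff_pos[paths[p, ]]
          cur <- chars[i, ]
          step_s <- c(0, 0, 0); step_v <- c(0, 0, 0)
          for (pos in order_pos) {
            nxt <- cur
            nxt[pos] <- chars[j, pos]
            cl_cur <- tabs$deg[idx_of[[paste(cur, collapse = "")]], pos]
            nxt_codon <- paste(nxt, collapse = "")
            cl_nxt <- if (is_sense(nxt_codon)) tabs$deg[idx_of[[nxt_codon]], pos] else cl_cur
            w <- c(0, 0, 0)
            for (cc in c(cl_cur, cl_nxt)) w[match(cc, c(0L, 2L, 4L))] <- w[match(cc, c(0L, 2L, 4L))] + 0.5
            if (.is_transition(cur[pos], nxt[pos])) step_s <- step_s + w else step_v <- step_v + w
            cur <- nxt
          }
          acc_s <- rbind(acc_s, step_s)
          acc_v <- rbind(acc_v, step_v)
        }
      }
      S[row, ] <- colMeans(acc_s)
      V[row, ] <- colMeans(acc_v)
    }
  }
  list(S = S, V = V)
}

#' Degeneracy class of each codon position
#'
#' Classifies the three positions of a sense codon by how many of the three
#' possible single-base changes at that position are synonymous under the
#' standard genetic code: none synonymous gives a nondegenerate (0-fold) site,
#' all three a fourfold site, and anything in between a twofold site.
#'
#' @param codon A single sense codon (3 characters, ACGT).
#' @return Integer vector of length 3 with values 0, 2 or 4.
#' @examples
#' classify_degeneracy("GGG")  # 0 0 4
#' classify_degeneracy("ATG")  # 0 0 0  (Met has no synonym)
#' @export
classify_degeneracy <- function(codon) {
  tabs <- .codon_tables()
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("'codon' must be a single 3-letter string")
  }
  if (codon %in% tabs$stop_codons) stop("cannot classify a stop codon: ", codon)
  if (!codon %in% tabs$codons) stop("ambiguous or invalid codon: ", codon)
  unname(tabs$deg[codon, ])
}
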