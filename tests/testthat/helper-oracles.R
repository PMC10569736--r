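# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the hull volume works from vertex coordinates, the
# pathway oracle enumerates mutational orderings explicitly.

# numeric volume of the convex hull of the 12 icosahedron vertices at
# circumradius R, by summing centre-to-face tetrahedra over the 20 faces
# (faces = equilateral vertex triples at the minimal pairwise distance)
icosa_hull_volume <- function(R) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(1, 1, -1, -1), phi * c(1, -1, 1, -1)),
    cbind(c(1, 1, -1, -1), phi * c(1, -1, 1, -1), 0),
    cbind(phi * c(1, -1, 1, -1), 0, c(1, 1, -1, -1))
  )
  v <- v / sqrt(1 + phi^2) * R
  dd <- as.matrix(dist(v))
  edge <- min(dd[dd > 1e-9 * max(R, 1)])
  vol <- 0
  for (i in 1:10) {
    for (j in (i + 1):11) {
      for (k in (j + 1):12) {
        if (abs(dd[i, j] - edge) < 1e-6 * edge &&
            abs(dd[i, k] - edge) < 1e-6 * edge &&
            abs(dd[j, k] - edge) < 1e-6 * edge) {
          vol <- vol + abs(det(rbind(v[i, ], v[j, ], v[k, ]))) / 6
        }
      }
    }
  }
  vol
}

# all orderings of a set of positions, written independently of the package
.orderings <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .orderings(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# brute-force pathway-averaged per-class transition/transversion counts for a
# sense codon pair: walk every ordering of the differing positions, discard
# pathways through stop codons, classify each step's changed site half by its
# class in the source codon and half in the destination codon
oracle_pathway_counts <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  stopifnot(code[[c1]] != "*", code[[c2]] != "*")
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  deg_of <- function(codon, pos) classify_degeneracy(codon)[pos]
  is_ts <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) || (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  acc <- list()
  for (ord in .orderings(diff_pos)) {
    cur <- a
    S <- c(`0` = 0, `2` = 0, `4` = 0)
    V <- S
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      nxt_codon <- paste(nxt, collapse = "")
      if (code[[nxt_codon]] == "*") { blocked <- TRUE; break }
      cur_codon <- paste(cur, collapse = "")
      w <- c(`0` = 0, `2` = 0, `4` = 0)
      for (cl in c(deg_of(cur_codon, pos), deg_of(nxt_codon, pos))) {
        w[as.character(cl)] <- w[as.character(cl)] + 0.5
      }
      if (is_ts(cur[pos], nxt[pos])) S <- S + w else V <- V + w
      cur <- nxt
    }
    if (!blocked) acc[[length(acc) + 1L]] <- rbind(S, V)
  }
  if (length(acc) == 0L) return(NULL)  # fully blocked pair (none exist)
  m <- Reduce(`+`, acc) / length(acc)
  list(S = m[1, ], V = m[2, ])
}

# half-up rounding to two decimals, as used when comparing densities to
# printed values
round2 <- function(x) floor(x * 100 + 0.5) / 100

extfile <- function(...) system.file("extdata", ..., package = "phagehost", mustWork = TRUE)
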