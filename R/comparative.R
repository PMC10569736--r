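# Orthogroup host-exclusivity and duplication filters, fragment-based average
# nucleotide identity, and the ICTV species-demarcation rule.

.check_orthogroup_table <- function(t) {
  if (!is.list(t) || is.null(names(t))) {
    stop("orthogroup table must be a named list (orthogroup -> genome -> genes)")
  }
  t
}

#' Orthogroups whose genes all come from phages of one host
#'
#' Returns the orthogroups whose member genes are found exclusively in genomes
#' mapped to the given host, and that span at least `min_genomes` distinct
#' genomes. This is the filter used to isolate candidate host-interaction genes
#' shared across otherwise unrelated phages infecting the same bacterium.
#'
#' @param table Orthogroup table from [read_orthogroups()]: a named list,
#'   one element per orthogroup, each a named list of gene-id vectors per genome.
#' @param host_map Named character vector mapping genome_id to host_id.
#' @param host Host id to filter on.
#' @param min_genomes Minimum number of distinct member genomes (default 1).
#' @return Character vector of orthogroup ids.
#' @export
host_specific_orthogroups <- function(table, host_map, host, min_genomes = 1L) {
  table <- .check_orthogroup_table(table)
  if (!host %in% host_map) stop("unknown host: ", host)
  keep <- vapply(table, function(og) {
    members <- names(og)[lengths(og) > 0L]
    if (length(members) < min_genomes || length(members) == 0L) return(FALSE)
    if (!all(members %in% names(host_map))) {
      stop("genome(s) missing from host map: ",
           paste(setdiff(members, names(host_map)), collapse = ", "))
    }
    all(host_map[members] == host)
  }, logical(1))
  names(table)[keep]
}

#' Gene-duplication retention flag for an orthogroup
#'
#' Computes the fraction of member genomes that retain two or more gene copies
#' in the orthogroup, and flags the orthogroup when that fraction reaches the
#' retention threshold (inclusive). Orthogroups flagged this way are dominated
#' by retained duplicates and are typically excluded from per-site selection
#' analyses.
#'
#' @param table Orthogroup table (see [host_specific_orthogroups()]).
#' @param og Orthogroup id.
#' @param retention_threshold Fraction in \[0, 1\] (default 0.5).
#' @return List with `flag` (logical) and `retained_fraction`.
#' @export
duplication_flag <- function(table, og, retention_threshold = 0.5) {
  table <- .check_orthogroup_table(table)
  if (!og %in% names(table)) stop("orthogroup not found: ", og)
  counts <- lengths(table[[og]])
  with_gene <- sum(counts >= 1L)
  if (with_gene == 0L) return(list(flag = FALSE, retained_fraction = 0))
  frac <- sum(counts >= 2L) / with_gene
  list(flag = frac >= retention_threshold, retained_fraction = frac)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Cuts the query genome into consecutive non-overlapping fragments, locally
#' aligns each fragment against the full reference (Smith-Waterman), and
#' retains fragments whose alignment reaches the identity and fragment-coverage
#' filters. ANI is the mean percent identity of retained fragments; genome
#' coverage is the retained fraction of the fragmented query, in percent. The
#' trailing remainder shorter than `fragment_length` is excluded from both
#' numerator and denominator, so a self-comparison yields exactly 100/100.
#'
#' @param query,reference Genome sequences: single character strings,
#'   `Biostrings::DNAString`, or length-1 `DNAStringSet`.
#' @param fragment_length Fragment size in bp (default 1020, the classic
#'   fragmentation scheme).
#' @param min_fragment_identity Minimum percent identity for a fragment to be
#'   retained (default 30).
#' @param min_fragment_cover Minimum aligned fraction of the fragment
#'   (default 0.7).
#' @param gap_opening,gap_extension Alignment gap penalties (positive costs).
#' @return Object of class `ani_result` with `identity_percent` (NA when no
#'   fragment is retained), `coverage_percent`, `n_fragments` (retained) and
#'   `n_fragments_total`.
#' @examples
#' g <- sim_genome(5000, seed = 1)
#' ani <- compute_ani(g, mutate_genome(g, 0.02, seed = 2))
#' ani
#' @export
compute_ani <- function(query, reference, fragment_length = 1020,
                        min_fragment_identity = 30, min_fragment_cover = 0.7,
                        gap_opening = 2, gap_extension = 1) {
  query <- .as_dna_string(query, "query")
  reference <- .as_dna_string(reference, "reference")
  if (length(query) == 0L || length(reference) == 0L) stop("sequences must be non-empty")
  n_frag <- length(query) %/% fragment_length
  if (n_frag == 0L) {
    ## query shorter than one fragment: use it whole
    frags <- list(query)
  } else {
    starts <- (seq_len(n_frag) - 1L) * fragment_length + 1L
    frags <- lapply(starts, function(s) {
      Biostrings::subseq(query, s, s + fragment_length - 1L)
    })
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  ids <- numeric(length(frags))
  covered <- logical(length(frags))
  for (k in seq_along(frags)) {
    aln <- Biostrings::pairwiseAlignment(frags[[k]], reference, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = gap_opening,
                                         gapExtension = gap_extension)
    frac_aligned <- Biostrings::width(Biostrings::pattern(aln)) / length(frags[[k]])
    ids[k] <- Biostrings::pid(aln, type = "PID1")
    covered[k] <- frac_aligned >= min_fragment_cover && ids[k] >= min_fragment_identity
  }
  structure(list(
    identity_percent = if (any(covered)) mean(ids[covered]) else NA_real_,
    coverage_percent = 100 * sum(covered) / length(frags),
    n_fragments = sum(covered),
    n_fragments_total = length(frags),
    fragment_length = fragment_length
  ), class = "ani_result")
}

.as_dna_string <- function(x, what) {
  if (inherits(x, "DNAString")) return(x)
  if (inherits(x, "XStringSet")) {
    if (length(x) != 1L) stop("'", what, "' must be a single sequence")
    return(x[[1]])
  }
  if (is.character(x) && length(x) == 1L) return(Biostrings::DNAString(toupper(x)))
  stop("'", what, "' must be a single DNA sequence")
}

#' @export
print.ani_result <- function(x, digits = 4, ...) {
  cat("Average nucleotide identity\n")
  id_txt <- if (is.na(x$identity_percent)) "undefined (no retained fragment)" else
    paste0(format(x$identity_percent, digits = digits), " %")
  cat(sprintf("  identity: %s over %s %% genome coverage (%d/%d fragments of %d bp)\n",
              id_txt, format(x$coverage_percent, digits = digits),
              x$n_fragments, x$n_fragments_total, x$fragment_length))
  invisible(x)
}

#' ICTV species-demarcation call from an ANI result
#'
#' Two genomes are conspecific when identity >= `min_identity` percent over
#' coverage >= `min_coverage` percent of the genome (both inclusive). An
#' undefined identity (no retained fragment) yields `NA` (indeterminate), not
#' `FALSE`.
#'
#' @param r An `ani_result` from [compute_ani()], or a numeric identity
#'   percentage (with `coverage` supplied).
#' @param coverage Coverage percentage when `r` is numeric.
#' @param min_identity,min_coverage Demarcation cutoffs (default 95 and 85).
#' @return `TRUE`, `FALSE` or `NA`.
#' @examples
#' species_call(95.5, 79.1)   # FALSE: high identity but insufficient coverage
#' species_call(95, 85)       # TRUE: cutoffs are inclusive
#' @export
species_call <- function(r, coverage = NULL, min_identity = 95, min_coverage = 85) {
  if (inherits(r, "ani_result")) {
    identity <- r$identity_percent
    coverage <- r$coverage_percent
  } else {
    if (is.null(coverage)) stop("'coverage' required when 'r' is a numeric identity")
    identity <- as.numeric(r)
  }
  if (is.na(identity)) return(NA)
  identity >= min_identity && coverage >= min_coverage
}
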