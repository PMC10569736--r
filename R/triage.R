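# Complete-genome triage: pick one complete phage genome per sample from
# assembly metadata.

.CONTIG_COLS <- c("contig_id", "sample_id", "length", "viral", "coverage", "completeness")
.COMPLETENESS_LEVELS <- c("complete", "high", "medium", "low", "undetermined")

.check_contigs <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame")
  }
  missing_cols <- setdiff(.CONTIG_COLS, names(records))
  if (length(missing_cols)) {
    stop("missing contig columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(records$length <= 0)) stop("contig lengths must be > 0")
  if (any(records$coverage < 0)) stop("coverage must be >= 0")
  if (!is.logical(records$viral)) stop("'viral' must be logical")
  bad <- !records$completeness %in% .COMPLETENESS_LEVELS
  if (any(bad)) {
    stop("unknown completeness value(s): ",
         paste(unique(records$completeness[bad]), collapse = ", "))
  }
  dup <- duplicated(records[, c("sample_id", "contig_id")])
  if (any(dup)) {
    stop("duplicate contig id within a sample: ",
         paste(unique(records$contig_id[dup]), collapse = ", "))
  }
  records
}

#' Select one complete phage genome per sample
#'
#' Applies the assembly triage rule: within each sample, candidate contigs must
#' exceed `min_length` (strictly), be flagged viral, and be classified
#' `"complete"`; among candidates the one with the highest read coverage wins,
#' with ties broken by length (longer wins) and then lexicographically smallest
#' contig id. Samples with no candidate are reported with a warning and absent
#' from the result. The selection depends only on the set of records, not their
#' order.
#'
#' @param records Data frame with columns `contig_id`, `sample_id`, `length`
#'   (bp), `viral` (logical), `coverage`, `completeness` (one of `"complete"`,
#'   `"high"`, `"medium"`, `"low"`, `"undetermined"`).
#' @param min_length Length threshold in bp (strict; default 90000).
#' @return Named character vector mapping sample_id to the selected contig_id.
#' @examples
#' recs <- data.frame(contig_id = c("u1", "u2"), sample_id = "s1",
#'                    length = c(95000, 120000), viral = c(TRUE, FALSE),
#'                    coverage = c(300, 900), completeness = "complete")
#' select_complete_genomes(recs)
#' @export
select_complete_genomes <- function(records, min_length = 90000) {
  records <- .check_contigs(records)
  cand <- records[records$length > min_length & records$viral &
                    records$completeness == "complete", , drop = FALSE]
  samples <- sort(unique(records$sample_id))
  out <- character(0)
  empty <- character(0)
  for (s in samples) {
    cs <- cand[cand$sample_id == s, , drop = FALSE]
    if (nrow(cs) == 0L) {
      empty <- c(empty, s)
      next
    }
    cs <- cs[order(-cs$coverage, -cs$length, cs$contig_id), , drop = FALSE]
    out[s] <- cs$contig_id[1]
  }
  if (length(empty)) {
    warning("no complete genome candidate for sample(s): ",
            paste(empty, collapse = ", "))
  }
  out
}
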