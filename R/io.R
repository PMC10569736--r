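# Format readers and writers: FASTA, square distance matrices (PHYLIP/TSV),
# orthogroup tables, and the small TSV tables used across the pipeline.
# Readers reject malformed input rather than silently coercing; every writer
# produces files its own reader accepts.

#' Read a FASTA file of (possibly aligned) nucleotide sequences
#'
#' Sequences are upper-cased; U is mapped to T with a warning. An empty file
#' yields an empty set with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet` (gaps permitted).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) == 0L) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  if (!startsWith(trimws(lines[non_blank[1]]), ">")) {
    stop(sprintf("malformed FASTA record at line %d of %s: expected '>'",
                 non_blank[1], path))
  }
  x <- toupper(as.character(Biostrings::readBStringSet(path)))
  if (any(grepl("U", x, fixed = TRUE))) {
    warning("RNA alphabet detected: mapping U to T")
    x <- gsub("U", "T", x, fixed = TRUE)
  }
  Biostrings::DNAStringSet(x)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param records Named character vector or `XStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(toupper(records))
  Biostrings::writeXStringSet(records, path, width = 60L)
  invisible(path)
}

#' Read a labelled square distance matrix
#'
#' Supports the PHYLIP square format (first line: object count; then one row
#' per object: label followed by the distances) and TSV (header of labels, row
#' label in the first column). Asymmetry up to 1e-8 is symmetrized silently, up
#' to 1e-6 with a warning, and is an error beyond that.
#'
#' @param path Input path.
#' @param dialect `"auto"` (detect), `"phylip_square"` or `"tsv"`.
#' @return Labelled symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path, dialect = c("auto", "phylip_square", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    first <- trimws(readLines(path, n = 1L))
    dialect <- if (grepl("^[0-9]+$", first)) "phylip_square" else "tsv"
  }
  if (dialect == "phylip_square") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("parse error: PHYLIP header must be the object count")
    if (length(lines) != n + 1L) {
      stop(sprintf("parse error: expected %d matrix rows, found %d", n, length(lines) - 1L))
    }
    labels <- character(n)
    m <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      fields <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
      if (length(fields) != n + 1L) {
        stop(sprintf("parse error: row %d has %d values, expected %d",
                     i, length(fields) - 1L, n))
      }
      labels[i] <- fields[1]
      m[i, ] <- as.numeric(fields[-1])
    }
    dimnames(m) <- list(labels, labels)
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    labels <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    if (nrow(m) != ncol(m)) stop("parse error: distance matrix is not square")
    rownames(m) <- labels
    if (!identical(colnames(m), labels)) {
      stop("parse error: row labels do not match column labels")
    }
  }
  if (anyNA(m)) stop("parse error: non-numeric distance values")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    stop(sprintf("distance matrix asymmetric beyond tolerance (max |d - d'| = %g)", asym))
  }
  if (asym > 1e-8) {
    warning(sprintf("symmetrizing distance matrix (max |d - d'| = %g)", asym))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write a labelled square distance matrix
#'
#' @param d Labelled symmetric matrix.
#' @param path Output path.
#' @param dialect `"phylip_square"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, dialect = c("phylip_square", "tsv")) {
  dialect <- match.arg(dialect)
  d <- .check_distance_matrix(d)
  if (dialect == "phylip_square") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(c(rownames(d)[i], format(d[i, ], digits = 10, trim = TRUE)),
                       collapse = "\t"), con)
    }
  } else {
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an orthogroup table (Orthogroups.tsv dialect)
#'
#' Expects a tab-separated file whose first column holds orthogroup ids and
#' whose remaining columns, one per genome, hold comma(-space)-separated gene
#' lists; empty cells mean no member genes. Duplicate gene ids anywhere in the
#' table are an error.
#'
#' @param path Input path.
#' @return Named list: orthogroup id -> named list of gene-id character
#'   vectors per genome. The genome universe is in attribute `genomes`.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("parse error: orthogroup table needs genome columns")
  genomes <- names(df)[-1]
  out <- vector("list", nrow(df))
  names(out) <- df[[1]]
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- lapply(seq_along(genomes), function(g) {
      cell <- trimws(df[i, g + 1L])
      if (!nzchar(cell)) return(character(0))
      trimws(strsplit(cell, ",")[[1]])
    })
    names(row) <- genomes
    genes <- unlist(row, use.names = FALSE)
    dup <- genes[genes %in% seen | duplicated(genes)]
    if (length(dup)) stop("duplicate gene id in orthogroup table: ", dup[1])
    seen <- c(seen, genes)
    out[[i]] <- row
  }
  attr(out, "genomes") <- genomes
  out
}

#' Read a genome-to-host map
#'
#' @param path TSV with columns `genome_id`, `host_id`.
#' @return Named character vector genome_id -> host_id.
#' @export
read_host_map <- function(path) {
  df <- .read_tsv_cols(path, c("genome_id", "host_id"))
  if (anyDuplicated(df$genome_id)) stop("duplicate genome_id in host map")
  setNames(df$host_id, df$genome_id)
}

#' Read host-parasite links
#'
#' @param path TSV with columns `parasite_id`, `host_id` (one row per link).
#' @return Binary association matrix (parasites x hosts).
#' @export
read_links <- function(path) {
  df <- .read_tsv_cols(path, c("parasite_id", "host_id"))
  association_matrix(df$parasite_id, df$host_id)
}

#' Read TEM capsid measurements
#'
#' @param path TSV with columns `phage_id`, `diameter_nm`, `diameter_sd_nm`,
#'   `tail_nm`, `genome_bp` (the SD and tail columns may be empty).
#' @return List of [capsid_measurement()] objects with a `genome_bp` attribute
#'   holding the genome lengths (named by phage).
#' @export
read_capsid_measurements <- function(path) {
  df <- .read_tsv_cols(path, c("phage_id", "diameter_nm", "genome_bp"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    capsid_measurement(df$phage_id[i], df$diameter_nm[i],
                       diameter_sd_nm = if ("diameter_sd_nm" %in% names(df))
                         df$diameter_sd_nm[i] else NA_real_,
                       tail_nm = if ("tail_nm" %in% names(df)) df$tail_nm[i] else NA_real_)
  })
  names(out) <- df$phage_id
  attr(out, "genome_bp") <- setNames(df$genome_bp, df$phage_id)
  out
}

#' Read an assembly contig metadata table
#'
#' @param path TSV with columns `contig_id`, `sample_id`, `length`, `viral`
#'   (true/false), `coverage`, `completeness`.
#' @return Validated data frame suitable for [select_complete_genomes()].
#' @export
read_contigs <- function(path) {
  df <- .read_tsv_cols(path, .CONTIG_COLS)
  v <- tolower(trimws(as.character(df$viral)))
  if (!all(v %in% c("true", "false"))) stop("parse error: 'viral' must be true/false")
  df$viral <- v == "true"
  df$length <- as.numeric(df$length)
  df$coverage <- as.numeric(df$coverage)
  .check_contigs(df)
}

.read_tsv_cols <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("parse error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path)
  }
  df
}
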