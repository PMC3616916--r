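# Readers/writers for the plain-text formats the pipeline consumes.

#' Write an EST set to FASTA
#' @param sequences named character vector of nucleotide sequences.
#' @param path output FASTA path.
#' @export
write_est_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read an EST set from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_est_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "aligned_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Write a hit table as headerless 12-column tabular output
#'
#' Standard tabular column order; a 13th \code{dataset_id} column is
#' appended when present (readers that expect exactly 12 columns ignore it).
#' @param hits hit data frame.
#' @param path output TSV path.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- BLAST6_COLS
  if ("dataset_id" %in% names(hits)) cols <- c(cols, "dataset_id")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tabular (outfmt-6 style) hit table
#'
#' Expects the 12 standard columns; extra columns are tolerated — the 13th
#' is taken as a dataset label unless \code{dataset_id} is supplied, and any
#' further columns are dropped. Malformed rows raise an error naming the
#' line.
#' @param path TSV path (headerless).
#' @param dataset_id optional dataset label to stamp on all rows.
#' @return hit data frame with named columns.
#' @export
read_blast_hits <- function(path, dataset_id = NULL) {
  raw <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(raw) < 12) {
    stop("hit table '", path, "' has ", ncol(raw),
         " columns; 12 tabular columns required", call. = FALSE)
  }
  hits <- raw[, 1:12]
  names(hits) <- BLAST6_COLS
  for (col in c("percent_identity", "aligned_length", "e_value", "bit_score")) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    bad <- which(is.na(v) & !is.na(hits[[col]]))
    if (length(bad)) {
      stop("hit table '", path, "': malformed ", col, " at line ", bad[1],
           call. = FALSE)
    }
    hits[[col]] <- v
  }
  if (any(hits$e_value < 0, na.rm = TRUE)) {
    stop("hit table '", path, "': negative e-value at line ",
         which(hits$e_value < 0)[1], call. = FALSE)
  }
  hits$dataset_id <- if (!is.null(dataset_id)) {
    dataset_id
  } else if (ncol(raw) >= 13) {
    as.character(raw[[13]])
  } else {
    "default"
  }
  hits
}

#' Write a data frame as a TSV with header
#' @param x data frame.
#' @param path output path.
#' @export
write_tab <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy-number table (family_id, n_copies)
#' @param path TSV path with header.
#' @export
read_copy_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("family_id", "n_copies") %in% names(x))) {
    stop("copy-number table needs columns family_id, n_copies", call. = FALSE)
  }
  x
}

#' Read a gene-family presence/absence matrix (families x species)
#' @param path TSV with header row of species ids and first column of
#'   family ids.
#' @export
read_family_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(x)
}

#' Write a gene-family matrix
#' @param m families x species matrix.
#' @param path output path.
#' @export
write_family_matrix <- function(m, path) {
  df <- data.frame(family_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format probe intensity table
#' @param path TSV with header: probe_id, target_id, condition_id,
#'   intensity (and optional is_random; otherwise rows with empty/NA
#'   target_id are taken as random probes).
#' @export
read_probe_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("probe_id", "target_id", "condition_id", "intensity")
  if (!all(need %in% names(x))) {
    stop("probe table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"is_random" %in% names(x)) x$is_random <- is.na(x$target_id)
  x$is_random <- as.logical(x$is_random)
  x
}

#' Write a TruthBundle as JSON
#' @param truth list of truth components.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
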