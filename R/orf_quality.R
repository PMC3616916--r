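# Sequence-quality metrics for the annotated-vs-orphan comparison:
# longest ORF per read, start-codon presence, nucleotide length and GC.
#
# An ORF is defined stop-to-stop: the longest maximal stop-free in-frame
# interval, with start-codon presence reported separately (a read can have
# a long ORF that never contains an in-frame ATG). Coordinates are 0-based
# half-open on the read. The default frame set is the three forward frames,
# matching directionally cloned, 5'-sequenced libraries; pass
# frames = c(1, 2, 3, -1, -2, -3) for a six-frame search.

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Codons containing N are ambiguous: treated as neither stop nor start.
codon_split <- function(seq, offset) {
  n <- nchar(seq)
  if (offset + 1L > n - 2L) return(character(0))
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Find the longest open reading frame in a read
#'
#' Scans the requested frames for the longest maximal stop-free in-frame
#' interval. Ties are broken by frame order \code{1 < 2 < 3 < -1 < -2 < -3},
#' then by smaller start. \code{has_start_codon} is \code{TRUE} iff an
#' in-frame ATG occurs within the interval. For negative frames the
#' coordinates refer to the reverse-complemented read.
#'
#' @param sequence nucleotide string (alphabet A/C/G/T/N) or a single-row
#'   EST record with a \code{sequence} field.
#' @param frames subset of \code{c(1, 2, 3, -1, -2, -3)}.
#' @return list: \code{frame}, \code{start}, \code{end} (0-based half-open),
#'   \code{orf_length_nt}, \code{has_start_codon}. If no stop-free codon
#'   exists in any requested frame, a zero-length call at the first
#'   requested frame's offset is returned.
#' @export
find_orf <- function(sequence, frames = c(1L, 2L, 3L)) {
  if (is.list(sequence) && !is.null(sequence$sequence)) {
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) {
    stop("sequence shorter than 3 nt: no codon fits", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  frame_order <- c(1L, 2L, 3L, -1L, -2L, -3L)
  frames <- as.integer(frames)
  if (!all(frames %in% frame_order)) {
    stop("frames must be a subset of 1,2,3,-1,-2,-3", call. = FALSE)
  }
  frames <- frame_order[frame_order %in% frames]
  rc <- if (any(frames < 0)) revcomp(sequence) else NULL

  best <- NULL
  for (f in frames) {
    s <- if (f > 0) sequence else rc
    off <- abs(f) - 1L
    codons <- codon_split(s, off)
    if (!length(codons)) next
    is_stop <- codons %in% STOP_CODONS
    # maximal stop-free runs of codons
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts_run <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      c0 <- starts_run[k]; c1 <- ends[k]
      start <- off + (c0 - 1L) * 3L
      end <- off + c1 * 3L
      len <- end - start
      cand <- list(frame = f, start = start, end = end,
                   orf_length_nt = len,
                   has_start = any(codons[c0:c1] == "ATG"))
      if (is.null(best) || len > best$orf_length_nt) best <- cand
      # equal length: earlier frame in iteration order wins, then smaller
      # start; runs within a frame are visited left to right already
    }
  }
  if (is.null(best)) {
    f <- frames[1]
    off <- abs(f) - 1L
    best <- list(frame = f, start = off, end = off, orf_length_nt = 0L,
                 has_start = FALSE)
  }
  list(frame = best$frame, start = best$start, end = best$end,
       orf_length_nt = best$orf_length_nt,
       has_start_codon = best$has_start)
}

#' GC content of a read, in percent
#'
#' 100 * (G + C) / (A + C + G + T); N bases are excluded from the
#' denominator. An all-N (or empty-denominator) sequence is an error.
#' @param sequence nucleotide string.
#' @return percent in [0, 100].
#' @export
gc_content <- function(sequence) {
  if (is.list(sequence) && !is.null(sequence$sequence)) {
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  bases <- strsplit(sequence, "")[[1]]
  n_gc <- sum(bases %in% c("G", "C"))
  n_acgt <- sum(bases %in% c("A", "C", "G", "T"))
  if (n_acgt == 0) {
    stop("GC content undefined: no unambiguous bases", call. = FALSE)
  }
  100 * n_gc / n_acgt
}

#' Per-EST quality metrics
#'
#' Computes, for every read: nucleotide length, longest-ORF length, frame,
#' start-codon presence and GC percent.
#' @param sequences named character vector of reads.
#' @param frames frame set passed to \code{\link{find_orf}}.
#' @return data frame with one row per read.
#' @export
est_metrics <- function(sequences, frames = c(1L, 2L, 3L)) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  orfs <- lapply(sequences, find_orf, frames = frames)
  data.frame(
    est_id = names(sequences),
    length_nt = nchar(sequences),
    orf_length_nt = vapply(orfs, `[[`, integer(1), "orf_length_nt"),
    frame = vapply(orfs, `[[`, integer(1), "frame"),
    has_start = vapply(orfs, `[[`, logical(1), "has_start_codon"),
    gc_percent = vapply(sequences, gc_content, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Group quality summaries for annotated vs unannotated reads
#'
#' @param metrics per-EST metric data frame from \code{\link{est_metrics}}
#'   (columns est_id, length_nt, orf_length_nt, has_start, gc_percent).
#' @param partition named character vector mapping every est_id to a group
#'   label (conventionally "annotated"/"unannotated").
#' @return data frame with one row per group: n, mean_orf_length_nt,
#'   mean_length_nt, n_without_start, mean_gc_percent.
#' @export
summarize_quality <- function(metrics, partition) {
  missing <- setdiff(metrics$est_id, names(partition))
  if (length(missing)) {
    stop("partition does not cover all ids: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  grp <- as.character(partition[metrics$est_id])
  pieces <- split(metrics, grp)
  out <- do.call(rbind, Map(function(label, d) {
    data.frame(
      group = label,
      n = nrow(d),
      mean_orf_length_nt = mean(d$orf_length_nt),
      mean_length_nt = mean(d$length_nt),
      n_without_start = sum(!d$has_start),
      mean_gc_percent = mean(d$gc_percent),
      stringsAsFactors = FALSE
    )
  }, names(pieces), pieces))
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, as used to compare quality metrics between annotated and
#' unannotated reads. Wraps \code{stats::t.test(var.equal = FALSE)}.
#' @param a,b numeric vectors (each n >= 2; at least one with nonzero
#'   variance).
#' @return list: t_statistic, degrees_of_freedom, p_value, mean_a, mean_b.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_t: each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("welch_t: both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
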