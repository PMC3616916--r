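# Independent brute-force oracles. These deliberately share no code with
# the package: interval enumeration instead of run-length logic, row loops
# instead of vectorised filters, explicit sort-and-interpolate quantiles.

bf_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# Enumerate every in-frame stop-free interval in every requested frame and
# keep the longest (ties: earlier frame in canonical order, then smaller
# start). Codons containing N count as neither stop nor start.
bf_orf <- function(seq, frames = c(1, 2, 3)) {
  stops <- c("TAA", "TAG", "TGA")
  order_f <- c(1, 2, 3, -1, -2, -3)
  frames <- order_f[order_f %in% frames]
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  for (f in frames) {
    s <- if (f > 0) seq else bf_revcomp(seq)
    off <- abs(f) - 1
    if (off > n - 3) next
    for (st in seq(off, n - 3, by = 3)) {
      en <- st
      while (en + 3 <= n && !(substr(s, en + 1, en + 3) %in% stops)) {
        en <- en + 3
        len <- en - st
        if (is.null(best) || len > best$orf_length_nt) {
          has <- FALSE
          for (p in seq(st, en - 3, by = 3)) {
            if (substr(s, p + 1, p + 3) == "ATG") has <- TRUE
          }
          best <- list(frame = f, start = st, end = en,
                       orf_length_nt = len, has_start_codon = has)
        }
      }
    }
  }
  if (is.null(best)) {
    f <- frames[1]
    best <- list(frame = f, start = abs(f) - 1, end = abs(f) - 1,
                 orf_length_nt = 0L, has_start_codon = FALSE)
  }
  best
}

# Type-7 quantile by explicit sort and interpolation.
bf_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q
  lo <- floor(h)
  if (lo + 1 >= n) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# Row-by-row filter scan.
bf_filter <- function(hits, e_max = 1e-5, min_len = 33) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep[i] <- hits$e_value[i] <= e_max && hits$aligned_length[i] >= min_len
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Family-by-family set algebra.
bf_exclusive <- function(mat, focal) {
  out <- character(0)
  for (i in seq_len(nrow(mat))) {
    pres <- colnames(mat)[mat[i, ] > 0]
    if (length(pres) > 0 && any(pres %in% focal) && all(pres %in% focal)) {
      out <- c(out, rownames(mat)[i])
    }
  }
  out
}

# Per-query best-hit assignment by explicit pairwise comparison.
bf_assign <- function(hits, family_map) {
  fams <- character(0)
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    best <- 1
    for (i in seq_len(nrow(h))[-1]) {
      better <- h$e_value[i] < h$e_value[best] ||
        (h$e_value[i] == h$e_value[best] &&
           h$bit_score[i] > h$bit_score[best]) ||
        (h$e_value[i] == h$e_value[best] &&
           h$bit_score[i] == h$bit_score[best] &&
           h$subject_id[i] < h$subject_id[best])
      if (better) best <- i
    }
    fam <- family_map$family_id[family_map$subject_id == h$subject_id[best]]
    if (length(fam)) fams <- c(fams, fam)
  }
  tab <- table(fams)
  data.frame(family_id = names(tab), n_copies = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

# All sequences of a given length over ACGT.
all_sequences <- function(len) {
  apply(do.call(expand.grid, rep(list(c("A", "C", "G", "T")), len)),
        1, paste, collapse = "")
}

random_dna <- function(len, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

expect_orf_matches_oracle <- function(seq, frames = c(1, 2, 3)) {
  got <- find_orf(seq, frames = frames)
  want <- bf_orf(seq, frames = frames)
  expect_equal(got$orf_length_nt, want$orf_length_nt, info = seq)
  expect_equal(got$frame, want$frame, info = seq)
  expect_equal(got$start, want$start, info = seq)
  expect_equal(got$end, want$end, info = seq)
  expect_equal(got$has_start_codon, want$has_start_codon, info = seq)
}
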