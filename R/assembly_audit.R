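# Assembly accounting and the single-copy-ortholog assembly-failure
# statistic.
#
# The failure-rate estimator multiplies (i) the fraction of matched
# conserved single-copy ortholog families that appear in more than one
# focal sequence by (ii) the fraction of the sequences inside those
# multi-copy families that correspond to real genes (one per family). With
# the worked counts 415 matched families / 86 multi-copy / 194 sequences,
# this gives (86/415) * (86/194) ~= 9.2%, and discounting a 14,310-sequence
# unique set by that rate removes 1,315 sequences.

#' Gene discovery rate
#'
#' Unique sequences (contigs + singletons) per input read.
#' @param n_input_reads number of reads entering assembly.
#' @param n_unique number of unique sequences produced.
#' @return fraction in (0, 1].
#' @export
discovery_rate <- function(n_input_reads, n_unique) {
  if (n_input_reads <= 0) stop("discovery_rate: zero input reads",
                               call. = FALSE)
  if (n_unique <= 0 || n_unique > n_input_reads) {
    stop("discovery_rate: n_unique must be in (0, n_input_reads]",
         call. = FALSE)
  }
  n_unique / n_input_reads
}

#' Assembly composition object
#'
#' @param n_input_reads reads entering assembly.
#' @param contig_sizes integer vector of member-read counts, one per contig
#'   (each >= 2).
#' @param n_singletons reads that assembled with no other.
#' @return validated list of class \code{assembly_composition}.
#' @export
assembly_composition <- function(n_input_reads, contig_sizes, n_singletons) {
  contig_sizes <- as.integer(contig_sizes)
  if (length(contig_sizes) && any(contig_sizes < 2)) {
    stop("assembly composition: contig with fewer than 2 members",
         call. = FALSE)
  }
  if (n_singletons + sum(contig_sizes) != n_input_reads) {
    stop("assembly composition: singletons + contig members (",
         n_singletons + sum(contig_sizes), ") != input reads (",
         n_input_reads, ")", call. = FALSE)
  }
  structure(list(n_input_reads = n_input_reads, contig_sizes = contig_sizes,
                 n_singletons = n_singletons),
            class = "assembly_composition")
}

#' Build an assembly composition from a read-membership table
#' @param membership data frame with columns read_id and contig_id, where
#'   contig_id is \code{"SINGLETON"} for unassembled reads.
#' @export
composition_from_membership <- function(membership) {
  stopifnot(all(c("read_id", "contig_id") %in% names(membership)))
  singles <- membership$contig_id == "SINGLETON"
  sizes <- table(membership$contig_id[!singles])
  assembly_composition(nrow(membership), as.integer(sizes), sum(singles))
}

#' Contig size spectrum
#'
#' Histogram of contig member counts plus the fraction of contigs made of
#' two or three reads.
#' @param composition an \code{\link{assembly_composition}}.
#' @return list: \code{spectrum} (data frame n_members, n_contigs),
#'   \code{frac_2_3}, and two candidate redundancy ratios
#'   (contigs/reads and 1 - unique/reads) emitted as notes.
#' @export
contig_spectrum <- function(composition) {
  stopifnot(inherits(composition, "assembly_composition"))
  sizes <- composition$contig_sizes
  tab <- table(sizes)
  spectrum <- data.frame(n_members = as.integer(names(tab)),
                         n_contigs = as.integer(tab))
  n_contigs <- length(sizes)
  n_unique <- n_contigs + composition$n_singletons
  list(
    spectrum = spectrum,
    frac_2_3 = if (n_contigs) sum(sizes %in% c(2L, 3L)) / n_contigs else NA_real_,
    n_contigs = n_contigs,
    n_unique = n_unique,
    redundancy_contigs_per_read = n_contigs / composition$n_input_reads,
    redundancy_one_minus_discovery =
      1 - n_unique / composition$n_input_reads
  )
}

failure_estimate_from_counts <- function(n_families_matched,
                                         n_multicopy_families,
                                         n_sequences_in_multicopy_families) {
  p_multicopy <- n_multicopy_families / n_families_matched
  p_true_singletons <- if (n_multicopy_families > 0) {
    n_multicopy_families / n_sequences_in_multicopy_families
  } else 0
  structure(list(
    n_families_matched = n_families_matched,
    n_multicopy_families = n_multicopy_families,
    n_sequences_in_multicopy_families = n_sequences_in_multicopy_families,
    p_multicopy = p_multicopy,
    p_true_singletons = p_true_singletons,
    failure_rate = p_multicopy * p_true_singletons,
    n_discounted = NA_integer_,
    adjusted_unique = NA_integer_
  ), class = "failure_estimate")
}

#' Assembly failure rate from a single-copy ortholog copy-number table
#'
#' @param table data frame (family_id, n_copies) restricted to families
#'   single-copy in all reference species and matched in the focal set.
#' @return \code{failure_estimate}: counts, the two proportions and their
#'   product (the failure rate). Discounted counts are filled in by
#'   \code{\link{adjust_unique_count}}.
#' @export
failure_rate <- function(table) {
  if (is.null(table) || nrow(table) == 0) {
    stop("failure_rate: empty copy-number table", call. = FALSE)
  }
  if (any(table$n_copies < 1)) {
    stop("failure_rate: copy counts must be positive integers",
         call. = FALSE)
  }
  multi <- table$n_copies > 1
  failure_estimate_from_counts(
    n_families_matched = nrow(table),
    n_multicopy_families = sum(multi),
    n_sequences_in_multicopy_families = sum(table$n_copies[multi])
  )
}

round_half_up <- function(x) floor(x + 0.5)  # half away from zero for x >= 0

#' Discount a unique-sequence count by the assembly failure rate
#'
#' \code{n_discounted = round(n_unique * failure_rate)} with half rounded
#' away from zero; \code{adjusted_unique = n_unique - n_discounted}.
#' @param n_unique unique-sequence count to adjust.
#' @param estimate a \code{failure_estimate} from \code{\link{failure_rate}}.
#' @return the estimate with \code{n_discounted} and \code{adjusted_unique}
#'   filled in.
#' @export
adjust_unique_count <- function(n_unique, estimate) {
  stopifnot(inherits(estimate, "failure_estimate"))
  if (n_unique <= 0) stop("adjust_unique_count: n_unique must be positive",
                          call. = FALSE)
  estimate$n_discounted <- as.integer(
    round_half_up(n_unique * estimate$failure_rate))
  estimate$adjusted_unique <- as.integer(n_unique) - estimate$n_discounted
  estimate
}

#' @export
print.failure_estimate <- function(x, ...) {
  cat(sprintf(
    "Assembly-failure estimate: %d/%d families multi-copy (%.1f%%), %d/%d sequences real (%.1f%%)\n",
    x$n_multicopy_families, x$n_families_matched, 100 * x$p_multicopy,
    x$n_multicopy_families, x$n_sequences_in_multicopy_families,
    100 * x$p_true_singletons))
  cat(sprintf("  failure rate = %.2f%%\n", 100 * x$failure_rate))
  if (!is.na(x$n_discounted)) {
    cat(sprintf("  discounted %d sequences -> %d adjusted unique\n",
                x$n_discounted, x$adjusted_unique))
  }
  invisible(x)
}

#' Assign ESTs to gene families by best hit and count copies
#'
#' Each query is assigned the family of its best hit (lowest e-value, ties
#' broken by highest bit score, then lexicographically smallest subject
#' id); a family's copy count is the number of distinct queries assigned to
#' it. Queries without a passing hit are omitted.
#' @param hits pre-filtered hit data frame.
#' @param family_map data frame (subject_id, family_id).
#' @return copy-number table (family_id, n_copies).
#' @export
assign_families <- function(hits, family_map) {
  stopifnot(all(c("subject_id", "family_id") %in% names(family_map)))
  if (nrow(hits) == 0) {
    return(data.frame(family_id = character(0), n_copies = integer(0)))
  }
  best <- best_hits(hits, by_dataset = FALSE)
  fam <- family_map$family_id[match(best$subject_id, family_map$subject_id)]
  keep <- !is.na(fam)
  tab <- table(fam[keep])
  data.frame(family_id = names(tab), n_copies = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
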