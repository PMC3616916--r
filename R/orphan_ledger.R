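# The stepwise orphan accounting: run the four explanatory analyses in
# sequence — homology annotation, start-codon screen, assembly-failure
# discount, expression support, reference-completeness correction — and
# record, at every step, how many ESTs are explained and how many orphan
# candidates remain. Works either from real/synthetic per-EST inputs
# (run_pipeline) or from a fixture of printed count tables
# (ledger_from_counts).

new_ledger <- function(steps, headline, notes = character(0),
                       printed = NULL) {
  structure(list(steps = steps, headline = headline, notes = notes,
                 printed = printed),
            class = "orphan_ledger")
}

ledger_step <- function(label, n_considered, n_removed, note = "") {
  if (n_removed < 0 || n_removed > n_considered) {
    stop("ledger step '", label, "': removed count ", n_removed,
         " outside [0, ", n_considered, "]", call. = FALSE)
  }
  data.frame(label = label,
             n_considered = as.integer(n_considered),
             n_removed = as.integer(n_removed),
             n_remaining = as.integer(n_considered - n_removed),
             note = note,
             stringsAsFactors = FALSE)
}

#' Read a count-table fixture (YAML) for fixture-mode accounting
#'
#' @param path YAML file with the structure documented in
#'   \code{\link{ledger_from_counts}}. The package ships one under
#'   \code{system.file("extdata", "printed_counts.yaml")} transcribing the
#'   worked example's published count tables.
#' @return a counts list.
#' @export
read_counts_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Build an orphan ledger from printed count tables
#'
#' Fixture mode: all inputs are counts (e.g. transcribed from a published
#' study's tables); every derived quantity — failure rate, adjusted unique
#' count, retained fractions, corrected homology — is recomputed here from
#' those inputs.
#'
#' @param counts a list with components (all optional except
#'   \code{n_total}, \code{n_annotated}/\code{n_unannotated}):
#'   \code{n_no_start_unannotated}; \code{qa} (n_reads, n_unique);
#'   \code{copy_number} (n_families_matched, n_multicopy, n_seqs_multicopy);
#'   \code{expression} (n_probed, n_retained, n_retained_annotated);
#'   \code{homology}: data frame or list of records with dataset, n_match,
#'   n_nomatch and either p_intra or n_self_match (paired with top-level
#'   \code{n_reference_transcripts}); \code{union_match}; \code{printed}: a
#'   named list of the source's printed values, carried along for
#'   side-by-side comparison only.
#' @return an \code{orphan_ledger}.
#' @export
ledger_from_counts <- function(counts) {
  n_total <- counts$n_total
  if (is.null(n_total)) stop("ledger_from_counts: n_total required",
                             call. = FALSE)
  n_unannot <- counts$n_unannotated
  n_annot <- counts$n_annotated
  if (is.null(n_unannot) && is.null(n_annot)) {
    stop("ledger_from_counts: need n_annotated or n_unannotated",
         call. = FALSE)
  }
  if (is.null(n_unannot)) n_unannot <- n_total - n_annot
  if (is.null(n_annot)) n_annot <- n_total - n_unannot
  if (n_annot + n_unannot != n_total) {
    stop("ledger_from_counts: annotated + unannotated != total",
         call. = FALSE)
  }
  notes <- character(0)
  steps <- rbind(
    ledger_step("input unique ESTs", n_total, 0L),
    ledger_step("annotated by homology search", n_total, n_annot,
                "explained: homologs in reference databases")
  )
  remaining <- n_unannot

  headline <- list(unannotated_fraction = n_unannot / n_total)

  if (!is.null(counts$qa)) {
    dr <- discovery_rate(counts$qa$n_reads, counts$qa$n_unique)
    headline$qa_discovery_rate <- dr
    headline$qa_discovery_percent <- round_half_up(100 * dr)
  }

  if (!is.null(counts$n_no_start_unannotated)) {
    steps <- rbind(steps, ledger_step(
      "unannotated lacking a start codon", remaining,
      counts$n_no_start_unannotated,
      "explained: poor sequence quality"))
    remaining <- remaining - counts$n_no_start_unannotated
  } else {
    notes <- c(notes, "start-codon stage skipped: no count supplied")
  }

  if (!is.null(counts$copy_number)) {
    cn <- counts$copy_number
    fe <- failure_estimate_from_counts(cn$n_families_matched,
                                       cn$n_multicopy, cn$n_seqs_multicopy)
    fe <- adjust_unique_count(n_total, fe)
    headline$failure_rate <- fe$failure_rate
    headline$failure_rate_percent <- round_half_up(100 * fe$failure_rate)
    headline$n_discounted <- fe$n_discounted
    headline$adjusted_unique <- fe$adjusted_unique
  } else {
    notes <- c(notes, "assembly-failure stage skipped: no copy-number counts")
  }

  if (!is.null(counts$expression)) {
    ex <- counts$expression
    fs <- functional_summary(n_probed = ex$n_probed,
                             n_retained = ex$n_retained,
                             n_retained_annotated = ex$n_retained_annotated)
    headline$frac_retained <- fs$frac_retained
    headline$frac_retained_annotated <- fs$frac_retained_annotated
    headline$n_retained_unannotated <- fs$n_retained_unannotated
    headline$frac_retained_unannotated <- fs$frac_retained_unannotated
    removed <- remaining - fs$n_retained_unannotated
    if (removed >= 0) {
      steps <- rbind(steps, ledger_step(
        "unannotated without expression support (or unprobed)",
        remaining, removed, "explained: no evidence of function"))
      remaining <- remaining - removed
    } else {
      notes <- c(notes,
                 "expression stage not chained: retained unannotated exceeds remaining")
    }
  } else {
    notes <- c(notes, "expression stage skipped: no microarray counts")
  }

  if (!is.null(counts$homology)) {
    hom <- counts$homology
    if (!is.data.frame(hom)) {
      hom <- do.call(rbind, lapply(hom, function(h) {
        data.frame(dataset = h$dataset, n_match = h$n_match,
                   n_nomatch = h$n_nomatch,
                   p_intra = if (!is.null(h$p_intra)) h$p_intra else NA_real_,
                   n_self_match = if (!is.null(h$n_self_match)) {
                     h$n_self_match
                   } else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }
    if (!"p_intra" %in% names(hom)) hom$p_intra <- NA_real_
    if ("n_self_match" %in% names(hom) &&
        !is.null(counts$n_reference_transcripts)) {
      use <- is.na(hom$p_intra) & !is.na(hom$n_self_match)
      hom$p_intra[use] <- vapply(hom$n_self_match[use], intraspecific_rate,
                                 numeric(1),
                                 n_reference_queries = counts$n_reference_transcripts)
    }
    hom$raw_fraction <- hom$n_match / (hom$n_match + hom$n_nomatch)
    hom$corrected_fraction <- NA_real_
    hom$corrected_percent <- NA_real_
    for (i in seq_len(nrow(hom))) {
      if (!is.na(hom$p_intra[i])) {
        cm <- corrected_matching(hom$n_match[i] + hom$n_nomatch[i],
                                 hom$n_match[i], hom$n_nomatch[i],
                                 hom$p_intra[i])
        hom$corrected_fraction[i] <- cm$corrected_fraction
        hom$corrected_percent[i] <- cm$corrected_percent
      }
    }
    headline$homology <- hom[, c("dataset", "n_match", "n_nomatch",
                                 "p_intra", "raw_fraction",
                                 "corrected_fraction", "corrected_percent")]
    if (!is.null(counts$union_match)) {
      headline$union_match <- counts$union_match
      headline$union_fraction <- counts$union_match / n_total
    }
  } else {
    notes <- c(notes, "reference-dataset homology stage skipped")
  }

  headline$n_orphan_candidates <- remaining
  new_ledger(steps, headline, notes, printed = counts$printed)
}

#' Run the full partitioning pipeline on synthetic inputs
#'
#' Generates every stage input from one \code{\link{sim_config}} (shared
#' seed sub-streams keep the id universe consistent), executes the four
#' analyses, and assembles the ledger. Stages omitted from \code{stages}
#' are marked skipped and the running total is carried through; with the
#' homology stage absent every EST is unannotated.
#'
#' @param config a \code{sim_config}.
#' @param stages subset of c("homology", "quality", "assembly",
#'   "expression", "exclusivity").
#' @param q,min_conditions expression-calling parameters.
#' @return list of class \code{orphan_pipeline}: \code{ledger} plus the
#'   per-stage components (metrics, partition, quality summary, failure
#'   estimate, expression calls, truth bundles).
#' @export
run_pipeline <- function(config,
                         stages = c("homology", "quality", "assembly",
                                    "expression"),
                         q = 0.995, min_conditions = 2L) {
  stopifnot(inherits(config, "sim_config"))
  ids <- est_ids(config$n_ests)
  est <- gen_est_set(config)
  metrics <- est_metrics(est$sequences)
  notes <- character(0)

  part <- NULL
  annotated_ids <- character(0)
  if ("homology" %in% stages) {
    gh <- gen_homology_table(config)
    filt <- filter_hits(gh$hits)
    part <- partition_queries(ids, filt)
    if (ncol(part$flags) > 0) {
      annotated_ids <- rownames(part$flags)[rowSums(part$flags) > 0]
    }
  } else {
    notes <- c(notes, "homology stage skipped: all ESTs treated as unannotated")
  }
  unannot_ids <- setdiff(ids, annotated_ids)
  partition <- stats::setNames(
    ifelse(ids %in% annotated_ids, "annotated", "unannotated"), ids)

  steps <- rbind(
    ledger_step("input ESTs", config$n_ests, 0L),
    ledger_step("annotated by homology search", config$n_ests,
                length(annotated_ids),
                if ("homology" %in% stages) {
                  "explained: homologs in reference"
                } else "stage skipped")
  )
  remaining_ids <- unannot_ids

  quality <- NULL
  welch <- NULL
  if ("quality" %in% stages) {
    quality <- summarize_quality(metrics, partition)
    a <- metrics$orf_length_nt[metrics$est_id %in% annotated_ids]
    b <- metrics$orf_length_nt[metrics$est_id %in% unannot_ids]
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::var(a) > 0 || stats::var(b) > 0)) {
      welch <- welch_t(a, b)
    }
    no_start <- metrics$est_id[!metrics$has_start]
    removed <- intersect(remaining_ids, no_start)
    steps <- rbind(steps, ledger_step(
      "unannotated lacking a start codon", length(remaining_ids),
      length(removed), "explained: poor sequence quality"))
    remaining_ids <- setdiff(remaining_ids, removed)
  } else {
    notes <- c(notes, "quality stage skipped")
  }

  fe <- NULL
  copies <- NULL
  if ("assembly" %in% stages) {
    copies <- gen_copy_number_scenario(config)
    fe <- adjust_unique_count(config$n_ests, failure_rate(copies$table))
  } else {
    notes <- c(notes, "assembly stage skipped")
  }

  calls <- NULL
  fs <- NULL
  if ("expression" %in% stages) {
    pm <- gen_probe_matrix(config)
    calls <- call_expression(pm$probes, q = q,
                             min_conditions = min_conditions)
    annotation <- data.frame(target_id = ids,
                             annotated = ids %in% annotated_ids,
                             stringsAsFactors = FALSE)
    fs <- functional_summary(calls, annotation)
    functional_ids <- calls$targets$target_id[calls$targets$functional]
    removed <- setdiff(remaining_ids, functional_ids)
    steps <- rbind(steps, ledger_step(
      "unannotated without expression support (or unprobed)",
      length(remaining_ids), length(removed),
      "explained: no evidence of function"))
    remaining_ids <- setdiff(remaining_ids, removed)
    expr_truth <- pm$truth
  } else {
    notes <- c(notes, "expression stage skipped")
    expr_truth <- NULL
  }

  headline <- list(
    unannotated_fraction = length(unannot_ids) / config$n_ests
  )
  if (!is.null(fe)) {
    headline$failure_rate <- fe$failure_rate
    headline$failure_rate_percent <- round_half_up(100 * fe$failure_rate)
    headline$n_discounted <- fe$n_discounted
    headline$adjusted_unique <- fe$adjusted_unique
  }
  if (!is.null(fs)) {
    headline$frac_retained <- fs$frac_retained
    headline$frac_retained_annotated <- fs$frac_retained_annotated
    headline$frac_retained_unannotated <- fs$frac_retained_unannotated
  }
  if (!is.null(part) && nrow(part$marginals) > 0) {
    hom <- part$marginals
    hom$p_intra <- config$reference_completeness
    hom$raw_fraction <- hom$frac_match
    corr <- lapply(seq_len(nrow(hom)), function(i) {
      corrected_matching(part$n_queries, hom$n_match[i], hom$n_nomatch[i],
                         hom$p_intra[i])
    })
    hom$corrected_fraction <- vapply(corr, `[[`, numeric(1),
                                     "corrected_fraction")
    hom$corrected_percent <- vapply(corr, `[[`, numeric(1),
                                    "corrected_percent")
    headline$homology <- hom[, c("dataset", "n_match", "n_nomatch",
                                 "p_intra", "raw_fraction",
                                 "corrected_fraction", "corrected_percent")]
    headline$union_match <- part$union_matched
    headline$union_fraction <- part$union_fraction
  }

  excl <- NULL
  if ("exclusivity" %in% stages && !is.null(config$focal_species)) {
    fm <- gen_family_matrix(config)
    excl <- exclusivity_test(fm$matrix, config$focal_species,
                             seed = sub_seed(config$seed, "resample"))
    headline$n_exclusive <- excl$n_exclusive
    headline$exclusivity_z <- excl$z_score
  }

  headline$n_orphan_candidates <- length(remaining_ids)
  ledger <- new_ledger(steps, headline, notes)
  structure(list(
    ledger = ledger,
    metrics = metrics,
    partition = part,
    quality = quality,
    welch = welch,
    failure = fe,
    calls = calls,
    functional = fs,
    exclusivity = excl,
    truth = list(est = est$truth, copies = copies$truth,
                 expression = expr_truth)
  ), class = "orphan_pipeline")
}

#' Render an orphan ledger as machine tables and a readable report
#'
#' Writes the step table (TSV) and the headline numbers (JSON) when a
#' directory is given; in fixture mode (a ledger built with a
#' \code{printed} component) also produces a side-by-side
#' computed-vs-printed comparison flagging deviations beyond
#' \code{tolerance}.
#' @param ledger an \code{orphan_ledger}.
#' @param dir optional output directory (created if missing).
#' @param tolerance flag threshold for |computed - printed| (units of the
#'   reported values, i.e. percentage points for percent rows).
#' @return list: steps, headline, comparison (or NULL).
#' @export
render_report <- function(ledger, dir = NULL, tolerance = 0.5) {
  stopifnot(inherits(ledger, "orphan_ledger"))
  comparison <- NULL
  if (!is.null(ledger$printed)) {
    p <- ledger$printed
    h <- ledger$headline
    rows <- list()
    add <- function(metric, computed, printed) {
      if (is.null(computed) || is.null(printed)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        metric = metric, computed = as.numeric(computed),
        printed = as.numeric(printed),
        stringsAsFactors = FALSE)
    }
    add("failure_rate_percent", h$failure_rate_percent,
        p$failure_rate_percent)
    add("adjusted_unique", h$adjusted_unique, p$adjusted_unique)
    add("discovery_rate_percent", h$qa_discovery_percent,
        p$discovery_rate_percent)
    add("frac_retained_percent", round(100 * h$frac_retained, 1),
        p$frac_retained_percent)
    add("frac_retained_annotated_percent",
        round(100 * h$frac_retained_annotated, 1),
        p$frac_retained_annotated_percent)
    add("frac_retained_unannotated_percent",
        round_half_up(100 * h$frac_retained_unannotated),
        p$frac_retained_unannotated_percent)
    if (!is.null(p$corrected_percent) && !is.null(h$homology)) {
      for (ds in names(p$corrected_percent)) {
        i <- match(ds, h$homology$dataset)
        if (!is.na(i)) {
          add(paste0("corrected_percent_", ds),
              h$homology$corrected_percent[i], p$corrected_percent[[ds]])
        }
      }
    }
    if (length(rows)) {
      comparison <- do.call(rbind, rows)
      comparison$abs_diff <- abs(comparison$computed - comparison$printed)
      comparison$flagged <- comparison$abs_diff > tolerance
    }
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tab(ledger$steps, file.path(dir, "ledger_steps.tsv"))
    jsonlite::write_json(headline_for_json(ledger$headline),
                         file.path(dir, "headline.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
    if (!is.null(comparison)) {
      write_tab(comparison, file.path(dir, "comparison.tsv"))
    }
  }
  list(steps = ledger$steps, headline = ledger$headline,
       comparison = comparison)
}

headline_for_json <- function(h) h

#' Serialize a ledger to JSON
#' @param ledger an \code{orphan_ledger}.
#' @return a JSON string.
#' @export
ledger_to_json <- function(ledger) {
  stopifnot(inherits(ledger, "orphan_ledger"))
  jsonlite::toJSON(unclass(ledger), auto_unbox = TRUE, digits = NA,
                   dataframe = "columns", null = "null")
}

#' Rebuild a ledger from its JSON serialization
#' @param json a JSON string from \code{\link{ledger_to_json}}.
#' @return an \code{orphan_ledger} equal to the original.
#' @export
ledger_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  steps <- as.data.frame(x$steps, stringsAsFactors = FALSE)
  steps$n_considered <- as.integer(steps$n_considered)
  steps$n_removed <- as.integer(steps$n_removed)
  steps$n_remaining <- as.integer(steps$n_remaining)
  headline <- x$headline
  if (!is.null(headline$homology)) {
    headline$homology <- as.data.frame(headline$homology,
                                       stringsAsFactors = FALSE)
  }
  for (f in c("n_discounted", "adjusted_unique", "n_retained_unannotated",
              "n_orphan_candidates", "union_match", "n_exclusive",
              "qa_discovery_percent", "failure_rate_percent")) {
    if (!is.null(headline[[f]])) headline[[f]] <- as.integer(headline[[f]])
  }
  notes <- if (is.null(x$notes)) character(0) else as.character(x$notes)
  new_ledger(steps, headline, notes, printed = x$printed)
}

#' @export
print.orphan_ledger <- function(x, ...) {
  cat("Orphan accounting ledger\n")
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    cat(sprintf("  %-55s %6d considered, %6d removed, %6d remain\n",
                s$label, s$n_considered, s$n_removed, s$n_remaining))
  }
  h <- x$headline
  if (!is.null(h$unannotated_fraction)) {
    cat(sprintf("  unannotated fraction: %.1f%%\n",
                100 * h$unannotated_fraction))
  }
  if (!is.null(h$failure_rate)) {
    cat(sprintf("  assembly failure rate: %.1f%% -> adjusted unique %s\n",
                100 * h$failure_rate, h$adjusted_unique))
  }
  if (!is.null(h$frac_retained)) {
    cat(sprintf("  functional: %.1f%% of probed; %.1f%% of functional annotated\n",
                100 * h$frac_retained, 100 * h$frac_retained_annotated))
  }
  if (!is.null(h$homology)) {
    cat("  corrected homology (%):",
        paste(sprintf("%s=%s", h$homology$dataset,
                      h$homology$corrected_percent), collapse = ", "), "\n")
  }
  invisible(x)
}
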