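# Expression calling against a random-probe empirical null.
#
# For each condition the threshold is the 99.5% quantile of the random
# (no-target) probes' intensities, so each per-score test has an empirical
# false-positive rate of 0.005 (the construction behind the "0.5% FDR"
# label; it is a per-test rate, not a Benjamini-Hochberg FDR). A target's
# score in a condition is the median of its probes; it is called expressed
# when the score strictly exceeds the condition's threshold, and a target
# is functional when it is expressed in at least min_conditions conditions
# (default 2 of 12, i.e. "no evidence of expression in 11 or 12 conditions"
# inverted).

#' Empirical null threshold for one condition
#'
#' Quantile of the random-probe intensities by linear interpolation between
#' order statistics (\code{stats::quantile type 7}).
#' @param null_values random-probe intensities for one condition.
#' @param q quantile (default 0.995).
#' @return the threshold.
#' @export
null_threshold <- function(null_values, q = 0.995) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0) {
    stop("null_threshold: empty null set", call. = FALSE)
  }
  if (length(null_values) < 200) {
    warning("null_threshold: fewer than 200 null values (",
            length(null_values), "); threshold is noisy", call. = FALSE)
  }
  unname(stats::quantile(null_values, probs = q, type = 7, names = FALSE))
}

#' Call condition-dependent expression against the random-probe null
#'
#' @param probes long-format probe data frame: probe_id, target_id,
#'   condition_id, intensity, is_random (every condition needs at least one
#'   random probe; targets represented by a single probe use that probe's
#'   value as the median).
#' @param q null quantile for the per-condition threshold.
#' @param min_conditions minimum expressed conditions for a target to be
#'   called functional.
#' @return list of class \code{expression_calls}: \code{thresholds} (per
#'   condition), \code{calls} (per target x condition: median_intensity,
#'   threshold, expressed), \code{targets} (per target:
#'   n_conditions_expressed, functional).
#' @export
call_expression <- function(probes, q = 0.995, min_conditions = 2L) {
  need <- c("target_id", "condition_id", "intensity", "is_random")
  stopifnot(all(need %in% names(probes)))
  conds <- sort(unique(probes$condition_id))
  rnd <- probes[probes$is_random, , drop = FALSE]
  missing_null <- setdiff(conds, unique(rnd$condition_id))
  if (length(missing_null)) {
    stop("call_expression: conditions without random probes: ",
         paste(missing_null, collapse = ", "), call. = FALSE)
  }
  n_null_min <- min(table(rnd$condition_id))
  if (n_null_min < 200) {
    warning("call_expression: some condition has only ", n_null_min,
            " random probes; thresholds are noisy", call. = FALSE)
  }
  thresholds <- vapply(split(rnd$intensity, rnd$condition_id),
                       function(v) suppressWarnings(null_threshold(v, q)),
                       numeric(1))[conds]

  gene <- probes[!probes$is_random, , drop = FALSE]
  if (any(is.na(gene$target_id))) {
    stop("call_expression: non-random probe without target id",
         call. = FALSE)
  }
  med <- tapply(gene$intensity,
                list(target = gene$target_id, cond = gene$condition_id),
                stats::median)
  targets <- rownames(med)
  calls <- data.frame(
    target_id = rep(targets, times = ncol(med)),
    condition_id = rep(colnames(med), each = nrow(med)),
    median_intensity = as.vector(med),
    stringsAsFactors = FALSE
  )
  calls$threshold <- thresholds[calls$condition_id]
  calls$expressed <- !is.na(calls$median_intensity) &
    calls$median_intensity > calls$threshold
  n_expr <- rowSums(!is.na(med) & med > matrix(thresholds[colnames(med)],
                                               nrow = nrow(med),
                                               ncol = ncol(med),
                                               byrow = TRUE))
  target_df <- data.frame(
    target_id = targets,
    n_conditions_expressed = as.integer(n_expr),
    functional = as.integer(n_expr) >= min_conditions,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(thresholds = thresholds, calls = calls,
                 targets = target_df, q = q,
                 min_conditions = as.integer(min_conditions)),
            class = "expression_calls")
}

#' Per-condition positive call rate
#' @param calls an \code{expression_calls} object.
#' @return named numeric vector: fraction of targets called expressed in
#'   each condition.
#' @export
call_rate_by_condition <- function(calls) {
  stopifnot(inherits(calls, "expression_calls"))
  vapply(split(calls$calls$expressed, calls$calls$condition_id), mean,
         numeric(1))
}

#' Functional-classification summary (microarray validation table shape)
#'
#' Counts how many probed targets were retained (functional) and how many
#' of the retained carry an annotation, per source and in union.
#' @param calls an \code{expression_calls} object, or \code{NULL} when
#'   supplying counts directly.
#' @param annotation data frame with a target_id column plus one logical
#'   column per annotation source; or \code{NULL}.
#' @param n_probed,n_retained,n_retained_annotated direct-count mode, used
#'   when \code{calls} is \code{NULL}.
#' @param per_source optional named counts of retained-and-annotated per
#'   source (direct-count mode).
#' @return list: n_probed, n_retained, frac_retained,
#'   n_retained_annotated, frac_retained_annotated (of retained),
#'   n_retained_unannotated, frac_retained_unannotated, per_source data
#'   frame.
#' @export
functional_summary <- function(calls = NULL, annotation = NULL,
                               n_probed = NULL, n_retained = NULL,
                               n_retained_annotated = NULL,
                               per_source = NULL) {
  if (!is.null(calls)) {
    stopifnot(inherits(calls, "expression_calls"))
    t <- calls$targets
    n_probed <- nrow(t)
    n_retained <- sum(t$functional)
    src_counts <- integer(0)
    if (!is.null(annotation)) {
      stopifnot("target_id" %in% names(annotation))
      sources <- setdiff(names(annotation), "target_id")
      ann <- annotation[match(t$target_id, annotation$target_id), sources,
                        drop = FALSE]
      ann[is.na(ann)] <- FALSE
      src_counts <- vapply(sources, function(s) {
        sum(t$functional & ann[[s]])
      }, integer(1))
      n_retained_annotated <- sum(t$functional & rowSums(ann) > 0)
    } else {
      n_retained_annotated <- NA_integer_
    }
    per_source <- src_counts
  }
  if (is.null(n_probed) || is.null(n_retained)) {
    stop("functional_summary: supply either calls or counts", call. = FALSE)
  }
  out <- list(
    n_probed = n_probed,
    n_retained = n_retained,
    frac_retained = if (n_probed > 0) n_retained / n_probed else 0,
    n_retained_annotated = n_retained_annotated,
    frac_retained_annotated =
      if (!is.null(n_retained_annotated) && !is.na(n_retained_annotated) &&
          n_retained > 0) n_retained_annotated / n_retained else 0,
    per_source = if (length(per_source)) {
      data.frame(source = names(per_source),
                 n_retained_annotated = as.integer(per_source),
                 fraction_of_retained = if (n_retained > 0) {
                   as.integer(per_source) / n_retained
                 } else 0,
                 stringsAsFactors = FALSE)
    } else NULL
  )
  if (!is.null(n_retained_annotated) && !is.na(n_retained_annotated)) {
    out$n_retained_unannotated <- n_retained - n_retained_annotated
    out$frac_retained_unannotated <-
      if (n_retained > 0) out$n_retained_unannotated / n_retained else 0
  }
  out
}
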