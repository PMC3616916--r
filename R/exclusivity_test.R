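# Gene-family exclusivity: how many families are private to a focal set of
# species, compared against a resampling null of random same-size species
# combinations.

#' Families exclusive to a focal species set
#'
#' A family is exclusive iff it is present in at least one focal species
#' and in zero non-focal species.
#' @param matrix families x species presence matrix (0/1 or counts;
#'   anything > 0 counts as present), with row and column names.
#' @param focal character vector of focal species (non-empty subset of the
#'   columns).
#' @return list: \code{families} (exclusive family ids), \code{n_exclusive},
#'   and \code{spectrum} (data frame: number of focal species sharing each
#'   exclusive family, count of families).
#' @export
exclusive_families <- function(matrix, focal) {
  if (length(focal) == 0) stop("exclusive_families: empty focal set",
                               call. = FALSE)
  unknown <- setdiff(focal, colnames(matrix))
  if (length(unknown)) {
    stop("exclusive_families: unknown species id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pres <- matrix > 0
  nonfocal <- setdiff(colnames(matrix), focal)
  in_focal <- rowSums(pres[, focal, drop = FALSE])
  in_nonfocal <- if (length(nonfocal)) {
    rowSums(pres[, nonfocal, drop = FALSE])
  } else {
    rep(0L, nrow(matrix))
  }
  excl <- in_focal >= 1 & in_nonfocal == 0
  sharing <- in_focal[excl]
  tab <- table(factor(sharing, levels = seq_along(focal)))
  list(
    families = rownames(matrix)[excl],
    n_exclusive = sum(excl),
    spectrum = data.frame(n_focal_sharing = as.integer(names(tab)),
                          n_families = as.integer(tab))
  )
}

#' Resampling null for exclusive-family counts
#'
#' Draws \code{n_combinations} random k-species combinations (each
#' combination is a without-replacement sample of species; combinations may
#' repeat across draws unless \code{distinct = TRUE}) and records the
#' exclusive-family count of each. \code{exclude} drops a specific
#' combination (typically the observed focal set) from the null.
#' @param matrix families x species presence matrix.
#' @param k species per combination.
#' @param n_combinations number of draws (>= 2).
#' @param seed RNG seed.
#' @param distinct force all drawn combinations to be distinct.
#' @param exclude optional species set never drawn as a combination.
#' @return list: null_mean, null_sd (sample, n-1), counts, combinations.
#' @export
resample_null <- function(matrix, k = 5L, n_combinations = 30L, seed = 1L,
                          distinct = FALSE, exclude = NULL) {
  sp <- colnames(matrix)
  if (k > length(sp)) {
    stop("resample_null: k (", k, ") exceeds number of species (",
         length(sp), ")", call. = FALSE)
  }
  if (n_combinations < 2) {
    stop("resample_null: need at least 2 combinations", call. = FALSE)
  }
  n_avail <- choose(length(sp), k) - (!is.null(exclude))
  if (distinct && n_combinations > n_avail) {
    stop("resample_null: fewer than n_combinations distinct combinations ",
         "available", call. = FALSE)
  }
  excl_key <- if (!is.null(exclude)) paste(sort(exclude), collapse = "|")
  withr::with_seed(seed, {
    combos <- list()
    seen <- character(0)
    while (length(combos) < n_combinations) {
      cand <- sort(sample(sp, k))
      key <- paste(cand, collapse = "|")
      if (!is.null(excl_key) && key == excl_key) next
      if (distinct && key %in% seen) next
      seen <- c(seen, key)
      combos[[length(combos) + 1L]] <- cand
    }
    counts <- vapply(combos, function(cmb) {
      exclusive_families(matrix, cmb)$n_exclusive
    }, numeric(1))
    list(null_mean = mean(counts),
         null_sd = stats::sd(counts),
         counts = counts,
         combinations = combos)
  })
}

#' Compare an observed exclusive count to the resampling null
#' @param observed observed exclusive-family count.
#' @param null_mean,null_sd null summary from \code{\link{resample_null}}.
#' @return list: z_score (NA when null_sd is 0), within_one_sd.
#' @export
compare_to_null <- function(observed, null_mean, null_sd) {
  z <- if (null_sd == 0) NA_real_ else (observed - null_mean) / null_sd
  list(
    z_score = z,
    within_one_sd = if (null_sd == 0) {
      observed == null_mean
    } else {
      abs(z) <= 1
    }
  )
}

#' Exclusivity test for a focal species set
#'
#' Counts families exclusive to the focal set and compares the count to a
#' resampling null over random same-size combinations; by default the
#' focal combination itself is excluded from the null draws.
#' @param matrix families x species presence matrix.
#' @param focal focal species.
#' @param k combination size (defaults to the focal set size).
#' @param n_combinations,seed,distinct passed to
#'   \code{\link{resample_null}}.
#' @param include_focal allow the focal combination in the null draws.
#' @return list of class \code{exclusivity_result}: focal, n_exclusive,
#'   sharing spectrum, null_mean, null_sd, n_combinations, z_score,
#'   within_one_sd, and the total family count.
#' @export
exclusivity_test <- function(matrix, focal, k = length(focal),
                             n_combinations = 30L, seed = 1L,
                             distinct = FALSE, include_focal = FALSE) {
  obs <- exclusive_families(matrix, focal)
  null <- resample_null(matrix, k = k, n_combinations = n_combinations,
                        seed = seed, distinct = distinct,
                        exclude = if (include_focal) NULL else focal)
  cmp <- compare_to_null(obs$n_exclusive, null$null_mean, null$null_sd)
  structure(list(
    focal = focal,
    n_families = nrow(matrix),
    n_exclusive = obs$n_exclusive,
    exclusive_fraction = obs$n_exclusive / nrow(matrix),
    spectrum = obs$spectrum,
    null_mean = null$null_mean,
    null_sd = null$null_sd,
    n_combinations = n_combinations,
    z_score = cmp$z_score,
    within_one_sd = cmp$within_one_sd
  ), class = "exclusivity_result")
}

#' @export
print.exclusivity_result <- function(x, ...) {
  cat(sprintf(
    "Exclusivity: %d of %d families (%.1f%%) exclusive to {%s}\n",
    x$n_exclusive, x$n_families, 100 * x$exclusive_fraction,
    paste(x$focal, collapse = ", ")))
  cat(sprintf("  null over %d combinations: mean %.1f, sd %.1f, z = %s (%s 1 sd)\n",
              x$n_combinations, x$null_mean, x$null_sd,
              formatC(x$z_score, digits = 2, format = "f"),
              if (isTRUE(x$within_one_sd)) "within" else "outside"))
  invisible(x)
}
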