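# Synthetic inputs with known ground truth for every pipeline stage.
#
# Each generator is a pure function of a sim_config (including its seed):
# independent seed sub-streams are derived per generator so that, e.g., the
# EST set and the homology table produced from the same config agree on
# which ESTs are true homologs.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(
  outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
  c("A", "C", "G", "T"), paste0
))

#' Simulation configuration
#'
#' Bundles every knob the synthetic-data generators understand and validates
#' it once. Defaults emulate the study conditions of a normalized tick EST
#' collection: ~29% of reads with a detectable homolog, a reference whose
#' own transcripts match it 66.2% of the time, 12% read redundancy, GC near
#' 50% (annotated) vs 45.2% (unannotated), 4% of planted ORFs lacking a
#' start codon, a 12-condition array with nine probes per gene and an
#' N(0,1) random-probe null, and a 21% multi-copy fraction among matched
#' single-copy ortholog families with extra copies mostly in pairs.
#'
#' @param seed integer seed; the same seed gives byte-identical outputs.
#' @param n_ests number of EST reads to simulate.
#' @param orf_length_mean,orf_length_sd planted ORF length distribution (nt;
#'   rounded to codons, floor 60 nt so the planted ORF provably dominates
#'   any off-frame interval).
#' @param utr5_range,utr3_range integer length ranges for the flanking
#'   regions around the planted ORF.
#' @param gc_annotated,gc_unannotated GC fraction used when sampling bases
#'   for true-homolog vs orphan reads.
#' @param frac_no_start fraction of planted ORFs built without any in-frame
#'   ATG.
#' @param redundancy fraction of reads that are exact copies of an earlier
#'   transcript.
#' @param true_match_frac fraction of EST ids that truly have a homolog in
#'   the reference.
#' @param reference_completeness probability that a true homolog receives a
#'   filter-passing hit; the simulated analogue of the intraspecific
#'   matching rate of a reference dataset.
#' @param decoy_frac fraction of emitted hit rows that deliberately fail
#'   exactly one filter (e-value just above cutoff, or aligned length 32).
#' @param dataset_id label stamped on generated hits.
#' @param n_families number of matched conserved single-copy families.
#' @param frac_multicopy fraction of those families given >1 focal sequence.
#' @param copy_weights named weights over extra-copy counts for multi-copy
#'   families (names are the copy counts).
#' @param n_species,n_matrix_families,presence_prob gene-family
#'   presence/absence matrix dimensions and background presence rate.
#' @param focal_species optional species names forming a focal set for
#'   planted exclusivity.
#' @param n_exclusive number of families planted as exclusive to
#'   \code{focal_species}.
#' @param n_genes number of array targets; \code{NULL} (default) reuses the
#'   EST id universe so pipeline stages share ids.
#' @param n_conditions,probes_per_gene,n_random_probes array geometry.
#' @param effect_shift intensity shift (in null SD units) applied to
#'   expressed genes in every condition.
#' @param frac_expressed fraction of genes that are truly expressed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_ests = 1000L,
                       orf_length_mean = 230,
                       orf_length_sd = 80,
                       utr5_range = c(30L, 120L),
                       utr3_range = c(30L, 150L),
                       gc_annotated = 0.500,
                       gc_unannotated = 0.452,
                       frac_no_start = 0.04,
                       redundancy = 0.12,
                       true_match_frac = 0.29,
                       reference_completeness = 0.662,
                       decoy_frac = 0.10,
                       dataset_id = "ref",
                       n_families = 415L,
                       frac_multicopy = 0.21,
                       copy_weights = c("2" = 70, "3" = 12, "4" = 2, "5" = 2),
                       n_species = 14L,
                       n_matrix_families = 2000L,
                       presence_prob = 0.35,
                       focal_species = NULL,
                       n_exclusive = 0L,
                       n_genes = NULL,
                       n_conditions = 12L,
                       probes_per_gene = 9L,
                       n_random_probes = 11657L,
                       effect_shift = 4,
                       frac_expressed = 0.64) {
  cfg <- list(
    seed = seed, n_ests = n_ests,
    orf_length_mean = orf_length_mean, orf_length_sd = orf_length_sd,
    utr5_range = utr5_range, utr3_range = utr3_range,
    gc_annotated = gc_annotated, gc_unannotated = gc_unannotated,
    frac_no_start = frac_no_start, redundancy = redundancy,
    true_match_frac = true_match_frac,
    reference_completeness = reference_completeness,
    decoy_frac = decoy_frac, dataset_id = dataset_id,
    n_families = n_families, frac_multicopy = frac_multicopy,
    copy_weights = copy_weights,
    n_species = n_species, n_matrix_families = n_matrix_families,
    presence_prob = presence_prob, focal_species = focal_species,
    n_exclusive = n_exclusive, n_genes = n_genes,
    n_conditions = n_conditions, probes_per_gene = probes_per_gene,
    n_random_probes = n_random_probes, effect_shift = effect_shift,
    frac_expressed = frac_expressed
  )
  fracs <- c("gc_annotated", "gc_unannotated", "frac_no_start", "redundancy",
             "true_match_frac", "reference_completeness", "decoy_frac",
             "frac_multicopy", "presence_prob", "frac_expressed")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: field '", f, "' must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  counts <- c("n_ests", "n_families", "n_species", "n_matrix_families",
              "n_conditions", "probes_per_gene", "n_random_probes")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v)) {
      stop("sim_config: field '", f, "' must be a positive integer count",
           call. = FALSE)
    }
    cfg[[f]] <- as.integer(v)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("sim_config: field 'seed' must be a single integer", call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  if (cfg$orf_length_mean <= 0 || cfg$orf_length_sd < 0) {
    stop("sim_config: field 'orf_length_mean'/'orf_length_sd' invalid",
         call. = FALSE)
  }
  if (!is.null(cfg$n_genes)) {
    if (cfg$n_genes < 1) stop("sim_config: field 'n_genes' must be positive",
                              call. = FALSE)
    cfg$n_genes <- as.integer(cfg$n_genes)
  }
  if (cfg$n_exclusive > 0 && is.null(cfg$focal_species)) {
    stop("sim_config: field 'n_exclusive' requires 'focal_species'",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Derive a reproducible sub-seed (< 2^31) for a named generator stream.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.double(seed) * 10007 + h * 97) %% 2147483647
}

est_ids <- function(n) sprintf("est_%05d", seq_len(n))

#' True homolog ids for a configuration
#'
#' Exactly \code{round(true_match_frac * n_ests)} ids, drawn from a seed
#' sub-stream shared by the EST and homology generators.
#' @param config a \code{sim_config}.
#' @return character vector of EST ids.
#' @export
homolog_ids <- function(config) {
  ids <- est_ids(config$n_ests)
  n_hom <- round(config$true_match_frac * config$n_ests)
  withr::with_seed(sub_seed(config$seed, "homologs"),
                   sort(sample(ids, n_hom)))
}

# -- EST set -----------------------------------------------------------------

gc_base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                G = gc / 2, T = (1 - gc) / 2)

random_bases <- function(k, gc) {
  sample(c("A", "C", "G", "T"), k, replace = TRUE, prob = gc_base_probs(gc))
}

# Flank with a stop codon every 10 nt whose frame cycles (offsets 7, 17, 27
# hit frames 1, 2, 0), so no flank harbours a long ORF in any frame.
flank_seq <- function(len, gc) {
  if (len <= 0) return("")
  n_block <- ceiling(len / 10)
  blocks <- vapply(seq_len(n_block), function(i) {
    paste0(paste(random_bases(7L, gc), collapse = ""), "TAA")
  }, character(1))
  substr(paste(blocks, collapse = ""), 1L, len)
}

codon_weights <- function(codons, gc) {
  p <- gc_base_probs(gc)
  vapply(codons, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, numeric(1))
}

# Stop-free codon run; first codon ATG when with_start. Every 5th codon
# pair is a fixed motif planting stop codons in the two other reading
# frames ("CTAAGC" contains TAA at offset +1, "ACTAAG" at offset +2).
# Combined with the 60-nt floor on planted ORFs and the stop-dense flanks
# (a stop every 30 nt in each frame), any competing interval in another
# frame is < 60 nt, so the planted in-frame ORF is the longest interval
# across frames.
orf_codons <- function(n_codons, gc, with_start) {
  pool <- setdiff(ALL_CODONS, STOP_CODONS)
  if (!with_start) pool <- setdiff(pool, "ATG")
  w <- codon_weights(pool, gc)
  out <- sample(pool, n_codons, replace = TRUE, prob = w)
  if (with_start) out[1L] <- "ATG"
  j <- seq.int(4L, length.out = max(0L, (n_codons - 4L) %/% 5L), by = 5L)
  j <- j[j + 1L <= n_codons]
  for (i in seq_along(j)) {
    if (i %% 2L == 1L) {
      out[j[i]] <- "CTA"; out[j[i] + 1L] <- "AGC"
    } else {
      out[j[i]] <- "ACT"; out[j[i] + 1L] <- "AAG"
    }
  }
  out
}

#' Generate a synthetic EST set with planted ORFs
#'
#' Each unique transcript carries one planted maximal ORF (stop-bounded in
#' its own frame, with periodic off-frame stops inside) whose length is
#' drawn from the configured normal; a \code{frac_no_start} share of ORFs is
#' built without any in-frame ATG. GC content differs between true-homolog
#' ("annotated") and orphan reads. A \code{redundancy} share of reads are
#' exact copies of earlier transcripts.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth}: a data frame of per-EST planted ORF coordinates (0-based
#'   half-open), frame, start-codon presence, homolog status and duplicate
#'   source, plus the homolog id set.
#' @export
gen_est_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  homs <- homolog_ids(config)
  withr::with_seed(sub_seed(config$seed, "ests"), {
    n <- config$n_ests
    ids <- est_ids(n)
    n_dup <- round(config$redundancy * n)
    n_unique <- n - n_dup
    if (n_unique < 1L) stop("sim_config: field 'redundancy' leaves no unique reads",
                            call. = FALSE)
    dup_src <- c(rep(NA_integer_, n_unique),
                 if (n_dup > 0) sample.int(n_unique, n_dup, replace = TRUE))

    seqs <- character(n)
    orf_start <- orf_end <- integer(n)
    frame <- integer(n)
    has_start <- logical(n)
    gc_used <- numeric(n)
    for (i in seq_len(n_unique)) {
      gc <- if (ids[i] %in% homs) config$gc_annotated else config$gc_unannotated
      n_codons <- max(20L, as.integer(round(
        rnorm(1, config$orf_length_mean, config$orf_length_sd) / 3)))
      with_start <- runif(1) >= config$frac_no_start
      utr5 <- sample(config$utr5_range[1]:config$utr5_range[2], 1L)
      utr3 <- sample(config$utr3_range[1]:config$utr3_range[2], 1L)
      left <- flank_seq(utr5, gc)
      substr(left, utr5 - 2L, utr5) <- "TAA"  # in-frame stop bounding the ORF
      orf <- paste(orf_codons(n_codons, gc, with_start), collapse = "")
      seqs[i] <- paste0(left, orf, "TAA", flank_seq(utr3, gc))
      orf_start[i] <- utr5
      orf_end[i] <- utr5 + 3L * n_codons
      frame[i] <- utr5 %% 3L + 1L
      has_start[i] <- with_start
      gc_used[i] <- gc
    }
    if (n_dup > 0) {
      src <- dup_src[(n_unique + 1L):n]
      seqs[(n_unique + 1L):n] <- seqs[src]
      orf_start[(n_unique + 1L):n] <- orf_start[src]
      orf_end[(n_unique + 1L):n] <- orf_end[src]
      frame[(n_unique + 1L):n] <- frame[src]
      has_start[(n_unique + 1L):n] <- has_start[src]
      gc_used[(n_unique + 1L):n] <- gc_used[src]
    }
    names(seqs) <- ids
    truth <- data.frame(
      est_id = ids,
      orf_start = orf_start,
      orf_end = orf_end,
      frame = frame,
      has_start = has_start,
      gc_target = gc_used,
      is_homolog = ids %in% homs,
      duplicate_of = ifelse(is.na(dup_src), NA_character_, ids[dup_src]),
      stringsAsFactors = FALSE
    )
    list(sequences = seqs,
         truth = list(ests = truth, homologs = homs))
  })
}

# -- Homology hit table ------------------------------------------------------

#' Generate a synthetic homology hit table (tabular BLAST dialect)
#'
#' True homologs receive one or more filter-passing hits with probability
#' \code{reference_completeness}; non-homologs receive none. A
#' \code{decoy_frac} share of emitted rows deliberately fails exactly one
#' filter (e-value in (1e-5, 1e-3] or aligned length 32) to exercise
#' boundary handling downstream.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{hits} (data frame in 12-column tabular order plus
#'   \code{dataset_id}) and \code{truth} (homolog ids, detected ids).
#' @export
gen_homology_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  homs <- homolog_ids(config)
  ids <- est_ids(config$n_ests)
  withr::with_seed(sub_seed(config$seed, "hits"), {
    detected <- homs[runif(length(homs)) < config$reference_completeness]
    n_hits_each <- 1L + rpois(length(detected), 0.4)
    q <- rep(detected, n_hits_each)
    n_pass <- length(q)
    pass <- hit_rows(q, log10_e = runif(n_pass, -60, -6),
                     len = sample(33:200, n_pass, replace = TRUE),
                     dataset_id = config$dataset_id)
    n_decoy <- if (config$decoy_frac >= 1) {
      stop("sim_config: field 'decoy_frac' must be < 1", call. = FALSE)
    } else {
      round(config$decoy_frac / (1 - config$decoy_frac) * n_pass)
    }
    decoys <- NULL
    if (n_decoy > 0) {
      dq <- sample(ids, n_decoy, replace = TRUE)
      weak_e <- runif(n_decoy) < 0.5
      decoys <- hit_rows(
        dq,
        log10_e = ifelse(weak_e, runif(n_decoy, -4.99, -3), runif(n_decoy, -60, -6)),
        len = ifelse(weak_e, sample(33:200, n_decoy, replace = TRUE), 32L),
        dataset_id = config$dataset_id
      )
    }
    hits <- rbind(pass, decoys)
    if (is.null(hits)) hits <- empty_hit_df(config$dataset_id)
    if (nrow(hits) > 0) hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
    rownames(hits) <- NULL
    list(hits = hits,
         truth = list(homologs = homs, detected = sort(unique(detected))))
  })
}

empty_hit_df <- function(dataset_id) {
  data.frame(
    query_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), aligned_length = integer(0),
    mismatches = integer(0), gap_opens = integer(0),
    q_start = integer(0), q_end = integer(0),
    s_start = integer(0), s_end = integer(0),
    e_value = numeric(0), bit_score = numeric(0),
    dataset_id = character(0), stringsAsFactors = FALSE
  )
}

hit_rows <- function(query_id, log10_e, len, dataset_id) {
  n <- length(query_id)
  if (n == 0) return(NULL)
  data.frame(
    query_id = query_id,
    subject_id = sprintf("ref_%06d", sample.int(500000L, n, replace = TRUE)),
    percent_identity = round(runif(n, 40, 99.9), 2),
    aligned_length = as.integer(len),
    mismatches = sample(0:40, n, replace = TRUE),
    gap_opens = sample(0:5, n, replace = TRUE),
    q_start = 1L,
    q_end = as.integer(len) * 3L,
    s_start = 1L,
    s_end = as.integer(len),
    e_value = 10^log10_e,
    bit_score = round(pmax(30, -log10(10^log10_e) * 2.2 + rnorm(n, 0, 3)), 1),
    dataset_id = dataset_id,
    stringsAsFactors = FALSE
  )
}

# -- Copy-number scenario ----------------------------------------------------

#' Generate a conserved single-copy ortholog copy-number table
#'
#' A \code{frac_multicopy} share of families gets more than one focal
#' sequence (copy counts drawn from \code{copy_weights}; by default mostly
#' 2, some 3-5); extra copies are the planted assembly failures.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{table} (family_id, n_copies) and \code{truth}
#'   (multi-copy family ids, their copy counts, and the injected failure
#'   rate implied by the planted counts).
#' @export
gen_copy_number_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, "copies"), {
    nf <- config$n_families
    fam <- sprintf("fam_%05d", seq_len(nf))
    n_multi <- round(config$frac_multicopy * nf)
    copies <- rep(1L, nf)
    multi_idx <- integer(0)
    if (n_multi > 0) {
      multi_idx <- sort(sample.int(nf, n_multi))
      copies[multi_idx] <- sample(as.integer(names(config$copy_weights)),
                                  n_multi, replace = TRUE,
                                  prob = config$copy_weights)
    }
    injected <- if (n_multi > 0) {
      (n_multi / nf) * (n_multi / sum(copies[multi_idx]))
    } else 0
    list(
      table = data.frame(family_id = fam, n_copies = copies,
                         stringsAsFactors = FALSE),
      truth = list(multicopy_families = fam[multi_idx],
                   n_copies = copies[multi_idx],
                   n_extra_copies = sum(copies[multi_idx] - 1L),
                   injected_rate = injected)
    )
  })
}

#' Fraction of multi-copy families needed to plant a target failure rate
#'
#' The failure-rate statistic converges to frac_multicopy divided by the
#' mean copy count of multi-copy families; inverting gives the
#' frac_multicopy that plants a target rate under given copy weights.
#' @param rate target failure rate.
#' @param copy_weights named weights over copy counts.
#' @return fraction in [0, 1].
#' @export
frac_multicopy_for_rate <- function(rate, copy_weights = c("2" = 70, "3" = 12,
                                                           "4" = 2, "5" = 2)) {
  m <- sum(as.numeric(names(copy_weights)) * copy_weights) / sum(copy_weights)
  f <- rate * m
  if (f > 1) stop("target rate not attainable with these copy weights",
                  call. = FALSE)
  f
}

# -- Gene-family presence/absence matrix -------------------------------------

#' Generate a gene-family presence/absence matrix across species
#'
#' Background presence is Bernoulli per cell; empty families are given one
#' random species. When \code{focal_species} and \code{n_exclusive} are set,
#' exactly that many families are planted as exclusive to the focal set and
#' every other family is forced to have at least one non-focal occurrence,
#' so the truth set equals the exclusive set.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{matrix} (families x species 0/1 integer matrix)
#'   and \code{truth} (planted exclusive family ids).
#' @export
gen_family_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, "families"), {
    nf <- config$n_matrix_families
    ns <- config$n_species
    fam <- sprintf("gf_%05d", seq_len(nf))
    sp <- sprintf("sp_%02d", seq_len(ns))
    m <- matrix(rbinom(nf * ns, 1L, config$presence_prob), nrow = nf,
                dimnames = list(fam, sp))
    empty <- which(rowSums(m) == 0)
    if (length(empty)) {
      m[cbind(empty, sample.int(ns, length(empty), replace = TRUE))] <- 1L
    }
    planted <- character(0)
    if (config$n_exclusive > 0) {
      focal <- config$focal_species
      if (!all(focal %in% sp)) {
        stop("sim_config: 'focal_species' must be among the generated ",
             "species ids (", paste(sp[1:min(3, ns)], collapse = ", "),
             ", ...)", call. = FALSE)
      }
      nonfocal <- setdiff(sp, focal)
      if (config$n_exclusive > nf) {
        stop("sim_config: 'n_exclusive' exceeds 'n_matrix_families'",
             call. = FALSE)
      }
      pl <- sort(sample.int(nf, config$n_exclusive))
      planted <- fam[pl]
      m[pl, nonfocal] <- 0L
      for (i in pl) {
        pres <- rbinom(length(focal), 1L, 0.5)
        if (sum(pres) == 0) pres[sample.int(length(focal), 1L)] <- 1L
        m[i, focal] <- pres
      }
      # non-planted families must not be focal-exclusive by accident
      if (length(nonfocal)) {
        others <- setdiff(seq_len(nf), pl)
        acc <- others[rowSums(m[others, nonfocal, drop = FALSE]) == 0]
        if (length(acc)) {
          m[cbind(acc, match(sample(nonfocal, length(acc), replace = TRUE), sp))] <- 1L
        }
      }
    }
    list(matrix = m, truth = list(exclusive_families = planted))
  })
}

# -- Probe intensity matrix --------------------------------------------------

#' Generate a long-format probe intensity matrix with random-probe null
#'
#' Random probes are N(0,1) per condition (the empirical null); each
#' expressed gene's probes are shifted by \code{effect_shift} in every
#' condition. Unexpressed genes' probes are pure null draws.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{probes} (data frame: probe_id, target_id,
#'   condition_id, intensity, is_random) and \code{truth} (expressed target
#'   ids).
#' @export
gen_probe_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, "probes"), {
    targets <- if (is.null(config$n_genes)) {
      est_ids(config$n_ests)
    } else {
      sprintf("gene_%05d", seq_len(config$n_genes))
    }
    ng <- length(targets)
    nc <- config$n_conditions
    ppg <- config$probes_per_gene
    conds <- sprintf("cond_%02d", seq_len(nc))
    n_expr <- round(config$frac_expressed * ng)
    expressed <- if (n_expr > 0) sort(sample(targets, n_expr)) else character(0)

    gene_target <- rep(targets, each = ppg)
    gene_probe <- paste0(gene_target, "_p", rep(seq_len(ppg), times = ng))
    n_gene_rows <- ng * ppg * nc
    gene_df <- data.frame(
      probe_id = rep(gene_probe, times = nc),
      target_id = rep(gene_target, times = nc),
      condition_id = rep(conds, each = ng * ppg),
      intensity = rnorm(n_gene_rows) +
        ifelse(rep(gene_target, times = nc) %in% expressed,
               config$effect_shift, 0),
      is_random = FALSE,
      stringsAsFactors = FALSE
    )
    nr <- config$n_random_probes
    rnd_probe <- sprintf("rnd_%05d", seq_len(nr))
    rnd_df <- data.frame(
      probe_id = rep(rnd_probe, times = nc),
      target_id = NA_character_,
      condition_id = rep(conds, each = nr),
      intensity = rnorm(nr * nc),
      is_random = TRUE,
      stringsAsFactors = FALSE
    )
    list(probes = rbind(gene_df, rnd_df),
         truth = list(expressed = expressed))
  })
}
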