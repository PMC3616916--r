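# Hit filtering, partitioning, e-value/taxon summaries, and the
# reference-completeness discount correction.

mk_hits <- function(e, len, query = NULL, dataset = "d1") {
  n <- length(e)
  if (n == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      aligned_length = integer(0), e_value = numeric(0),
                      bit_score = numeric(0), dataset_id = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    query_id = if (is.null(query)) sprintf("q%03d", seq_len(n)) else query,
    subject_id = sprintf("s%03d", seq_len(n)),
    aligned_length = as.integer(len),
    e_value = e,
    bit_score = 50,
    dataset_id = dataset,
    stringsAsFactors = FALSE
  )
}

test_that("filter_hits keeps both boundaries inclusive and each filter bites alone", {
  h <- mk_hits(e = c(1e-5, 2e-5, 1e-9, 1e-9),
               len = c(33, 100, 32, 33))
  kept <- filter_hits(h)
  expect_equal(kept$query_id, c("q001", "q004"))
})

test_that("filter_hits equals the brute-force row scan on decoy-laden tables", {
  cfg <- sim_config(seed = 13, n_ests = 400, decoy_frac = 0.25)
  gh <- gen_homology_table(cfg)
  got <- filter_hits(gh$hits)
  want <- bf_filter(gh$hits)
  expect_equal(got, want)
  # randomised boundary sweep
  withr::with_seed(14, {
    for (i in 1:10) {
      h <- mk_hits(e = 10^runif(50, -8, -3),
                   len = sample(30:36, 50, TRUE))
      expect_equal(filter_hits(h), bf_filter(h))
    }
  })
})

test_that("partition marginals and contingencies agree with a per-query scan", {
  withr::with_seed(15, {
    for (rep in 1:5) {
      n_q <- sample(c(50, 200, 1000), 1)
      universe <- sprintf("q%04d", seq_len(n_q))
      n_h <- sample(50:300, 1)
      hits <- data.frame(
        query_id = sample(universe, n_h, TRUE),
        subject_id = "s",
        aligned_length = 50L,
        e_value = 1e-20,
        bit_score = 40,
        dataset_id = sample(c("A", "B"), n_h, TRUE)
      )
      part <- partition_queries(universe, hits)
      for (ds in c("A", "B")) {
        want <- sum(universe %in% hits$query_id[hits$dataset_id == ds])
        expect_equal(part$marginals$n_match[part$marginals$dataset == ds],
                     want)
        expect_equal(part$marginals$n_match[part$marginals$dataset == ds] +
                       part$marginals$n_nomatch[part$marginals$dataset == ds],
                     n_q)
      }
      expect_equal(part$union_matched,
                   length(unique(hits$query_id)))
      tab <- part$contingency[["A x B"]]
      expect_equal(sum(tab), n_q)
      in_a <- universe %in% hits$query_id[hits$dataset_id == "A"]
      in_b <- universe %in% hits$query_id[hits$dataset_id == "B"]
      expect_equal(unname(tab["TRUE", "TRUE"]), sum(in_a & in_b))
      expect_equal(unname(tab["FALSE", "TRUE"]), sum(!in_a & in_b))
    }
  })
})

test_that("partition handles the no-hit and unknown-query cases", {
  universe <- c("q1", "q2", "q3")
  part <- partition_queries(universe, mk_hits(numeric(0), integer(0)))
  expect_equal(part$union_matched, 0L)
  expect_equal(nrow(part$marginals), 0)
  bad <- mk_hits(1e-9, 50, query = "nope")
  expect_error(partition_queries(universe, bad), "outside the universe")
})

test_that("partition flags equal the truth homolog set under a complete reference", {
  cfg <- sim_config(seed = 16, n_ests = 500, reference_completeness = 1)
  gh <- gen_homology_table(cfg)
  part <- partition_queries(orphanest:::est_ids(500), filter_hits(gh$hits))
  matched <- rownames(part$flags)[part$flags[[1]]]
  expect_setequal(matched, gh$truth$homologs)
})

test_that("partition reproduces worked marginal fractions from counts", {
  # 3,592 matches of 14,310 queries -> 25.1%
  universe <- sprintf("q%05d", 1:14310)
  hits <- data.frame(query_id = universe[1:3592], subject_id = "s",
                     aligned_length = 50L, e_value = 1e-9, bit_score = 40,
                     dataset_id = "peptides")
  part <- partition_queries(universe, hits)
  expect_equal(part$marginals$n_match, 3592L)
  expect_equal(part$marginals$n_nomatch, 10718L)
  expect_equal(round(100 * part$marginals$frac_match, 1), 25.1)
})

test_that("evalue_spectrum uses best hits and survives e = 0", {
  h <- mk_hits(e = rep(1e-60, 4), len = 50)
  sp <- evalue_spectrum(h)
  expect_equal(sp$frac_le_1e10, 1)
  expect_equal(sp$frac_le_1e50, 1)

  h2 <- mk_hits(e = c(1e-6, 1e-12, 1e-55, 1e-80), len = 50)
  sp2 <- evalue_spectrum(h2)
  expect_equal(sp2$frac_le_1e10, 0.75)
  expect_equal(sp2$frac_le_1e50, 0.5)

  h3 <- mk_hits(e = c(0, 1e-6), len = 50)
  sp3 <- evalue_spectrum(h3)
  expect_equal(sp3$frac_le_1e50, 0.5)
  expect_equal(sum(sp3$histogram$n), 2)
  # per-query best: a weak extra hit must not change the spectrum
  h4 <- rbind(h2, transform(h2[1, ], e_value = 1e-3, subject_id = "weak"))
  expect_equal(evalue_spectrum(h4)$frac_le_1e10, 0.75)
})

test_that("taxon_breakdown tallies best-hit subjects with nested groups", {
  h <- mk_hits(e = c(1e-10, 1e-20, 1e-30), len = 50)
  tm <- data.frame(subject_id = h$subject_id,
                   taxon = c("Ixodes", "Coxiellaceae", "OtherBacteria"))
  gm <- data.frame(taxon = tm$taxon,
                   group = c("Acari", "Bacteria", "Bacteria"))
  tb <- taxon_breakdown(h, tm, gm)
  expect_equal(sum(tb$by_taxon$n), 3)
  expect_equal(tb$by_group$n[tb$by_group$group == "Bacteria"], 2L)
  # single-taxon map -> 100% one group
  tm1 <- data.frame(subject_id = h$subject_id, taxon = "only")
  expect_equal(taxon_breakdown(h, tm1)$by_taxon$fraction, 1)
  # brute-force tally on random labels
  withr::with_seed(17, {
    h5 <- mk_hits(e = 10^runif(40, -40, -6), len = 50,
                  query = sprintf("q%02d", sample(1:15, 40, TRUE)))
    h5$subject_id <- sprintf("s%02d", sample(1:8, 40, TRUE))
    tm5 <- data.frame(subject_id = sprintf("s%02d", 1:8),
                      taxon = sample(c("x", "y", "z"), 8, TRUE))
    tb5 <- taxon_breakdown(h5, tm5)
    bf <- table(vapply(unique(h5$query_id), function(q) {
      hh <- h5[h5$query_id == q, ]
      hh <- hh[order(hh$e_value, -hh$bit_score, hh$subject_id), ]
      tm5$taxon[tm5$subject_id == hh$subject_id[1]]
    }, character(1)))
    expect_equal(setNames(tb5$by_taxon$n, tb5$by_taxon$taxon),
                 setNames(as.integer(bf), names(bf)))
  })
})

test_that("intraspecific_rate accepts counts or self-hit tables", {
  expect_equal(round(intraspecific_rate(128738, 194460), 3), 0.662)
  expect_equal(intraspecific_rate(10, 10), 1)
  self <- mk_hits(e = rep(1e-9, 3), len = 50,
                  query = c("r1", "r1", "r2"))
  expect_equal(intraspecific_rate(self, 4), 0.5)
  expect_error(intraspecific_rate(5, 0), "no reference queries")
})

test_that("corrected_matching reproduces the three worked corrected values", {
  c1 <- corrected_matching(14310, 3592, 10718, 0.662)
  expect_equal(c1$corrected_percent, 34)
  # the published contigs marginals sum to 14,309, one short of the stated
  # universe: accepted with a warning, computed with the values as given
  expect_warning(c2 <- corrected_matching(14310, 2365, 11944, 0.373),
                 "as given")
  expect_equal(c2$corrected_percent, 35)
  c3 <- corrected_matching(14310, 4124, 10186, 0.541)
  expect_equal(c3$corrected_percent, 43)
  # a perfect reference leaves the raw fraction untouched
  cp <- corrected_matching(1000, 300, 700, 1)
  expect_equal(cp$corrected_fraction, 0.3)
  expect_warning(corrected_matching(1000, 299, 700, 1), "as given")
  expect_error(corrected_matching(1000, 0, 1000, 0), "undefined")
})

test_that("corrected_matching never falls below the raw fraction", {
  withr::with_seed(18, {
    for (i in 1:50) {
      n <- sample(100:10000, 1)
      m <- sample(0:n, 1)
      p <- runif(1)
      if (m == 0 && p == 0) next
      cm <- corrected_matching(n, m, n - m, p)
      expect_gte(cm$corrected_fraction, cm$raw_fraction)
      if (p < 1 && m < n) expect_gt(cm$corrected_fraction, cm$raw_fraction)
    }
  })
})

test_that("the discount correction brackets the true homolog fraction", {
  # under the censoring model the estimator sits between raw (~ f*c) and f
  f <- 0.29
  cfg <- sim_config(seed = 19, n_ests = 10000, true_match_frac = f,
                    reference_completeness = 0.66)
  gh <- gen_homology_table(cfg)
  n_match <- length(unique(filter_hits(gh$hits)$query_id))
  cm <- corrected_matching(10000, n_match, 10000 - n_match, 0.66)
  expect_gt(cm$corrected_fraction, cm$raw_fraction)
  expect_lt(cm$corrected_fraction, f)
  se_raw <- sqrt(f * 0.66 * (1 - f * 0.66) / 10000)
  expect_lt(abs(cm$raw_fraction - f * 0.66), 3 * se_raw)
})

test_that("hit tables round-trip through the tabular format", {
  cfg <- sim_config(seed = 20, n_ests = 50)
  gh <- gen_homology_table(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(gh$hits, path)
  back <- read_blast_hits(path)
  expect_equal(back$query_id, gh$hits$query_id)
  expect_equal(back$e_value, gh$hits$e_value)
  expect_equal(back$dataset_id, gh$hits$dataset_id)
  expect_equal(nrow(filter_hits(back)), nrow(filter_hits(gh$hits)))
})
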