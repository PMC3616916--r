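# Sequence-quality metrics: ORF finder, GC content, group summaries,
# Welch's test.

test_that("find_orf handles canonical single-codon and stop-free cases", {
  orf <- find_orf("ATGAAATAG")
  expect_equal(orf$frame, 1L)
  expect_equal(orf$start, 0L)
  expect_equal(orf$end, 6L)
  expect_equal(orf$orf_length_nt, 6L)
  expect_true(orf$has_start_codon)

  orf <- find_orf("CCCCCC")
  expect_equal(orf$orf_length_nt, 6L)
  expect_false(orf$has_start_codon)

  expect_error(find_orf("AT"), "shorter than 3")
  expect_error(find_orf("ATGXXA"), "outside")
})

test_that("find_orf agrees with the interval-enumeration oracle exhaustively", {
  # every sequence of length 3..6, forward frames
  for (len in 3:6) {
    for (s in all_sequences(len)) {
      expect_orf_matches_oracle(s)
    }
  }
})

test_that("find_orf agrees with the oracle on random longer reads, both frame sets", {
  withr::with_seed(11, {
    for (i in 1:150) {
      s <- random_dna(sample(7:60, 1), with_n = i %% 5 == 0)
      expect_orf_matches_oracle(s)
      expect_orf_matches_oracle(s, frames = c(1, 2, 3, -1, -2, -3))
    }
    # longer reads as in real EST data
    for (i in 1:20) {
      s <- random_dna(300)
      expect_orf_matches_oracle(s)
      expect_orf_matches_oracle(s, frames = c(1, 2, 3, -1, -2, -3))
    }
  })
})

test_that("ORF length is bounded by read length and monotone under stop-free extension", {
  withr::with_seed(12, {
    for (i in 1:60) {
      s <- random_dna(sample(10:120, 1))
      orf <- find_orf(s)
      expect_lte(orf$orf_length_nt, nchar(s))
      # appending Gs can never create a stop codon in any frame
      ext <- find_orf(paste0(s, "GGGGGG"))
      expect_gte(ext$orf_length_nt, orf$orf_length_nt)
    }
  })
})

test_that("gc_content follows its definition and excludes N", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GCNNN"), 100)  # N out of the denominator
  expect_error(gc_content("NNNN"), "undefined")
  expect_error(gc_content(""), "empty")
})

test_that("summarize_quality reproduces group means and conserves sizes", {
  metrics <- data.frame(
    est_id = sprintf("e%02d", 1:6),
    length_nt = c(600, 590, 595, 540, 530, 538),
    orf_length_nt = c(340, 345, 334.7, 180, 190, 180.2),
    has_start = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    gc_percent = c(50, 51, 49, 45, 46, 44.6)
  )
  part <- setNames(rep(c("annotated", "unannotated"), each = 3),
                   metrics$est_id)
  s <- summarize_quality(metrics, part)
  expect_setequal(s$group, c("annotated", "unannotated"))
  expect_equal(sum(s$n), nrow(metrics))
  ann <- s[s$group == "annotated", ]
  una <- s[s$group == "unannotated", ]
  expect_equal(ann$mean_orf_length_nt, mean(c(340, 345, 334.7)))
  expect_equal(una$n_without_start, 1L)
  # per-EST values matching the worked example's published means reproduce
  # those means exactly
  m2 <- data.frame(est_id = c("a1", "a2", "u1", "u2"),
                   length_nt = c(594.9, 594.9, 536.0, 536.0),
                   orf_length_nt = c(339.9, 339.9, 183.4, 183.4),
                   has_start = TRUE, gc_percent = c(50, 50, 45.2, 45.2))
  p2 <- setNames(c("annotated", "annotated", "unannotated", "unannotated"),
                 m2$est_id)
  s2 <- summarize_quality(m2, p2)
  expect_equal(s2$mean_orf_length_nt[s2$group == "annotated"], 339.9)
  expect_equal(s2$mean_orf_length_nt[s2$group == "unannotated"], 183.4)
  expect_equal(s2$mean_gc_percent[s2$group == "unannotated"], 45.2)
  # identical groups give identical summaries
  m3 <- rbind(m2[1:2, ], transform(m2[1:2, ], est_id = c("b1", "b2")))
  p3 <- setNames(c("g1", "g1", "g2", "g2"), m3$est_id)
  s3 <- summarize_quality(m3, p3)
  expect_equal(s3[1, -1], s3[2, -1], ignore_attr = TRUE)

  expect_error(summarize_quality(metrics, part[-1]), "cover")
})

test_that("a planted ORF-length group difference is recovered in the summaries", {
  # two synthetic sets with different planted ORF-length means stand in for
  # the annotated/unannotated contrast
  cfg_a <- sim_config(seed = 61, n_ests = 400, orf_length_mean = 340,
                      redundancy = 0)
  cfg_u <- sim_config(seed = 62, n_ests = 400, orf_length_mean = 185,
                      redundancy = 0)
  est_a <- gen_est_set(cfg_a)
  est_u <- gen_est_set(cfg_u)
  seqs <- c(setNames(est_a$sequences, paste0("a_", names(est_a$sequences))),
            setNames(est_u$sequences, paste0("u_", names(est_u$sequences))))
  metrics <- est_metrics(seqs)
  part <- setNames(ifelse(grepl("^a_", metrics$est_id), "annotated",
                          "unannotated"), metrics$est_id)
  s <- summarize_quality(metrics, part)
  # group means equal the truth-bundle means exactly (finder recovers the
  # planted ORFs)
  expect_equal(s$mean_orf_length_nt[s$group == "annotated"],
               mean(est_a$truth$ests$orf_end - est_a$truth$ests$orf_start))
  expect_equal(s$mean_orf_length_nt[s$group == "unannotated"],
               mean(est_u$truth$ests$orf_end - est_u$truth$ests$orf_start))
  # and sit within 2 SE of the configured means (the 60-nt floor biases the
  # shorter group up by ~2 nt, well inside the band)
  se2 <- 2 * 80 / sqrt(400)
  expect_lt(abs(s$mean_orf_length_nt[s$group == "annotated"] - 340), se2)
  expect_lt(abs(s$mean_orf_length_nt[s$group == "unannotated"] - 185),
            se2 + 2.1)
  w <- welch_t(metrics$orf_length_nt[part == "annotated"],
               metrics$orf_length_nt[part == "unannotated"])
  expect_gt(w$t_statistic, 10)
  expect_lt(w$p_value, 1e-10)
})

test_that("welch_t matches hand-computed closed-form values", {
  # a = (1,2,3), b = (1,2,3,4,5): mean 2 vs 3, var 1 vs 2.5
  # t = -1 / sqrt(1/3 + 2.5/5) = -1.095445
  # df = (1/3 + 1/2)^2 / ((1/3)^2/2 + (1/2)^2/4) = 5.882353
  w <- welch_t(c(1, 2, 3), c(1, 2, 3, 4, 5))
  expect_equal(w$t_statistic, -1 / sqrt(1 / 3 + 0.5), tolerance = 1e-10)
  expect_equal(w$degrees_of_freedom,
               (1 / 3 + 1 / 2)^2 / ((1 / 3)^2 / 2 + (1 / 2)^2 / 4),
               tolerance = 1e-10)
  expect_true(w$p_value > 0 && w$p_value < 1)

  w0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t_statistic, 0)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(2, 2, 2), c(3, 3)), "zero variance")
})

test_that("welch_t type-I error rate is calibrated at the nominal level", {
  n_rep <- 1000
  withr::with_seed(99, {
    p <- replicate(n_rep, {
      welch_t(rnorm(15), rnorm(15))$p_value
    })
  })
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})
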