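# Generators: configuration validation, determinism, truth consistency,
# planted structure.

test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_no_start = 1.2), "frac_no_start")
  expect_error(sim_config(redundancy = -0.1), "redundancy")
  expect_error(sim_config(n_ests = 0), "n_ests")
  expect_error(sim_config(n_conditions = 2.5), "n_conditions")
  expect_error(sim_config(n_exclusive = 5), "focal_species")
})

test_that("generators are pure functions of the config (determinism)", {
  cfg <- sim_config(seed = 1, n_ests = 60, n_families = 50,
                    n_matrix_families = 40, n_random_probes = 250,
                    n_genes = 20)
  expect_identical(gen_est_set(cfg), gen_est_set(cfg))
  expect_identical(gen_homology_table(cfg), gen_homology_table(cfg))
  expect_identical(gen_copy_number_scenario(cfg),
                   gen_copy_number_scenario(cfg))
  expect_identical(gen_family_matrix(cfg), gen_family_matrix(cfg))
  expect_identical(gen_probe_matrix(cfg), gen_probe_matrix(cfg))
  # written FASTA is byte-identical across two runs
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_est_fasta(gen_est_set(cfg)$sequences, f1)
  write_est_fasta(gen_est_set(cfg)$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("planted ORFs honour frac_no_start and are recovered by the finder", {
  cfg0 <- sim_config(seed = 1, n_ests = 10, frac_no_start = 0,
                     redundancy = 0)
  est0 <- gen_est_set(cfg0)
  expect_true(all(est0$truth$ests$has_start))

  cfg <- sim_config(seed = 7, n_ests = 200, frac_no_start = 0.1)
  est <- gen_est_set(cfg)
  tr <- est$truth$ests
  n_no_start <- sum(!tr$has_start)
  se <- sqrt(200 * 0.1 * 0.9)
  expect_lt(abs(n_no_start - 20), 3 * se)
  # truth recount: finder agrees with every planted label
  m <- est_metrics(est$sequences)
  expect_identical(m$est_id, tr$est_id)
  expect_equal(m$orf_length_nt, tr$orf_end - tr$orf_start)
  expect_equal(m$frame, tr$frame)
  expect_equal(m$has_start, tr$has_start)
  # duplicates are exact copies of their source
  dup <- !is.na(tr$duplicate_of)
  expect_equal(sum(dup), round(0.12 * 200))
  expect_identical(unname(est$sequences[tr$est_id[dup]]),
                   unname(est$sequences[tr$duplicate_of[dup]]))
})

test_that("EST GC groups differ in the planted direction", {
  cfg <- sim_config(seed = 3, n_ests = 400, gc_annotated = 0.55,
                    gc_unannotated = 0.40)
  est <- gen_est_set(cfg)
  m <- est_metrics(est$sequences)
  hom <- est$truth$ests$is_homolog
  expect_gt(mean(m$gc_percent[hom]), mean(m$gc_percent[!hom]) + 2)
})

test_that("homology generator matches its contract at the boundaries", {
  cfg <- sim_config(seed = 3, n_ests = 100, true_match_frac = 0.5,
                    reference_completeness = 1)
  gh <- gen_homology_table(cfg)
  expect_length(gh$truth$homologs, 50)
  surviving <- unique(filter_hits(gh$hits)$query_id)
  expect_setequal(surviving, gh$truth$homologs)

  cfg0 <- sim_config(seed = 3, n_ests = 100, reference_completeness = 0)
  gh0 <- gen_homology_table(cfg0)
  expect_equal(nrow(filter_hits(gh0$hits)), 0)
  # decoys are a fraction of emitted rows, and pass rows never exist here,
  # so the table is empty but well-formed
  expect_named(gh0$hits)
  # with passing rows present, decoys appear and never survive filtering
  cfgd <- sim_config(seed = 3, n_ests = 200, decoy_frac = 0.3,
                     reference_completeness = 1)
  ghd <- gen_homology_table(cfgd)
  expect_gt(nrow(ghd$hits), nrow(filter_hits(ghd$hits)))
  expect_setequal(unique(filter_hits(ghd$hits)$query_id),
                  ghd$truth$detected)
})

test_that("realized fractions sit within 3 binomial SE at large n", {
  cfg <- sim_config(seed = 5, n_ests = 10000, true_match_frac = 0.5,
                    reference_completeness = 0.662)
  gh <- gen_homology_table(cfg)
  detected <- unique(filter_hits(gh$hits)$query_id)
  expect_setequal(detected, gh$truth$detected)
  n_hom <- length(gh$truth$homologs)
  frac <- length(detected) / n_hom
  se <- sqrt(0.662 * (1 - 0.662) / n_hom)
  expect_lt(abs(frac - 0.662), 3 * se)
})

test_that("copy-number scenario plants the advertised multi-copy structure", {
  cfg1 <- sim_config(seed = 2, n_families = 100, frac_multicopy = 0)
  sc1 <- gen_copy_number_scenario(cfg1)
  expect_true(all(sc1$table$n_copies == 1))
  expect_equal(sc1$truth$injected_rate, 0)

  cfg <- sim_config(seed = 2, n_families = 415, frac_multicopy = 0.21)
  sc <- gen_copy_number_scenario(cfg)
  expect_equal(nrow(sc$table), 415)
  expect_equal(length(sc$truth$multicopy_families), round(0.21 * 415))
  expect_true(all(sc$table$n_copies[sc$table$family_id %in%
                                      sc$truth$multicopy_families] > 1))
  # downstream estimator recovers the planted rate exactly on the noiseless
  # table (the table realises the truth)
  fe <- failure_rate(sc$table)
  expect_equal(fe$failure_rate, sc$truth$injected_rate)
})

test_that("family matrix plants exclusivity exactly and keeps rows non-empty", {
  focal <- sprintf("sp_%02d", 1:5)
  cfg <- sim_config(seed = 4, n_species = 14, n_matrix_families = 500,
                    focal_species = focal, n_exclusive = 50)
  fm <- gen_family_matrix(cfg)
  expect_length(fm$truth$exclusive_families, 50)
  expect_true(all(rowSums(fm$matrix) > 0))
  got <- exclusive_families(fm$matrix, focal)
  expect_setequal(got$families, fm$truth$exclusive_families)

  # single species, every family present
  cfg1 <- sim_config(seed = 4, n_species = 1, n_matrix_families = 30,
                     presence_prob = 1)
  fm1 <- gen_family_matrix(cfg1)
  expect_equal(exclusive_families(fm1$matrix, "sp_01")$n_exclusive, 30)
})

test_that("probe matrix separates expressed genes and keeps truth ids in the file", {
  cfg <- sim_config(seed = 6, n_genes = 100, n_random_probes = 300,
                    frac_expressed = 0.5, effect_shift = 6)
  pm <- gen_probe_matrix(cfg)
  expect_length(pm$truth$expressed, 50)
  targets <- unique(pm$probes$target_id[!pm$probes$is_random])
  expect_true(all(pm$truth$expressed %in% targets))
  expect_equal(sum(pm$probes$is_random),
               300 * cfg$n_conditions)
  calls <- call_expression(pm$probes)
  fn <- calls$targets
  expect_true(all(fn$functional[fn$target_id %in% pm$truth$expressed]))
  # a huge shift on every gene makes everything functional
  cfg2 <- sim_config(seed = 6, n_genes = 30, n_random_probes = 300,
                     frac_expressed = 1, effect_shift = 30)
  pm2 <- gen_probe_matrix(cfg2)
  calls2 <- call_expression(pm2$probes)
  expect_true(all(calls2$targets$functional))
})
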