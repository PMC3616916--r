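#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: an EST set with planted ORFs, a homology hit table, a
# single-copy-ortholog copy-number table, a 14-species gene-family matrix,
# and a 12-condition probe-intensity matrix — all from one seeded
# configuration, with their truth bundles.

suppressPackageStartupMessages(library(orphanest))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 42, n_ests = 2000, n_random_probes = 11657)
saveRDS <- NULL  # everything below is plain text

est <- gen_est_set(cfg)
write_est_fasta(est$sequences, file.path(out, "ests.fasta"))
write_truth_json(est$truth$ests, file.path(out, "est_truth.json"))

gh <- gen_homology_table(cfg)
write_hits_tsv(gh$hits, file.path(out, "hits.tsv"))
write_truth_json(gh$truth, file.path(out, "hit_truth.json"))

cn <- gen_copy_number_scenario(cfg)
write_tab(cn$table, file.path(out, "copy_number.tsv"))
write_truth_json(cn$truth, file.path(out, "copy_truth.json"))

fm <- gen_family_matrix(cfg)
write_family_matrix(fm$matrix, file.path(out, "family_matrix.tsv"))

pm <- gen_probe_matrix(cfg)
write_tab(pm$probes, file.path(out, "probes.tsv"))
write_truth_json(pm$truth, file.path(out, "probe_truth.json"))

cat("Simulated", length(est$sequences), "ESTs (",
    sum(est$truth$ests$is_homolog), "true homologs,",
    sum(!is.na(est$truth$ests$duplicate_of)), "duplicate reads ),",
    nrow(gh$hits), "hit rows,", nrow(cn$table), "ortholog families,",
    nrow(fm$matrix), "gene families x", ncol(fm$matrix), "species,",
    nrow(pm$probes), "probe rows ->", out, "\n")
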