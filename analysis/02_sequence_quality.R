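#!/usr/bin/env Rscript
# Sequence-quality audit: compare ORF length, read length, start-codon
# presence and GC content between annotated and unannotated ESTs, with
# Welch's t-test on ORF lengths. Expects 01_simulate.R to have run.

suppressPackageStartupMessages(library(orphanest))

out <- "results"
seqs <- read_est_fasta("results/sim/ests.fasta")
hits <- filter_hits(read_blast_hits("results/sim/hits.tsv"))
annotated <- unique(hits$query_id)

metrics <- est_metrics(seqs)
partition <- setNames(
  ifelse(names(seqs) %in% annotated, "annotated", "unannotated"),
  names(seqs))
quality <- summarize_quality(metrics, partition)
write_tab(metrics, file.path(out, "est_metrics.tsv"))
write_tab(quality, file.path(out, "quality_summary.tsv"))

w <- welch_t(metrics$orf_length_nt[partition[metrics$est_id] == "annotated"],
             metrics$orf_length_nt[partition[metrics$est_id] == "unannotated"])

# ORF-length histogram data (annotated vs unannotated), 50-nt bins
breaks <- seq(0, max(metrics$orf_length_nt) + 50, by = 50)
hist_df <- do.call(rbind, lapply(split(metrics$orf_length_nt,
                                       partition[metrics$est_id]),
                                 function(v) {
  data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
             n = as.integer(table(cut(v, breaks, include.lowest = TRUE))))
}))
hist_df$group <- rep(names(split(metrics$orf_length_nt,
                                 partition[metrics$est_id])),
                     each = length(breaks) - 1)
write_tab(hist_df, file.path(out, "orf_length_histogram.tsv"))

cat("Quality summary (", nrow(metrics), "ESTs ):\n")
print(quality, row.names = FALSE)
cat(sprintf("Welch's t on ORF length: t = %.2f, df = %.0f, p = %.3g\n",
            w$t_statistic, w$degrees_of_freedom, w$p_value))
cat(sprintf("Start-codon-less unannotated ESTs: %d\n",
            quality$n_without_start[quality$group == "unannotated"]))
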