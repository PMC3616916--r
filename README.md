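# orphanest

Auditing the unannotated ("orphan") fraction of an assembled EST
collection, and partitioning it among four explanatory sources.

## The problem

Transcriptome surveys of understudied taxa — ticks, mites, crustaceans,
and other lineages far from the densely sequenced insects — routinely find
that most assembled sequences match nothing in reference databases. Before
reading that as lineage-specific biology, four mundane explanations must
be quantified: poor **sequence quality**, **assembly failure** (one gene
split into several "unique" sequences), **non-function** (cloned introns
or frame-shifted fragments), and **taxonomic isolation** (real genes whose
relatives are missing from, or fragmented in, the references).
`orphanest` implements each audit, a stepwise accounting ledger that
chains them, a gene-family exclusivity resampling test, and a seeded
synthetic-data module that generates every input with known ground truth.

The three bespoke statistics at the core:

* **Assembly failure rate.** With *n* matched conserved single-copy
  ortholog families, *m* of them multi-copy holding *s* focal sequences,
  `failure_rate = (m/n) · (m/s)`; a unique count *U* is discounted to
  `U − round(U · rate)`.
* **Reference-completeness discount.** A reference whose own transcripts
  match it at rate *p* cannot be blamed for all failures:
  `corrected = M / (N − (N−M)(1−p))` for *M* matches among *N* queries.
* **Empirical-null expression calling.** Per condition, the threshold is
  the 99.5% quantile of random-probe intensities; a target is expressed
  when its median probe intensity strictly exceeds it, and functional when
  expressed in ≥ 2 of 12 conditions.

See `vignettes/orphan-partitioning.Rmd` for the full model descriptions,
parameter defaults, and design notes.

## Worked example

The package ships the printed count tables of a tick EST study as a
fixture (`inst/extdata/printed_counts.yaml`); every derived number below
is recomputed from those inputs at run time.

```r
library(orphanest)
counts <- read_counts_yaml(system.file("extdata", "printed_counts.yaml",
                                       package = "orphanest"))
ledger_from_counts(counts)
#> Orphan accounting ledger
#>   input unique ESTs                                        14310 considered,      0 removed,  14310 remain
#>   annotated by homology search                             14310 considered,   4118 removed,  10192 remain
#>   unannotated lacking a start codon                        10192 considered,    398 removed,   9794 remain
#>   unannotated without expression support (or unprobed)      9794 considered,   4542 removed,   5252 remain
#>   unannotated fraction: 71.2%
#>   assembly failure rate: 9.2% -> adjusted unique 12995
#>   functional: 64.2% of probed; 41.4% of functional annotated
#>   corrected homology (%): ests=NA, peptides=34, contigs=35, singletons=43
```

Reading the output: 71.2% of the 14,310 unique ESTs are unannotated; 398
of those lack any in-frame start codon and are attributed to sequence
quality; under-assembly inflates the unique count by ~9.2% (adjusted total
12,995); of the ESTs probed on the array, 64.2% show condition-dependent
expression, and 5,252 functional ESTs (59% of the functional set) remain
unannotated; correcting the per-dataset homology for reference
incompleteness raises matching from 16–29% raw to 34–43%. The `ests`
dataset has no intraspecific rate, hence no corrected value.

The same machinery runs end to end on synthetic data with known truth:

```r
cfg <- sim_config(seed = 42, n_ests = 2000)
pp  <- run_pipeline(cfg)            # generators + all four audits
pp$ledger
```

The numbered scripts under `analysis/` walk through the stages —
`01_simulate.R` writes the synthetic inputs (FASTA, hit TSV, copy-number,
family matrix, probe intensities) under `results/sim/`, and
`02`–`07` run the quality, assembly, homology, expression, exclusivity and
ledger analyses over them, writing tables under `results/`.

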