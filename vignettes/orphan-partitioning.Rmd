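---
title: "Partitioning orphan transcripts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning orphan transcripts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanest)
```

## The problem

When an EST collection for an understudied organism — the motivating case
is a hard-tick transcriptome — is annotated against reference protein and
genome databases, a large majority of the assembled sequences often find no
homolog at all. Before attributing these "orphans" to lineage-specific
biology, four mundane explanations have to be quantified and discounted:

1. **Sequence quality** — short or truncated reads with degenerate open
   reading frames;
2. **Assembly failure** — one gene split across several "unique"
   sequences, inflating the apparent gene count;
3. **Non-function** — cloned introns, untranscribed fragments or
   frame-shifted sequences that are not real genes;
4. **Taxonomic isolation** — real genes whose relatives are simply absent
   from (or fragmented in) the reference databases.

`orphanest` implements each audit as a small set of composable functions,
plus a stepwise accounting ledger that chains them, and a seeded
synthetic-data module that generates every input with known ground truth so
that every estimator can be tested end to end without any external
download.

## The four audits

### 1. Sequence quality (`find_orf`, `gc_content`, `summarize_quality`, `welch_t`)

An ORF is defined **stop-to-stop**: the longest maximal stop-free in-frame
interval, in 0-based half-open coordinates, with start-codon presence
reported separately. This separation matters because the screen that
actually removes sequences is "no in-frame ATG anywhere in the ORF", while
ORF *length* is only compared between groups. The default frame set is the
three forward frames — the emulated libraries are directionally cloned and
sequenced with single-pass 5' reads, so the mRNA strand is known — and a
six-frame search is available via the `frames` argument. Ties between
equally long intervals are broken by frame order (1, 2, 3, −1, −2, −3),
then by smaller start; codons containing `N` are treated as neither stop
nor start. GC content is `100·(G+C)/(A+C+G+T)` with `N` excluded from the
denominator. Group comparisons use Welch's unequal-variance *t* with
Welch–Satterthwaite degrees of freedom (delegated to `stats::t.test`).

### 2. Assembly failure (`failure_rate`, `adjust_unique_count`)

Families of conserved orthologs that are single-copy in *every* reference
species should appear at most once in a focal transcriptome; extra copies
are, under the audit's working assumption, under-assembly artifacts rather
than lineage-specific duplications. With $n$ matched single-copy families,
$m$ of them multi-copy, holding $s$ focal sequences in total, the failure
rate is the product of two proportions:

$$\widehat{r} \;=\; \underbrace{\frac{m}{n}}_{\text{families affected}}
\times \underbrace{\frac{m}{s}}_{\text{real genes among their sequences}}$$

and a unique-sequence count $U$ is discounted to
$U - \mathrm{round}(U\widehat{r})$, with halves rounded away from zero (the
worked example's counts 415/86/194 give $\widehat r = 9.19\%$ and
$14{,}310 \times \widehat r = 1{,}314.6 \to 1{,}315$, hence 12,995). The
companion accounting functions report the gene-discovery rate as
unique/reads — the definition validated by the 796-read QA sub-assembly
(787 unique → 99%) — and emit both candidate redundancy ratios
(contigs/reads and 1 − unique/reads) as unasserted notes, because the two
definitions disagree on the worked example's totals.

### 3. Expression support (`null_threshold`, `call_expression`)

Arrays carrying thousands of *random* probes (sequence composition matched,
no genomic target) provide an empirical null per condition: the threshold
is the 99.5% quantile of the random-probe intensities (type-7 linear
interpolation between order statistics), so each per-score test has an
empirical false-positive rate of 0.005. This is the construction sometimes
labelled a "0.5% FDR"; it is a per-test rate, not a Benjamini–Hochberg
FDR, and the package labels it accordingly. A target's score in a
condition is the **median** of its probes (a single-probe target uses that
probe's value); a score must *strictly* exceed the threshold to count as
expressed — a null value exactly at the quantile is not a detection — and
a target is *functional* when expressed in at least `min_conditions`
conditions (default 2 of 12, i.e. the complement of "no evidence of
expression in 11 or 12 conditions").

A calibration subtlety: the 0.005 rate is a property of a *score* whose
null distribution matches the thresholded one. With nine independent null
probes per target the median of nine is far less dispersed than a single
probe, and the realized false-call rate is essentially zero — which is the
design intent of probe replication. The pure-null calibration tests
therefore use one probe per target, where score and threshold nulls
coincide exactly.

### 4. Taxonomic isolation (`filter_hits`, `partition_queries`, `corrected_matching`)

Hits are filtered at e-value ≤ 1e−5 and aligned length ≥ 33 residues (both
boundaries inclusive); a query is matched in a dataset iff at least one
hit survives, and the cross-dataset union counts each query once. A
reference dataset that only matches a fraction $p$ of the reference
species' *own* transcripts (the intraspecific matching rate) cannot be
expected to match foreign queries it does not even represent. The discount
correction removes that share of the failures from the denominator:

$$\text{corrected} \;=\;
\frac{M}{N - (N-M)\,(1-p)}$$

with $M$ matches among $N$ queries. The direction of the discount —
discard $(N-M)(1-p)$, not $(N-M)\,p$ — is fixed by verification: it is
the only reading that reproduces all three worked corrected values
(34%, 35%, 43%) from the published marginals and intraspecific rates
(66.2%, 37.3%, 54.1%). The corrected fraction always satisfies
corrected ≥ raw, with equality iff $p = 1$.

**Known bias.** Under the generative model used for testing (each query a
true homolog with probability $f$, each homolog detected with probability
$c$, and $p$ estimated by $c$), the corrected estimator converges to
$f/(1 + f(1-c))$: it under-corrects by $O(f^2(1-c))$, because the discount
is applied only to observed non-matchers instead of to the whole universe.
At small homolog fractions the bias is negligible against sampling noise
(the recovery tests run at $f = 0.05$, $n = 10{,}000$, where the bias is
< 0.0015 against a ≈ 0.003 standard error); at $f \approx 0.3$ it is a
few percentage points, and the property the package asserts there is the
provable bracket raw ≤ corrected ≤ $f$. Practically: the correction is a
conservative lower-bound repair, not an unbiased completeness estimator.

### Exclusivity resampling (`exclusive_families`, `resample_null`)

A gene family is *exclusive* to a focal species set when it is present in
at least one focal species and absent from every other species in the
matrix. The observed exclusive count is compared to the mean and sample
(n−1) SD of the counts over random same-size species combinations
(default 30 draws of 5 of 14). Combinations may repeat across draws unless
`distinct = TRUE`; the focal combination itself is excluded from the null
by default (`include_focal = FALSE`) since including the observed set in
its own null can only shrink the contrast. Both choices are flags because
the emulated protocol does not specify them.

### The ledger (`ledger_from_counts`, `run_pipeline`)

The accounting chain is: total → unannotated (homology) → minus
start-codon-less (quality) → minus expression-unsupported (function) =
functional orphan candidates; the assembly-failure discount adjusts the
unique-sequence total in parallel rather than removing specific ids. Every
step records considered/removed/remaining and the invariant
`remaining = considered − removed` is enforced at construction. In fixture
mode the published values travel alongside as a `printed` component and
`render_report` emits a side-by-side comparison — published tables that
are internally inconsistent (a start-codon count printed three ways; match
marginals that sum one short of the universe) are reported beside the
recomputed values, never forced to agree. `corrected_matching` likewise
accepts marginals that do not sum to the stated universe with a warning
rather than an error, computing with the values as given.

## The synthetic-data generators

All generators are pure functions of one `sim_config` (same seed ⇒
byte-identical output), with per-generator seed sub-streams so that the
EST set and the hit table built from the same config agree on which ESTs
are true homologs. Defaults emulate the motivating study's conditions:
29% true homolog fraction, 66.2% reference completeness, 12% read
redundancy, GC 50% vs 45.2% for homolog vs orphan reads, 4% of planted
ORFs without a start codon, 415 matched single-copy families of which 21%
multi-copy with extra copies mostly in pairs (70:12:2:2 over copy counts
2–5), and a 12-condition array with nine probes per gene and 11,657
random probes.

Design specifics worth knowing:

* **Planted ORFs are provably maximal.** Each read is built as
  flank + stop + ORF + stop + flank. Flanks carry a stop codon every 10 nt
  with cycling frame offsets (so every frame sees a stop within 30 nt),
  and every fifth codon pair inside the ORF is a fixed motif planting
  stops in the two other reading frames; with the planted ORF floored at
  60 nt, no competing interval in any frame can reach it. The cost is
  composition: fixed motifs and stop-dense flanks pull realized GC a few
  points below nominal, so tests assert the GC *contrast* between groups,
  not the nominal values.
* **Start-codon omission is independent of homology status** (a
  `frac_no_start` Bernoulli per transcript). Real annotated sequences
  almost always have starts; the independence keeps the truth recount
  simple and does not affect any estimator under test.
* **Homology truth is per read id.** Duplicate reads copy their source
  sequence but draw detectability independently, emulating fragmentary
  reads of one transcript with different alignable spans. Exactly
  `round(true_match_frac · n_ests)` ids are homologs.
* **Decoy hits** make up 10% of emitted rows and fail exactly one filter —
  e-value in (1e−5, 1e−3] with good length, or aligned length 32 with
  good e-value — to exercise both boundaries; the passing-hit e-values are
  sampled strictly below the cutoff so filter correctness is attributable.
* **Random-probe intensities are standard normal** per condition. Any
  continuous null suffices for testing the quantile rule, and the normal
  gives closed-form quantiles for oracle tests; no claim is made about
  real array score distributions, normalization scales, or the
  composition modelling of real random probes.
* **What the generators do not emulate:** chromatograms and base-calling
  error, realistic codon usage, correlated probe effects, phylogenetic
  structure in the family matrix, or e-value/score joint distributions of
  real alignments. Passing tests demonstrate estimator correctness under
  the stated models, not robustness to those real-data features.

## Numerical and degenerate-input choices

* Quantiles: type 7 (R default linear interpolation); thresholds from
  fewer than 200 null values warn.
* Rounding of discounted counts: half away from zero (`floor(x + 0.5)`),
  required to reproduce the worked 1,315.
* Best-hit ties: lowest e-value, then highest bit score, then
  lexicographically smallest subject id (the emulated protocol is silent;
  the rule is total, so results are deterministic).
* Zero e-values are floored at 1e−180 for log-binning only; filtering and
  best-hit selection use them exactly.
* A read with no stop-free codon in any requested frame yields a
  zero-length ORF call at the first requested frame's offset rather than
  an error; reads shorter than one codon, all-`N` GC denominators, empty
  copy-number tables and empty null sets are errors.
* `resample_null` requires at least 2 combinations and `k` ≤ number of
  species; a null SD of exactly 0 yields `z = NA` with the
  within-one-SD verdict decided by equality.

## Problem sizes in the test suite

The suite checks the ORF finder exhaustively against a brute-force
interval enumerator over all 4³–4⁶ sequences plus randomized longer reads
(to 300 nt, both frame sets); calibration tests run at 10,000 queries /
10,000 families / 50,000 random probes with 3-standard-error bands
derived analytically (binomial noise plus, for expression calling,
empirical-quantile propagation); the exclusivity null is verified against
exhaustive enumeration of all 20 three-of-six combinations. These sizes
were chosen so each statistical check has power against its planted truth
while the whole suite stays comfortably interactive.

## Limitations

* The assembly-failure statistic cannot distinguish true lineage-specific
  duplications from under-assembly; it inherits that assumption.
* The discount correction is first-order (see the bias note above) and
  treats the intraspecific matching rate as exchangeable with
  cross-species detectability.
* Expression-based function calls are conservative: genes expressed only
  under unsampled conditions are classified non-functional.
* Fixture mode reproduces published arithmetic from published inputs; it
  cannot validate the upstream sequence-level steps (base calling,
  assembly, alignment) that produced those counts.
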