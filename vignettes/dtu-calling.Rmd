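---
title: "Calling differential transcript usage with bootstrap reproducibility filters"
author: "bootDTU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential transcript usage with bootstrap reproducibility filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Differential transcript usage (DTU) is a change, between two conditions, in
the relative proportions of a gene's isoforms — orthogonal to differential
gene expression, which concerns the total. `bootDTU` tests for DTU directly
on transcript abundance estimates, as produced by alignment-free quantifiers
such as Salmon and Kallisto, without returning to the reads.

The statistical engine is the G-test of independence, applied without
continuity corrections to tables of counts summed across the replicates of
each condition:

* **Gene level.** For each gene, the isoforms × conditions table is tested
  with `G = 2 Σ O ln(O/E)`, expectations from the row/column marginals, and
  `df = (r − 1)(c − 1)` where `r` counts the isoform rows with a nonzero
  total. Under the null of unchanged isoform ratios, `G` is asymptotically
  chi-squared. A significant gene-level `G` says the gene's isoform mix
  changed, without naming the isoform.
* **Transcript level.** Each transcript is tested against the pooled
  abundance of its sibling isoforms in a 2 × 2 table (`df = 1`). For a
  2-isoform gene the two tables coincide up to row order, so gene-level and
  transcript-level results are identical there — a property the test suite
  asserts.

Cells may be non-integer: length-normalised abundances (TPM) are accepted
after rescaling to a typical library size (`scaleTpmToCounts()`), because
count-based tests are badly under-powered on raw per-million values. Zero
cells contribute `0 · ln 0 := 0`; isoform rows that are all-zero after
summing are dropped before the degrees of freedom are counted, and a table
left with fewer than two nonzero rows is degenerate — the feature is marked
ineligible rather than crashing the run.

The two test families (all eligible genes; all eligible transcripts) are
corrected by Benjamini–Hochberg independently of each other, matching the two
independent result tables the package emits. The effect size is the
difference in isoform proportion, `Dprop = prop_B − prop_A` per transcript,
and the largest `|Dprop|` among a gene's isoforms at the gene level. The
effect filter is applied *after* the FDR correction, on the full tested
family: a feature can be highly significant yet rejected as `small_effect`,
and filtering does not shrink the correction family.

## Pre-filtering and eligibility

Isoform-ratio changes are only defined for genes expressed in both
conditions with at least two detected isoforms. Detection is judged on the
*mean* abundance across a condition's replicates, compared against a
threshold; means are invariant to the replication level, which keeps results
comparable when replicate numbers differ between studies. At threshold 0
every transcript counts as detected and eligibility depends only on the
annotation and on zero/nonzero expression. "At least two isoforms detected"
is read across the union of conditions — an isoform present only in one
condition is a genuine usage change, not a reason to skip the gene — and
"expressed in both conditions" is read as a positive gene total in each
condition.

Each feature receives exactly one eligibility record with the first failing
reason in the fixed order `unannotated`, `absent_in_a_condition`,
`single_isoform`, `below_abundance_threshold`.

The default detection threshold is 5 counts: a small positive floor that
suppresses ratio noise from barely-expressed isoforms in routine use.
Benchmark-style analyses (including this package's own acceptance checks)
set it to 0 so that no abundance pre-filter biases the comparison.

## Reproducibility filters

Point estimates from alignment-free quantifiers hide the read-assignment
uncertainty that their bootstrap iterations expose. The package therefore
screens every provisional call twice:

* **Quantification reproducibility (Qrep).** For each of `nQuantDraws`
  (default 100) draws, one bootstrap iteration index is sampled uniformly,
  independently per replicate, and the *entire* pipeline — detection,
  eligibility, both tests, BH, effect classification — is re-run on the
  drawn counts. The score is the fraction of draws reproducing a positive
  call; the default threshold demands > 0.95. Eligibility is deliberately
  recomputed from each draw's counts (rather than frozen at the point
  estimate), so a feature whose testability itself is unstable scores low.
  BH is performed within each draw, because a "positive DTU classification"
  is only defined through the full decision rule.
* **Inter-replicate reproducibility (Rrep).** The pipeline is re-run on
  every cross-condition one-vs-one replicate pair — all `n_a × n_b`
  combinations, e.g. 9 runs for 3 vs 3 — and the score is the fraction of
  pairs reproducing the call; the default threshold demands > 0.85 (at 3 vs
  3, at least 8 of 9 pairs). One-vs-one pairs are the smallest subsets that
  still cross the condition boundary; larger subset schemes would blur the
  per-replicate attribution and are not offered.

Both filters can only remove calls, never add them; a screened-out feature
records `low_quant_reproducibility` or `low_replicate_reproducibility` (in
that order of checking). When bootstraps are missing or a condition has a
single replicate, the respective filter is skipped with a warning and its
score column is `NA` — absent evidence does not veto a call. Thresholds are
strict inequalities, so a fraction exactly at the threshold is rejected.

Significance and effect thresholds (`α = 0.05`, `|Dprop| ≥ 0.2`) follow the
method's defaults; 0.1 and 0.05 are reasonable permissive effect settings
and are the default sweep of `runBenchmark()`, together with Qrep in
0.8–0.95 and Rrep in 0.55–0.85.

## The simulator

`simulateExperiment()` emulates the two benchmark designs at the count
level:

* Per-transcript baseline means are log-normal (`meanLog = log(100)`,
  `sdLog = 1.5` by default — median 100 with a realistic heavy tail);
  isoform counts per gene are uniform on 1–6; replicate counts are negative
  binomial with dispersion 0.1 (variance `μ + 0.1 μ²`, typical of bulk
  RNA-seq; 0 gives Poisson).
* Bootstrap iterations are multinomial resamples of each replicate's counts
  at its exact library size — the same uncertainty structure a quantifier's
  bootstrap produces for unambiguously assignable reads.
* DTU is injected by swapping the mean abundances of the two most abundant
  isoforms (judged on condition-A means, ties broken by transcript id) in a
  chosen number of genes, leaving the gene total untouched — a pure usage
  change. Candidates must be well-expressed (total mean ≥ 100 by default)
  and may be required to exceed a minimum injected `|Dprop|`
  (`dtuMinDprop`). The injected `|Dprop|` of a swap is
  `|μ₁ − μ₂| / Σ μ` over the gene's isoform means.
* The null design draws two disjoint pseudo-groups from a single-condition
  pool (`nullSplit()`), so every positive is a false positive by
  construction.

What the simulator does **not** emulate: read-level effects (fragment
length/GC bias), quantifier misattribution between paralogous or highly
similar transcripts (which makes real bootstrap variance locally much
larger and correlated across transcripts), correlated biological variation
between isoforms, and annotation errors. Passing tests on simulated data
therefore demonstrate the correctness and calibration of the decision
machinery under a known generative model — not that real-data calls at the
same thresholds achieve the same error rates.

One property of the generative model is worth stating openly: isoform
counts are drawn independently per transcript with negative-binomial
overdispersion, while the G-test's null assumes multinomial sampling of
isoforms within a gene. On well-expressed genes the raw significance test is
therefore anti-conservative under this model — which is precisely the regime
in which the effect-size and reproducibility filters carry the
false-positive control, as the null acceptance check demonstrates.

## Numerical and design choices

* Transcript ids are compared as exact strings; no version-suffix stripping
  is ever applied. Quantified transcripts absent from the annotation are
  dropped with a logged count (recorded in provenance), not an error.
* Salmon bootstrap archives are compressed binaries whose layout is
  version-dependent; bootstrap matrices are instead interchanged as plain
  TSV (transcripts × iterations), and Kallisto HDF5 files are decoded via a
  bundled h5py helper script (requires a Python on the PATH).
* GTF input is used only for its `transcript_id`/`gene_id` attributes;
  coordinates are never interpreted, so no 0/1-based or strand convention
  applies.
* Dominant-isoform switches are reported from the point proportions; ties on
  the maximum are broken lexicographically and flagged.
* All randomness (bootstrap draws, simulation, null splits) is driven by
  explicit integer seeds recorded in the provenance block; the caller's
  global RNG state is saved and restored around every seeded computation,
  and identical inputs plus seeds give byte-identical output bundles.

## Problem sizes used by the checks

The package's own acceptance checks run at desk scale, chosen to finish in
minutes on one CPU while keeping the Monte-Carlo error small relative to the
margins being tested: the null false-positive study uses 50 seeds × 2,000
genes (1–6 isoforms, n = 3 vs 3, 100 bootstrap iterations; ~5 minutes); the
injection-recovery study uses 400 two-isoform genes with 200 injected swaps
of `|Dprop| ≥ 0.5` at means centred on 1,000 counts. The swap-recovery study
uses 2-isoform genes because a narrow-spread mean distribution over many
isoforms cannot supply enough candidates with a 3:1 top-isoform ratio, which
a `|Dprop| ≥ 0.5` swap requires.

## Known limitations

* Exactly two conditions; no multi-group or covariate designs.
* No dispersion modelling or proportion shrinkage — genes with few counts
  rely entirely on the eligibility and effect filters for protection.
* The transcript-level test treats sibling isoforms as a single pool, so a
  compensating change spread over several siblings attributes less sharply.
* Reproducibility fractions are reported without uncertainty intervals, and
  nested schemes (bootstrap-within-subset) are not computed.
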