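---
title: "Activity records, promiscuity degrees and publication statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity records, promiscuity degrees and publication statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promlit)
```

## The analysis model

`promlit` works on flat tables of potency measurements: one row per
determination, carrying compound, assay, target (with organism and
type), the assay's confidence score and relationship type, the potency
type (Ki or IC50), the relation qualifier, the value with units, and
the source document. The pipeline has four stages, each a pure function
of the previous one:

1. **Curation** selects qualifying rows. The `set1` policy keeps direct
   interactions (relationship type "D") with single human protein
   targets at the highest assay confidence (score 9), with defined
   Ki/IC50 potencies from original publications; `set2` drops the
   relationship and confidence requirements. Approximate measurements —
   any relation other than "=", including ">", "<", "~", ">=" and
   "<=" — are always excluded, because a bound is not a defined potency.
2. **Activity records** aggregate the kept rows into one record per
   unique (compound, target) pair, pooling all assays, publications and
   nM-normalized values. Each record is classified by a decision tree:
   single vs. multiple publications, then (for single publications)
   one vs. several reported values, or (for multiple publications)
   varying values vs. multiple instances of one identical value, the
   latter indicating citation of an earlier measurement rather than an
   independent experiment.
3. **Publication profiles** count distinct assays, targets and
   compounds per document and categorize each document as single-assay,
   multiple assays for one target, or multiple assays for multiple
   targets. This assumes ChEMBL assay semantics: an assay belongs to
   exactly one document and measures one target, so
   `n_targets <= n_assays` per document; the profiler asserts the
   second inequality and warns when foreign data violate
   document-exclusivity.
4. **Promiscuity** summarizes per compound: the degree (number of
   records, i.e. distinct targets) and the publication count (distinct
   documents across all of the compound's records). Compounds fall into
   subsets A = (degree 1, 1 publication), B = (1, >5), C = (>5, 1),
   D = (>5, >5). ">5" is read as "six or more" throughout; the binned
   tables keep "5" and "6-10" separate, which fixes that boundary.

Identities that hold by construction, and that `consistency_check()`
re-verifies on any report: the four record classes partition the
records; the three publication categories partition the profiled
documents; the five subsets partition the compounds; the summed degrees
equal the record count; the summed per-record measurement counts equal
the kept row count; and the degree-by-publication matrix marginals
reproduce the two binned distributions bit-exactly.

## Parameters that matter

* `curation_policy(set, allowed_activity_types, ...)` — the relaxed
  policy's notion of "defined potency" is genuinely open: the source
  criteria name no explicit type list for it. We default both policies
  to {Ki, IC50} for comparability and expose the set as an argument;
  widening it (e.g. to Kd or EC50) is a one-line change whose effect is
  confined to the `allowed_activity_types` audit rule.
* `build_records()` — two potencies count as *the same value* when
  equal after normalization to nM and rounding to **3 significant
  figures**. Published potencies carry at most 2-3 significant digits,
  so a cited value re-reported as 0.05 uM matches the original 50 nM,
  while genuinely different determinations (which scatter on the log
  scale) virtually never collide. The threshold is a package choice;
  the source analysis states none.
* `range_histogram(records, min_publications = 10)` — records reported
  in strictly more than `min_publications` documents enter the
  histogram over potency ranges {<=1, (1,2], (2,3], >3} orders of
  magnitude.
* `journal_ranking(profiles, min_publications = 100)` — journals with
  strictly more than 100 qualifying publications, descending count,
  alphabetical ties.

## Numerical choices

* **Potency range** is computed over the 3-significant-figure distinct
  values, not the raw ones, so `log_range == 0` exactly when
  `n_distinct_values == 1` (replicated citations in different units
  cannot produce a spurious epsilon range). At 3 s.f. the difference
  from the raw range is below half a percent of a log unit.
* The **single-publication split** of the decision tree is by the
  number of reported values (measurements), not distinct values:
  replicate determinations in one paper that happen to coincide
  numerically still count as "multiple values". Ki and IC50 values are
  pooled within a record; the record is a compound-target unit.
* **Percent formatting** (`format_percent()`) prints one decimal, two
  decimals below 0.1%, so rare bins never print as "0.0".
* **Degenerate inputs**: readers return empty typed tibbles for
  header-only files and fail fast (with file line numbers) on missing
  columns, unparsable numbers, non-positive potencies and duplicate
  document ids; `curate()` on zero rows returns an all-zero audit;
  `range_histogram()` warns and returns an empty histogram when no
  record clears the threshold; the distribution summaries refuse empty
  input outright.
* **Determinism**: every writer emits a declared column order and a
  radix-sorted (C-locale) row order, and numbers embedded in joined
  text fields use the shortest decimal representation that parses back
  to the identical double, so write-read round-trips are exact and
  repeated runs are byte-identical.

## What the synthetic generator emulates

`generate_corpus()` exists so that every stage can be validated against
known ground truth without the source database. Its defaults are the
observed study conditions:

* Per-compound **degree** and **publication count** are sampled
  independently (the real data show no detectable correlation between
  the two) from the observed binned distributions of the curated
  high-confidence ChEMBL 21 set — 69.7% of compounds with one target,
  94.5% in one publication — using exact published counts rather than
  rounded percentages. Banded bins (6-10, 11-20, >20) draw uniformly
  within the band, ">20" capped at 80 (the most promiscuous observed
  compounds reach 71 targets).
* **Documents** are sized so that a publication reports on average 16.7
  compounds, and each carries a planned target-panel size (55% of
  papers single-target, mean about 2.4). A compound's records are
  reported in a primary document whose panel fits its degree; targets
  are preferentially reused from the panel (`target_reuse_probability`
  = 0.9), so co-published compounds form series sharing targets.
  Additional publications of a record are drawn with probability 0.8
  from documents already covering the target — retests and citations
  cluster on well-studied targets. Under these defaults a publication
  ends up with roughly 3 assays for 2.8 targets, and about a third of
  papers are single-assay.
* **Potencies** are log-normal: a per-record true value around 100 nM
  (log10 mean 2.0, between-record sd 1.0) with within-record
  measurement scatter of 0.5 log units, rounded to 3 significant
  figures and expressed in nM, uM or M. A document replicates the assay
  for a panel target with probability 0.107 (yielding
  single-publication multi-value records at the observed rate), and a
  multi-publication record repeats one identical cited value everywhere
  with probability 0.39 (the observed same-value fraction). The
  within-record sd is a modelling choice justified only qualitatively
  by the multi-order-of-magnitude ranges seen in heavily re-measured
  records; no variance model is published.
* **Contamination** appends rows that each violate exactly one
  high-confidence rule (approximate relation, confidence below 9,
  non-"D" relationship, non-human organism, non-protein target, patent
  document), 1% per rule by default, cloned from clean rows so nothing
  else changes. Rows violating only the confidence or relationship
  rules survive `set2`, as they should.

The manifest records the sampled truth — per-compound degree,
publication count and subset; per-record counts, class and log-range;
per-row contamination flags — and the test suite requires the pipeline
to recover all of it *exactly* (log-ranges to 1e-9) on a
10,000-compound corpus, which takes a few seconds.

What the generator does **not** emulate: chemical structures and
structural series, target families, journal-level realism beyond a
categorical field, inter-year trends beyond a simple recency-weighted
year, and the full shape of the per-publication assay histogram (its
mean and skew are matched; the observed 40/13/47 category split is
approximated as roughly 32/3/65 because replicate assays are modelled
per target rather than per paper). Passing tests therefore demonstrate
correctness of the accounting — aggregation, classification, binning,
conservation — under realistic marginals, not fidelity to every joint
property of the literature.

## Design decisions

* Rule order for audit attribution is coarse-to-fine: document type,
  organism, target type, relation, units, activity type, relationship
  type, confidence. A row failing several rules is charged to the
  first; membership of the kept set is order-independent because the
  rules are conjunctive. The units rule is ours: rows in units other
  than nM/uM/M cannot enter log-range computations, and the source
  criteria are silent about them.
* Compound identity is the compound id. Whether the source analysis
  merged salts with parent structures is not stated; we take the id as
  authoritative and leave structure standardization out of scope.
* Relation vocabulary is open-ended: ">=" and "<=" are preserved at
  read time and treated as approximate by curation.
* The package's interface is R functions plus one thin script
  (`scripts/acceptance.R`); the pipeline stages persist their
  intermediates through `write_table()`, so any stage can be re-run or
  audited in isolation without a shell-level subcommand layer.

## Problem sizes

The shipped tests run corpora of 150-1,000 compounds per module and one
10,000-compound corpus (about 20,000 measurement rows, 662 documents)
for the end-to-end properties; the whole suite completes in well under
a minute, and `scripts/acceptance.R` in a few seconds. Larger corpora
scale linearly in compounds.

## Known limitations

* Journal names are categorical labels; no abbreviation reconciliation.
* Target-family aggregation is not modelled (no family ontology).
* The per-compound publication count counts documents contributing any
  qualifying measurement; documents reporting the compound only in
  disqualified rows (e.g. approximate values) do not count, which is
  the natural reading of the curated analysis but not the only one.
* The "same value" test compares standardized values; if a cited value
  was re-reported after genuine re-rounding to fewer than 3 significant
  figures it would count as distinct.
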