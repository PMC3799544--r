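---
title: "Quantifying compound promiscuity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compound promiscuity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promiscuitr)
```

## The problem

Compound promiscuity is defined here as *specific* activity of one small
molecule against multiple biological targets, as opposed to non-specific
signals from aggregation, assay interference or cell-based readouts.
Promiscuity statistics therefore depend heavily on curation: which
activity annotations count as evidence of a direct ligand–target
interaction, and which measurement types are comparable with each other.
This package turns the standard desk analysis — from raw activity records
to promiscuity-rate tables, probability distributions, family and
molecular-weight stratifications and profile classifications — into a
reproducible pipeline with explicit, testable conventions.

## Curation model

**Confidence filtering.** A record is kept iff its curation confidence
level reaches `min_confidence` (default 9, the top of a 0–9 scale in
which 9 means a direct single-protein interaction), it carries the
direct-interaction flag (default required), and its relation qualifier is
allowed (default only `eq`). Qualified measurements (`<`, `>`) are
excluded by default because a censored value has no usable magnitude for
potency-spread analysis; the filter is fully configurable through
`filter_criteria()`.

**Measurement types.** Ki values are assay-independent equilibrium
constants; IC50 values depend on assay conditions and substrate
concentration. The pipeline never mixes them: records are split into Ki
and IC50 subsets that are analysed in parallel, and a compound measured
both ways contributes to both subsets. Records of any other measurement
type enter neither.

**Replicate aggregation.** Potencies are stored in nM and analysed as
pPotency = −log10(potency in mol/L) = 9 − log10(value in nM). Replicate
measurements of one (compound, target) interaction collapse to their
arithmetic-mean pPotency, i.e. the geometric mean on the concentration
scale — the standard choice for log-normally distributed potencies.
Identical duplicate rows are collapsed silently at read time; conflicting
replicates are kept and averaged. Aggregation is idempotent.

## The statistics

For a set of per-compound distinct-target counts $n_i \ge 1$:

* `avg_all` $= \bar n$, the mean over all compounds;
* a compound is *promiscuous* if $n_i \ge 2$; `avg_promiscuous` and
  `median_promiscuous` are taken over that subset;
* `p_ge2` $= P(n \ge 2)$ and `p_gt5` $= P(n > 5)$ (strict, i.e.
  $n \ge 6$);
* the median of an even-sized set is the mean of the two middle values.

Because every non-promiscuous compound has exactly one target, the
**mixture identity**

$$\text{avg\_all} = p_{\ge 2}\,\cdot\,\text{avg\_promiscuous} +
  (1 - p_{\ge 2})\cdot 1$$

holds exactly for every summary computed at the standard threshold of 2.
`verify_consistency()` recomputes it for every summary row of a report
bundle and flags gaps above $10^{-9}$; `run_pipeline()` refuses to emit a
bundle that fails. The same identity reconstructs published overall
averages from published $(p_{\ge 2}, \text{avg\_promiscuous})$ pairs, which
is what `scripts/acceptance.R` does.

Some compound categories are conventionally summarised with a different
cutoff for the *median* (approved drugs: more than four targets;
experimental drugs: at least two; screening actives: at least three).
`promiscuity_summary()` therefore takes a separate `median_threshold`
that restricts only the median; the promiscuous mean and the mixture
identity always use the threshold of 2.

**Counting rules per source.** ChEMBL-style records are counted after
filtering and aggregation. Drug–target annotations are counted without
any confidence filtering (all reported target categories). Screening
actives are counted over the distinct targets of their assays with
outcome `active`; `assay_coverage()` reports the fraction of confirmed
actives tested in strictly more than 50 distinct assays, the figure that
justifies using screening data for promiscuity assessment at all.

**Family scope.** A compound is `single` (one target), `intra_family`
(≥ 2 targets, one family) or `cross_family` (≥ 2 families). Intra-family
promiscuous compounds are candidates for privileged structures.

## Stratification conventions

Molecular-weight bins are lower-open and upper-closed, with the first bin
$(0, 200]$: a compound of exactly 200 Da falls in "≤ 200", one of exactly
700 Da in "(600, 700]". The published range notation leaves boundary
membership ambiguous; this convention was chosen once so that every
positive MW maps to exactly one bin, and is configurable through
`mw_bins()`. Compounds without a known MW are excluded from the MW
stratification and counted in a message.

Family summaries restrict each compound to its targets *within* the
family: a compound with two GPCR targets and one kinase target counts two
targets in the GPCR summary. Compounds active in several families appear
in each family's summary independently.

## The prevalent promiscuity profile

A promiscuous compound matches the prevalent profile iff it has 2–5
targets, every aggregated potency is strictly below 1 µM ("sub-µM",
pPotency > 6), all targets share one family, and the potency spread
(max − min pPotency) is at most 2 log units; spreads within 1 log unit
are flagged separately. Spread is computed as max-minus-min over
aggregated per-target potencies of a single measurement type — the
stricter reading of "potency differences within one or two orders of
magnitude" compared with a pairwise interpretation, and the one
implemented here.

The selectivity-outlier pattern — highly potent against one primary
target, weakly potent against all others — uses default cutoffs of
100 nM (potent) and 10 µM (weak). No published values exist for these
two numbers; they are exposed in the rule and chosen an order of
magnitude apart so that the outlier pattern and the prevalent profile
are mutually exclusive (the weak cutoff exceeds the sub-µM cutoff).
Profiles are undefined for compounds with fewer than two aggregated
pairs; such compounds are reported as not assessable rather than as
non-matching.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with known ground truth:

* **Target counts** follow a truncated geometric law on 1..K (default
  q = 0.62, K = 10), giving $P(n \ge 2) \approx 0.38$ and
  $P(n > 5) \approx 0.008$ — the shape observed for curated Ki-based
  bioactivity data: concentrated at 1–3 targets with a thin tail past
  five. `expected_statistics()` returns the law's exact mean, variance
  and tail probabilities for recovery tests.
* **Family clustering**: each compound draws a primary family
  (probability proportional to family size; default sizes echo the
  relative target counts of prominent families — GPCR class A 120,
  kinases 75, ion channels 25, proteases 90, nuclear receptors 15,
  other 100) and each additional target stays in that family with
  probability 0.97, yielding roughly 62/36/2 single/intra/cross
  percentages at the default count law.
* **Potencies** are normal on the pPotency scale (default mean 7.0 =
  100 nM, sd 1.0), i.e. log-normal in concentration, so a majority of
  activities are sub-µM.
* **Molecular weights** are normal (mean 400 Da, sd 100) truncated to
  positive values — the typical range of medicinal-chemistry compounds.
* **Measurement structure**: compounds are measured by Ki only, IC50
  only, or both (default 0.35/0.45/0.20); 20% of measurements carry a
  duplicate with pPotency noise (sd 0.2); 90% of records are at
  confidence 9 with the direct flag; 2% carry a `<` qualifier.
* **Drugs and screening data**: separate sections with heavier count
  laws (approved drugs: geometric q = 0.17 truncated at 30,
  experimental q = 0.56; screening actives q = 0.49 truncated at 20)
  and a log-normal tested-assay count calibrated so roughly three
  quarters of actives exceed 50 assays.

Ground truth records each compound's true target count, family scope and
per-measurement-type profile flags, computed inside the generator with
plain arithmetic — independently of the pipeline operations they are
later compared against.

One master seed drives everything; per-section sub-seeds are derived
arithmetically from it so that, for example, the drug section does not
change when the number of bioactive compounds does. Generation is
deterministic to the byte.

**What the generator does not emulate.** Real extracts have
database-specific identifier semantics (protein complexes vs single
proteins), correlated assay panels, frequent hitters, inter-source
overlap of compounds, and potency-dependent reporting bias. Passing
recovery tests on synthetic data therefore demonstrates that the
pipeline measures what it claims on data matching its assumptions — not
that any particular published rate is correct.

## Numerical choices and degenerate inputs

* Empty inputs yield explicit empty summaries (`n_compounds = 0`,
  statistics `NA`), never zeros; a category with no promiscuous
  compounds reports `NA` promiscuous fields.
* Report TSVs round averages to one decimal and probabilities to
  one-decimal percent; `report.json` keeps full precision, and the TSV
  cells equal the JSON values after contract rounding.
* Unit conversion accepts nM, µM/uM, mM and M on input; everything is
  stored in nM.
* The mixture-identity tolerance ($10^{-9}$) is far above accumulated
  double rounding at realistic set sizes but far below any real
  inconsistency.

## Problem sizes in the test suite

The suite checks oracle equivalence of all summary fields against naive
loop-based recomputation on 100 random instances of up to 1000
compounds; parameter recovery on 100 seeds of 10,000-compound synthetic
datasets (pipeline estimates within 3 Monte-Carlo standard errors of the
analytic law values in at least 95% of seeds); exact ground-truth
agreement of profile flags on a noise-free 1500-compound configuration;
and byte-level determinism of repeated simulation runs. These sizes give
standard errors a factor of ~50 below the effects being checked while
keeping the full suite at a few minutes on one core.

## Known limitations

* Target identifiers are opaque: whether a "target" is a single protein
  or a complex is whatever the input tables encode. The original
  analyses this pipeline mirrors most likely restricted to single
  proteins at top confidence; inputs at other confidence semantics will
  shift rates.
* Only `eq` records enter by default; analyses wanting censored records
  must opt in and interpret spreads cautiously.
* The probability-of-promiscuity figures are empirical fractions, not
  model-based estimates; no confidence intervals are attached.
* Cross-source compound identity is not resolved; the drug and
  screening sections are summarised independently of the activity
  tables.
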