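---
title: "Molecular classification of nasopharyngeal carcinoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular classification of nasopharyngeal carcinoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcmolclass)
```

## Overview

`npcmolclass` assigns nasopharyngeal carcinoma (NPC) tumors to one of
three genetic subtypes from somatic mutation and copy-number evidence and
evaluates the prognostic value of that assignment. This vignette explains
the model, the tunable parameters and their defaults, the synthetic data
the package generates, and the design decisions taken where the procedure
admitted more than one reasonable reading.

## The ordered decision tree

Each tumor is reduced to an *alteration profile*: its nonsilent mutations
(missense, in-frame and frameshift indels, stop gain/loss, splice-site)
and a per-gene copy-number state in {amplified, neutral, deleted}. The
classifier then walks an ordered cascade:

1. **Tier 1 (RAS/PI3K/AKT).** Any qualifying mutation in *KRAS*, *NRAS*,
   *HRAS*, *AKT1* or *PIK3CA*. Because the tiers are ordered, a tumor with
   both a tier-1 mutation and a cell-cycle copy-number event is
   RAS/PI3K/AKT: mutation evidence takes precedence.
2. **Tier 2 (cell-cycle).** A deletion of *CDKN2A* or *CDKN2B*, or an
   amplification of *CCND1* or *CDKN1B*. The rule is direction-specific;
   an amplified *CDKN2A* or a deleted *CCND1* never fires it.
3. **Unclassified.** Neither rule fires. Mutations in epigenetic
   regulators or Notch-pathway genes are attached as annotations but never
   reassign a tumor: the unclassified subtype is defined by exclusion, and
   the tree has no third decision node.

Design choices worth stating explicitly:

* *"RAS" is expanded to KRAS, NRAS and HRAS.* All three family members
  occur mutated in NPC (including an HRAS p.Q61R hotspot); the gene set is
  configurable for users who prefer a narrower reading.
* *Tier-1 qualification defaults to any nonsilent mutation.* A stricter
  mode (`require_pathogenic_for_tier1 = TRUE`) restricts tier 1 to
  mutations with a pathogenicity score ≥ 0.07, mirroring the screen used
  for driver discovery; the default keeps the two filters separate because
  the classifier is defined on mutations, not on the driver shortlist.
* *CDKN1B amplification is kept as a tier-2 event* exactly as the subtype
  is defined, although amplification of a CDK inhibitor is biologically
  surprising; users can drop it from `tier2_amplification_genes`.

## Alteration calling

**Copy number.** Gene-level state comes from SEG-format segment log2
ratios. For each (sample, gene), every segment overlapping the gene span
by at least one base is considered and the segment with the largest
absolute log2 ratio determines the state (ties broken by the earliest
start). State is amplified when log2 > 0.8 and deleted when log2 < −0.8 —
strict inequalities, so a segment at exactly ±0.8 is neutral. The
max-|log2| rule reads the threshold as a high-confidence extreme-value
screen; it is isolated in `call_gene_cnv()` so a length-weighted variant
could be substituted without touching anything else. Internally all
coordinates are 0-based half-open; MAF positions (1-based) and SEG rows
(1-based inclusive) are converted at the file boundary, which keeps
overlap logic free of off-by-one cases.

**Arm-level summaries** (gains/losses when segments beyond ±0.3 log2 cover
≥ 50% of an arm) are descriptive output only and never feed the
classifier; both thresholds are package defaults with no published
counterpart and are configurable.

**Tumor mutation burden** is the count of nonsilent coding mutations per
megabase. The denominator defaults to 38 Mb (a typical coding exome), but
no single denominator is correct across capture kits: cross-cohort TMB
comparisons should set `exome_size_mb` per cohort.

**Missing pathogenicity scores** are stored as absent, never as 0 (0 is a
legal score), and a mutation without a score is excluded by the pathogenic
filter — absence of a prediction is not evidence of pathogenicity — while
remaining in the nonsilent set and in TMB.

## Survival statistics

Kaplan–Meier estimation, the k-group log-rank test and Cox
proportional-hazards models are delegated to the `survival` package behind
the package's own interfaces; the test suite verifies each against
independent hand, grid-search or enumeration oracles on small instances.
Specific conventions:

* Survival-rate confidence intervals use the complementary log-log
  transform of the Greenwood variance by default, which respects [0, 1]
  and produces the asymmetric intervals typical for 5-year rates; a plain
  Greenwood interval is available by flag.
* Cox models default to Efron tie handling because follow-up recorded in
  months guarantees tied event times; Breslow is available for
  cross-checks. Monotone likelihoods (perfect separation) are reported as
  errors naming the covariate rather than returned as huge coefficients.
* The multivariate model in `run_pipeline()` uses age, sex, stage and the
  subtype with UNCLASSIFIED as the reference level; the covariate set and
  reference are arguments, since the appropriate adjustment set is a
  modelling choice, not a property of the classifier.
* The Wilcoxon rank-sum test uses the tie-corrected normal approximation
  without continuity correction; the Pearson chi-square test applies no
  Yates correction. Benjamini–Hochberg adjustment is the standard step-up
  procedure (`p.adjust`). Note the step-up transform is not idempotent on
  arbitrary inputs — re-adjusting an adjusted vector inflates it toward
  its maximum — and the tests assert the fixed-point property only on
  fully adjusted (flat) vectors.

## Synthetic cohorts

**The deterministic fixture** (`npc_fixture()`, 82 patients) encodes the
published cohort-level structure as planted evidence: 9 tier-1 patients (4
of whom also carry tier-2 copy-number events, so tier precedence is
observable), 34 additional cell-cycle patients, and 39 unclassified
patients. Planted per-gene totals are *CDKN2A* deleted in 19, *CDKN2B* in
16 and *CCND1* amplified in 17 patients; events are dealt cyclically so
every cell-cycle patient carries at least one and the 9p21 co-deletion
pattern appears naturally. The SEG file additionally carries decoys that a
correct caller must ignore: segments at exactly ±0.8 and at ±0.75,
high-|log2| segments that do not overlap any gene, and a wrong-direction
*CDKN2A* amplification. Gene coordinates are small synthetic spans on
synthetic 2 Mb contigs (arms split at 1 Mb) so the fixture is independent
of any genome build; the reader stack treats them exactly like real
coordinates. Fixture survival times are exponential *quantiles* (not
draws) at evenly spaced probabilities within each subtype, with periodic
censoring and administrative capping at 96 months — deterministic, so two
builds are byte-identical.

**The stochastic simulator** (`simulate_cohort()`) draws subtypes from
configurable prevalences (default 9:34:39), plants evidence consistent
with the drawn subtype (tier-1 patients also receive tier-2 events at a
configurable co-occurrence rate, default 4/9), and generates exponential
PFS/OS under independent uniform censoring. Default PFS medians are 18,
36 and 60 months for the RAS/PI3K/AKT, cell-cycle and unclassified
subtypes — values chosen to encode the published poor/intermediate/good
ordering at effect sizes plausible for an advanced-stage NPC cohort, since
individual-level times are not published; OS medians default to twice the
PFS medians. All randomness flows from one integer seed.

**What the synthetic data does not emulate:** mutational-signature
sequence context, realistic segment-length distributions, purity/ploidy
effects, EBV status, and inter-gene correlation beyond the planted
co-occurrence. Passing tests therefore demonstrate the correctness of the
calling, classification and survival machinery on data with the assumed
statistical structure — not the clinical validity of the classifier on new
sequencing data.

## Numerical and degenerate-input conventions

* Threshold comparisons in CNV calling are strict and unrounded; the test
  suite probes ±1e−9 around the boundaries.
* Kaplan–Meier with every subject censored returns a constant curve at 1
  with no event times; an empty record set is an error. The Greenwood
  variance is reported as 0 once the curve reaches 0.
* A log-rank test with no events, a Cox fit with a constant covariate, a
  chi-square table with a zero marginal, and p-values outside [0, 1] are
  argument errors rather than silently propagated NaN.
* Cox convergence is the `survival` package's iteration with its defaults;
  fits whose coefficients or standard errors diverge are reported as
  monotone-likelihood errors naming the covariate.
* Classification is pure: it depends only on the profile and the
  configuration, and reruns are bit-identical. The pipeline report
  contains no timestamp so end-to-end reruns are byte-identical too.

## Problem sizes used by the test suite

The suite runs on one CPU in well under a minute: the 82-patient fixture,
simulated cohorts of 150–500 patients, a 5000-replicate log-rank null
calibration (n = 50 per group), 20 replicates of n = 2000 for Cox
log-hazard-ratio recovery, and a 200-replicate power check of the
simulator's survival separation at n = 500. These sizes were chosen as the
smallest at which the asymptotic checks (type-I error within [0.04, 0.06],
|mean ln-HR bias| < 0.05) are stable across seeds.

## Known limitations

* The classifier consumes mutation evidence for tier 1 as published;
  copy-number gains of RAS-pathway genes are not tier-1 evidence.
* No proportional-hazards diagnostics are provided; the Cox summaries
  assume proportionality over the follow-up window.
* Arm-level calls use a simple coverage rule with package-default
  thresholds and should be treated as descriptive.
* The cross-cohort TMB comparison is only meaningful with per-cohort
  exome denominators, which the caller must supply.
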