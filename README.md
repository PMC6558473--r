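# npcmolclass

Genetic subtype classification and survival analysis for nasopharyngeal
carcinoma (NPC) cohorts.

## The problem

NPC lacks a clinically usable molecular classification. Whole-exome
sequencing of NPC tumors shows three recurrent, largely non-overlapping
patterns of somatic alteration, which support an ordered decision tree:

1. **RAS/PI3K/AKT subtype** — any nonsilent mutation in *KRAS*, *NRAS*,
   *HRAS*, *AKT1* or *PIK3CA*. Evaluated first: a tumor carrying such a
   mutation belongs here regardless of its copy-number state.
2. **Cell-cycle subtype** — otherwise, a deletion of *CDKN2A*/*CDKN2B* or
   an amplification of *CCND1*/*CDKN1B*.
3. **Unclassified** — neither rule fires. These tumors are dominated by
   mutations in epigenetic regulators (*KMT2C/2D/2B*, *PRDM2*, *PRDM16*,
   *NCOR2*, *KAT6B*, *EP300*, *CREBBP*) and the Notch pathway
   (*NOTCH1/2*), which the package reports as annotations without using
   them for assignment.

The subtypes are prognostic, with poor, intermediate and good
progression-free survival respectively.

`npcmolclass` implements the full pipeline: reading MAF-like mutation
tables, SEG copy-number segments, BED gene models and clinical tables;
gene-level copy-number calling from segment log2 ratios (amplified when
log2 > 0.8, deleted when log2 < −0.8, strict inequalities, determining
segment = maximum |log2| among segments overlapping the gene by ≥ 1 bp);
tumor mutation burden (nonsilent coding mutations per Mb); the ordered
classifier; and the survival statistics used to evaluate it — Kaplan–Meier
product-limit curves with Greenwood variance and complementary log-log
confidence intervals, k-group log-rank tests, Cox proportional-hazards
models (Efron ties), Wilcoxon rank-sum and Pearson chi-square cohort
comparisons, and Benjamini–Hochberg adjustment.

Because individual-level sequencing data cannot be redistributed, the
package ships a synthetic-data module: a fully deterministic 82-patient
fixture whose planted alterations reproduce published cohort-level counts
(9/34/39 subtype split; *CDKN2A* deleted in 19, *CDKN2B* in 16, *CCND1*
amplified in 17 of 82 tumors) together with threshold/overlap/direction
decoy segments, and a seeded stochastic simulator with configurable
prevalences and subtype-specific exponential survival.

## Worked example

```r
library(npcmolclass)

dir <- tempfile()
paths <- plant_fixture_cohort(dir)          # deterministic 82-patient cohort
report <- run_pipeline(paths[["mutations"]], paths[["segments"]],
                       paths[["genes"]], paths[["arms"]],
                       paths[["clinical"]], out_dir = file.path(dir, "out"))
summary(report)
```

```
NPC cohort report: 82 patient(s) (82 with molecular data)
  RAS_PI3K_AKT    9 (11.0%)
  CELL_CYCLE     34 (41.5%)
  UNCLASSIFIED   39 (47.6%)
  median TMB: 0.026 mutations/Mb
  OS log-rank: chi2 = 9.355 (df 2), p = 0.0093
  PFS log-rank: chi2 = 11.361 (df 2), p = 0.0034
OS 60-month survival rates:
  RAS_PI3K_AKT  47.6% (95% CI 12.3-76.9)
  CELL_CYCLE    66.7% (95% CI 46.7-80.6)
  UNCLASSIFIED  77.7% (95% CI 60.3-88.2)
PFS 60-month survival rates:
  RAS_PI3K_AKT  0.0% (95% CI 0.0-0.0) [extrapolated]
  CELL_CYCLE    37.7% (95% CI 20.1-55.3)
  UNCLASSIFIED  57.2% (95% CI 39.0-71.7)
```

The subtype split is the planted 9/34/39 partition; the log-rank tests
separate the three Kaplan–Meier curves because the fixture's survival
times follow per-subtype exponential distributions with medians 18, 36 and
60 months (PFS); the 5-year (60-month) rates order the subtypes from poor
to good outcome. The low TMB median simply reflects the fixture's sparse
synthetic mutation background (about one nonsilent mutation per patient
over a 38 Mb exome).

A thin command-line wrapper is installed with the package
(`system.file("cli", "npc-molclass", package = "npcmolclass")`), with
`run`, `fixture` and `simulate` subcommands.

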