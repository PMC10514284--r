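---
title: "Methods: evidence-weighted target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-weighted target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(targetrank)
library(dplyr)
```

`targetrank` implements a multi-criteria triage for therapeutic target
discovery: evidence about every candidate gene is collected from three
arms — a literature corpus split into seven asset classes, structured
genomic databases, and genomics raw-data analysis (differential expression
and variant calling) — filtered for relevance, classified by a set of
deterministic rules, and combined into one weighted score on a 0–100
scale. This vignette documents the model, its assumptions, the tunable
parameters, the synthetic-data generator used for validation, and the
design decisions that were genuinely open.

## The pipeline

```{r overview}
cohort  <- simulate_cohort(cohort_spec(n_targets = 120, n_planted_top = 5, seed = 2))
ranking <- prioritize_targets(cohort)
glance(ranking)
```

`prioritize_targets()` chains six stages, each exported on its own:

1. **DE post-processing** (`assign_regulation()`, `select_significant()`):
   rows of a differential-expression table survive when
   `p_adj <= 0.05` and `|log2FC| >= 1` (both configurable). The thresholds
   follow common practice for calling significant differential expression;
   a log2FC of exactly 0 carries no direction and is excluded with a log.
2. **Variant post-processing** (`filter_variants()`): GATK-style hard
   filters, downstream annotation filters, and loss-of-function calling
   (details below).
3. **Evidence ingestion** (`ingest_evidence()`): symbols are uppercased
   (plus an optional alias table — deterministic, no online symbol
   service), documents counted per asset class, and provenance flags
   recorded per arm. Unparseable rows are skipped and counted rather than
   failing the run.
4. **Relevance cascade** (`relevance_filter()`): targets with fewer than
   20 documents in total are dropped as non-specific hits; targets at or
   above 20 documents from a single asset class only are kept only when
   their pathways overlap the disease pathway set. All seven classes count
   equally toward the threshold (the rule names a total document count;
   nothing suggests class-specific weighting at this stage).
5. **Target evaluation** (`evaluate_targets()`): the rule-based
   classifiers described below.
6. **Scoring and ranking** (`class_scores()`, `scale_scores()`,
   `disease_parameter_scores()`, `combine_scores()`, `rank_targets()`).

## Literature scoring

Each document is scored as a sum of components, all bounded in [0, 1]:

| asset class | components |
|---|---|
| publication | recency + impact factor + position (+ optional citations) |
| clinical trial | status + phase + position |
| patent, grant, congress, news, thesis | recency + position |

The component definitions are design choices where only the parameter
*names* are conventional:

* **Recency** `= 2^(-age_years / half_life)` with a 5-year half-life.
  Exponential decay is monotone, bounded, and has an interpretable scale
  parameter; 5 years reflects how quickly a therapeutic-hypothesis
  literature turns over.
* **Impact factor** `= min(IF, 30) / 30`. Capping bounds journal-level
  outliers; 30 sits above almost all specialty journals.
* **Position weights** default to title 1.0, abstract 0.8,
  indication/intervention 0.7, full text 0.4, raw text 0.2 — the rank
  order of how specifically a mention ties the target to the disease.
* **Phase weights** 0.4/0.6/0.8/1.0 for phases 1–4; **status weights**
  completed/active 1.0, recruiting 0.8, terminated/withdrawn 0.2.
* **Citations** are arguably part of a publication's weight but double
  count impact; the component (`log1p(c)/log1p(cap)`) ships switched off.

Raw class scores are per-document sums, so they are additive and
monotone: adding a document can never lower a class score (a property the
test suite exercises with randomized perturbations). Min–max scaling to
[0, 1] is applied per class across the ranked cohort (after the relevance
cascade, so excluded targets do not distort the range). Degenerate cases
are fixed by convention: an all-equal class — including a single-target
cohort — scales to 0, because such a class carries no ranking information.

## Genomics post-processing

**Hard filters.** `QD > 2`, `FS < 60`, `MQ > 40`, `MQRankSum > -12.5`,
`ReadPosRankSum > -8`, `SOR < 4`. All comparisons are strict, exactly as
the operators are written, so a value sitting on a threshold fails — the
boundary convention is documented and tested. One threshold set is applied
to both SNPs and INDELs. Absent metrics (the rank-sum annotations are
routinely missing on homozygous sites) pass by default, matching common
hard-filtering practice; `missing_fails = TRUE` flips that.

**Downstream filters** (on hard-filter survivors): protein-coding biotype,
`AF < 0.01`, `ExAC_AF < 0.01`, consequence not synonymous, impact HIGH,
MODERATE or LOW (a variant is "modifier only" exactly when every
annotation block is MODIFIER; the most severe block is used otherwise).
Missing allele frequencies count as rare — absence of a population
frequency usually means the variant was not observed — with a switch to
invert that.

**Loss of function**: missense consequence, SIFT beginning with
"deleterious", PolyPhen damaging. Both `probably_damaging` and
`possibly_damaging` qualify by default since the rule names "damaging"
without qualification; `damaging = "probably_damaging"` restricts it.

Multi-allelic records are split per alternate allele before filtering,
since every predicate is per-allele.

## Target evaluation rules

* **Druggability**: *highly* = clinical precedence (any drug at phase
  ≥ 1, in any indication — precedence need not come from the studied
  disease) plus a 3D structure or surface localization; *potentially* =
  the feature without precedence. Modality is the union over
  clinical-stage drugs, or feature-implied for potentially druggable
  targets.
* **Safety** (first matching rule wins, mirroring the order the
  categories are defined in): target-attributed market withdrawal;
  target-attributed clinical withdrawal without a higher-phase ongoing or
  successful drug; essential gene. Withdrawals not attributed to the
  target do not flag it. Unsafe targets are *down-weighted* (safety score
  0), not removed — the intent is low priority, not exclusion.
* **Biomarker**: the union of evidence-tagged categories (diagnostic,
  prognostic, predictive, therapeutic); multi-category membership is
  expected and reported as such.
* **Novelty**: high-impact-journal discussion (IF > 8) within 10 years,
  news mention within 5 years, and no drug beyond phase 1 — all three
  required. The dates arrive as annotation columns (most recent qualifying
  publication/news date) rather than being recomputed from the document
  corpus, which keeps the taxonomy's genomics-only branch reachable:
  novel targets without literature provenance are *unknown knowns*;
  literature-backed novels split into *known knowns* (mechanism flag set)
  and *known unknowns*. The mechanism criterion is narrative in origin, so
  it is an explicit input column.
* **Tissue**: *exclusive* = detected in the disease tissue (lung) and
  nowhere else; *high_shared* = high in lung with any other tissue
  detected; otherwise *other*. A missing lung row counts as not detected
  and is logged.
* **Pathway enrichment** (`enrich_pathways()`): one-sided hypergeometric
  upper-tail p-values with Benjamini–Hochberg adjustment, the minimal
  standard choice for over-representation; the universe is the cohort's
  annotation table. Tests verify the p-values against direct tail
  summation to a relative error below 1e-10.

## Prioritization

Weights default to the 40/60 split — publications 12, congress 3, clinical
trials 9, patents 4, grants 6, news 6 (literature); druggability 12,
pathways 9, biomarker 3, safety 3, expression & mutation 12, tissue 9,
novelty 12 (disease). Theses are ingested and count toward the relevance
threshold but carry zero weight: exactly six literature classes are
weighted. The sums (40, 60, 100) are validated before any scoring, and
`reweight()` supports overrides under a *strict* policy (sums must still
hold) or a *normalize* policy (each arm rescaled proportionally).

How each disease parameter becomes a number in [0, 1] is a design choice
concentrated in one visible rule table (`disease_parameter_scores()`):
druggability 1 / 0.5 / 0; pathway overlap `min(count / 5, 1)` (a cap of 5
saturates the credit for promiscuous pathway membership); biomarker and
novelty indicators; safety 1 or 0; tissue 1 / 0.7 / 0.2; expression &
mutation the equal-weight mean of a DE-survivor indicator and a variant
severity score (HIGH 1, MODERATE 0.6, LOW 0.3). Every rule is monotone, so
improving any single piece of evidence can never hurt a target's rank —
a property the test suite checks over a thousand random perturbations.

Totals are reported raw on the 0–100 scale (no second cohort-wide
rescaling after weighting — rescaling would destroy comparability of
scores across runs and re-weightings). Ranking is descending by total with
alphabetical tie-break, making the output a deterministic permutation.

```{r reweight}
sm_view <- reweight(weight_config(policy = "normalize"),
                    disease = c(druggability = 24))
round(sm_view$disease, 2)
```

## The synthetic-data generator

No public corpus reproduces the proprietary literature-mining output the
pipeline is designed for, so validation rests on simulated cohorts with
planted ground truth (`simulate_cohort()`):

* **Documents**: per-target, per-class counts from a negative binomial
  (size 1) — literature counts are over-dispersed — at configurable mean
  rates (defaults around 0.3–3 documents per class); dates uniform over
  the 15 years before a fixed reference date (2023-01-01, so cohorts are
  byte-identical regardless of when they are generated); impact factors
  log-normal (median 3); positions categorical. *Planted top* targets
  receive 25+ documents in every class, recent dates, impact factors above
  10 and title/abstract positions — saturated evidence by construction.
* **DE tables**: control means log-normal; planted genes shifted by
  ±2 log2 units; p-values from a two-sample t-test on five simulated
  replicates per group with replicate noise 0.25 on the log2 scale,
  BH-adjusted. Under these conditions planted genes clear the default
  thresholds with wide margin and a false call requires a >6-sigma
  fluctuation, so planted up/down counts are recovered exactly.
* **Variants**: a configurable fraction drawn with all metrics strictly
  inside the hard-filter bounds, the rest violating exactly one sampled
  metric; ~8% missing rank-sum annotations; VEP-style consequence,
  impact, frequency, SIFT/PolyPhen fields; planted targets get one passing
  HIGH stop-gain and one passing loss-of-function missense each. Expected
  pass labels are computed at generation time directly from the printed
  inequalities. `simulate_variant_fixture()` additionally emits variants
  below / at / above every threshold and the full SIFT × PolyPhen grid.
* **Evaluation attributes** are planted label-first: the generator decides
  each target's class (at configurable fractions) and then writes
  attribute tables that realize that label under the classifier rules by
  construction, so classifier output can be compared to ground truth
  exactly.

What the generator does **not** emulate: document text (attributes only,
so no NER or concept-relevancy scoring is exercised), correlated evidence
across asset classes, symbol ambiguity beyond case/aliases, linkage
between variants, batch effects or count-level noise in expression (the DE
module consumes result tables, not counts). Passing tests therefore
demonstrate the correctness of the filtering, classification and scoring
logic under controlled separation — not the quality of any upstream mining
or calling on real data.

## Problem sizes and reproducibility

The test suite runs on cohorts of 60–600 targets with 200–550 variants and
up to 20 seeds for the rank-recovery property; the acceptance script uses
500-target cohorts over 5 seeds, a 550-variant boundary fixture and 100
random enrichment configurations. These sizes give stable statistics while
keeping a full run in the minutes range. All randomness flows through a
single integer seed per cohort; the same seed and spec reproduce files
byte for byte.

## Known limitations

* Parameter-level weightages inside a document score are uniform: each
  component contributes with weight 1 inside its class before the class
  weight is applied. Per-component weightages would be a straightforward
  extension of `scoring_config()`.
* Concept relevancy is represented by the mention-position category only;
  no TF–IDF over document text is computed.
* Gene symbol normalization is lexical; without an alias table, true
  aliases are treated as distinct targets.
* The structured-database arm is pass-through: database content arrives as
  tables and is never fetched from the source services.
* Enrichment assumes an unbiased universe; if the annotation table is
  itself evidence-biased, p-values inherit that bias.
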