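---
title: "Scoring participation in self-reported phenotype cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring participation in self-reported phenotype cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pindexr)
```

## The model

In a participant-driven cohort, each participant's public profile is a
bag of `(phenotype, value)` entries they chose to disclose. The scoring
model treats this as a bipartite weighting problem. Every unique
phenotype $F_i$ gets a score

$$S_i = \sum_{j=1}^{N} \mathbb{1}\{\text{participant } j \text{ has a
valid value for } F_i\},$$

the number of distinct participants validly reporting it; every
participant gets a participation index

$$\text{P-index}(j) = 100 \times
\frac{\sum_{i:\, j \text{ validly reports } F_i} S_i}{\sum_{i=1}^{M} S_i},$$

their share of the *theoretical maximum* $\sum_i S_i$ over the $M$ valid
phenotypes, on a 0–100 scale.

The model's assumptions are deliberate:

* **Self-weighting.** A phenotype is worth what the cohort collectively
  made it worth: each additional reporter raises both the phenotype's
  score and the value of reporting it, because shared phenotypes are the
  ones with statistical power for association studies. No external
  judgment of which phenotypes "matter" enters the index — that is what
  makes it unbiased.
* **Validity, not status.** Credit is for *declaring* a phenotype, not
  for *having* it: "no" counts exactly like "yes". This removes any
  incentive to misreport. Non-informative answers ("unsure",
  "not applicable", "other/don't know/no response", "no response",
  "not sure", "unspecified") earn nothing.
* **Once only.** Repeated measurements of the same phenotype count once;
  longitudinal credit is a deliberate non-goal.

The QtP-index applies the identical formula with the phenotype list
restricted to quantitative traits, with the denominator summed over that
restricted list. We draw the quantitative list from the already-filtered
valid table, so administrative or genotype entries can never re-enter
through the quantitative route.

## Normalization

Raw profile tables need three repairs before scoring, applied by
`pindex_pipeline()` in this order:

1. **Synonym reconciliation** (`apply_synonym_map()`): survey exports
   label the same phenotype differently ("1.2 --- Height" vs "Height").
   The default map ships with the six classical replacements and is
   fully user-overridable. The map must be acyclic, which makes the
   rewrite idempotent; merged entries are deduplicated.
2. **Checklist filling** (`fill_survey_negatives()`): disease surveys
   present a checklist and the profile lists only the checked ("yes")
   items, so an unchecked item by a survey taker means "no" — but a
   non-taker's missing item means nothing. We detect takers as
   participants with at least one entry from the survey's phenotype list
   (any value, valid or not: checklist surveys only surface answers, so
   any surfaced answer proves participation; the threshold is
   configurable). Detected takers' missing items are imputed as the
   literal value `"no"`, tagged `source = "imputed"` for audit. Only
   surveys flagged `checklist` in the catalog are filled — imputing "no"
   for a blood type would be nonsense. Filling never alters existing
   entries and is idempotent. A profile whose only survey answers are
   invalid values still counts as a taker for filling purposes; the fill
   report makes such cases visible.
3. **Deduplication** happens at load: identical
   `(participant, phenotype, value)` triples collapse to one record,
   case-insensitively, keeping first-seen casing.

## Filtering and its parameters

`filter_valid_phenotypes()` removes, in order of precedence:
administrative bookkeeping entries (exact, case-insensitive match
against `administrative_names`; defaults: enrolled, consent, account
created, eligibility screening, participant id, exam — entries generated
for every enrolled participant whether or not they contributed
anything), genome-data entries (substring match against
`genotype_keywords`; defaults: sequencing, genotyping, genome data,
23andme, variant — a keyword approach, since the curated exclusion list
of the original analysis is not public), and phenotypes scoring below
`min_share` (default 2). The `min_share` floor is what defeats junk
phenotypes: an invented phenotype scores 1 and is worthless unless a
second participant colludes; the cutoff can be raised if that ever
happens.

Tunable parameters, their defaults and units:

| parameter | default | meaning |
|---|---|---|
| `min_share` | 2 participants | minimum reporters for a valid phenotype |
| `quantitative_min_score` | 10 participants | support floor for QtP traits |
| `numeric_fraction` | 0.8 | share of values that must parse numerically |
| `hi`, `lo` | 90, 10 P-index points | strict tail thresholds |
| `min_group` | 30 participants | smallest reported stratum |

Quantitative-trait detection is a numeric-leading parse heuristic
(`"170 cm"` passes, `"blue"` does not) over each phenotype's valid
values. The original 88-trait list was curated by hand; a heuristic can
admit numeric-looking non-quantities (zip codes, dates), so the
selection is exposed as a plain character vector the user can edit
before calling `compute_qtp_index()`.

## Numerical and procedural choices

* **Ranking ties** are broken by ascending participant id after
  descending P-index, giving deterministic ordinal ranks; published
  rankings show tied rounded values at distinct ranks without stating a
  rule, so determinism was the design goal.
* **Suggestion gains** (`suggest_phenotypes()`) are quoted at the
  *current* score table: the hypothetical new report is not fed back
  into the scores. Gains therefore add exactly (a property the tests
  assert), at the cost of being a lower bound on the post-hoc value —
  the participant's report would itself raise the phenotype's score by
  one.
* **The sex-ratio test** is the exact binomial tail with null proportion
  0.5; one-sided is the upper tail of the male count, two-sided the
  standard minimum-likelihood sum, symmetric in its arguments. Both
  sidedness and the null proportion are parameters.
* **The rank-sum test** enumerates the exact distribution when the
  combined sample is at most 12 without ties, and otherwise uses the
  normal approximation with tie-corrected variance and continuity
  correction 0.5 — the standard Mann–Whitney large-sample treatment.
* **Degree cells** use floor(latitude) and the mathematical
  ceiling(longitude); with western (negative) longitudes the ceiling
  rounds toward zero, so (42.36, −71.06) lands in cell (42, −71). Cell
  boundary points (integral coordinates) stay in their own cell. Plot
  coordinates are the per-cell medians of the *unrounded* member
  coordinates.
* **Zip normalization** strips to digits, drops ZIP+4 suffixes, and
  left-pads to five digits, so `"2144"` geocodes as `"02144"`.
* **Degenerate inputs** fail loudly where silence would corrupt results:
  an empty valid-phenotype table (denominator 0), an empty quantitative
  list, an empty group in a statistical test, and an empty point set in
  clustering are all errors rather than NaNs.
* Participants reporting several distinct values for a stratification
  field (e.g. both sexes listed) form their own combined stratum rather
  than contaminating the two-group comparison; they are simply another
  label, excluded from male/female testing by construction.

## What the synthetic cohort emulates

`generate_cohort()` draws from a three-class mixture calibrated to the
participation structure observed in open cohorts: with probability
`p_zero` (0.27) a participant contributes nothing and exists only on the
roster; with probability `p_full_taker` (0.30) they take every survey;
otherwise they take each checklist survey with probability `p_answer`
(0.10) and the demographic profile survey with probability
`p_demo_answer` (0.70 — the profile survey is the enrollment entry
point, so partial takers complete it far more often than any disease
checklist). Checklist items are affirmative with `p_yes` (0.30, typical
of common-trait checklists dominated by high-prevalence items); a taken
checklist survey with zero affirmatives would be invisible on a real
profile, so survey taking is defined as *visible* taking: affirmative
counts are drawn conditional on at least one, and partial takers take at
least one visible survey. Records are corrupted realistically:
non-informative values at `p_invalid_value` (0.02), duplicated lines at
`p_duplicate_record` (0.01), administrative rows for every active
participant, and genome-data rows for a subset — all of which the
pipeline must clean out again.

Sex is male with probability 0.582 (plus a 0.005 non-binary share), and
`sex_effect` (0.10) shifts female survey-taking propensity upward —
applied to both the full-taker probability and the partial per-survey
rate, split as +`sex_effect`·(male share) for females and
−`sex_effect`·(female share) for males so the cohort-wide marginals stay
at their nominal values. Geography assigns each participant a state
(eight states with fixed weights) and a zip drawn from that state's
synthetic gazetteer, whose coordinates live in disjoint 2°×2° boxes.

Under these defaults the generated P-index distribution reproduces the
qualitative fingerprints of real participant-driven cohorts: a bimodal
distribution with roughly 30% above 90 and 27% exactly zero, and a
female-shifted index. What it does **not** emulate: disease comorbidity,
realistic per-disease prevalences, free-text value noise beyond the
fixed invalid set, medical-record phenotypes outside the survey battery,
or any genotype data. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's correctness and its ability to recover known
generative parameters — not that real cohorts satisfy the generator's
independence assumptions.

## Problem sizes in the test suite

The property suites run on 1,000 random mini-cohorts (≤ 20 participants,
≤ 15 phenotypes) checked exactly against an independent brute-force
double loop; parameter-recovery runs use one cohort of 2,000
participants (class-fraction recovery within three binomial standard
errors) and 50 replicates of 1,000 participants (rank-sum power check).
These sizes give the recovery checks their intended statistical
resolution while keeping each suite's runtime in seconds to a few
minutes.

## Known limitations

* Participation detection cannot distinguish a non-taker from a taker
  who answered "no" to everything; such takers are invisible in the
  input data itself, and their survey weight is unrecoverable by any
  method downstream of the profile scrape.
* The quantitative-trait heuristic needs human review (above).
* Synonym reconciliation is an explicit map; fuzzy matching of label
  variants ("systolic" vs "systolic blood pressure") is out of scope.
* The index rewards breadth, not accuracy: it cannot detect erroneous
  checkbox answers, only non-informative ones.
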