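---
title: "Methods: composite IHC biomarker signatures for relapse-free survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite IHC biomarker signatures for relapse-free survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcsig)
```

## The problem

Breast tumours respond very unevenly to adjuvant anthracycline-based
chemotherapy, and no routine assay tells apart the patients who will
benefit from those who will relapse regardless. One pragmatic approach is
a small panel of immunohistochemistry (IHC) markers — here TOP2A, PTEN,
EGFR, IGF1R and phospho-mTOR (read out twice: whole-cell and perinuclear)
— quantified by digital pathology on a tissue microarray (TMA),
dichotomised into high/low within the molecular subtypes where each marker
carries prognostic signal, and summed into a composite ±1 score that
stratifies relapse-free survival (RFS).

`ihcsig` implements that workflow end to end as reusable, tested
components: per-cell scoring, core QC, St Gallen subtyping, cutpoint
selection, signature composition and survival/ROC evaluation, plus a
synthetic-cohort generator so that every stage can be exercised and
validated without access to patient data.

## From cells to scores

Digital-pathology exports arrive as one row per detected cell with a
tumour/stroma class and per-compartment DAB optical densities (OD). The
scoring model is:

* **Intensity binning.** A cell's ordinal intensity (0–3, or 0–4 where a
  wider scale is configured) is the number of OD thresholds at or below
  its density (right-open bins). The thresholds are a platform
  calibration with no published values, so the shipped default is an even
  grid (0.2, 0.4, 0.6, optionally 0.8) and everything is overridable per
  biomarker.
* **Core QC.** Cores with fewer than 100 tumour cells are excluded;
  exactly 100 passes. Stromal cells never contribute to scores.
* **Percent positivity** for homogeneously staining readouts (TOP2A,
  perinuclear p-mTOR): the percentage of tumour cells with intensity ≥ 1.
* **H-score** for heterogeneous readouts (PTEN, EGFR, IGF1R, whole-cell
  p-mTOR): \(H = \sum_k k \cdot \%(\text{intensity} = k)\), range 0–300 on
  the 0–3 scale.
* **Triplicate aggregation.** Patients are arrayed in triplicate; the
  patient-level value is the mean of QC-passing cores (median available),
  missing when no core passes. The aggregation rule is a package
  convention — source material for such workflows typically leaves it
  unstated.

## Subtyping

St Gallen subtypes are assigned from ER, PR, HER2 and Ki67. ER/PR
positivity uses the Allred rule (proportion score ≥ 2 and total ≥ 3),
which on consistent inputs is exactly "≥ 1% of nuclei stained at any
intensity"; the Allred proportion bins (0, <1, 1–10, >10–1/3, >1/3–2/3,
>2/3 percent) follow the cited standard. Ki67 is positive strictly above
14%. HER2 status is a boolean input; ISH scoring is out of scope. The
five rules partition every complete marker set; any missing marker yields
`"Unknown"`, which is retained but excluded from subtype-specific
analyses and from the composite signature.

## Thresholds: median split versus survival-optimised scan

Each biomarker is dichotomised within the subtype group where its
prognostic association was reported. Two candidate strategies are
implemented:

* `median_cutoff()`: the within-group median, the unbiased default.
* `scan_cutoffs()`: every midpoint between consecutive distinct scores is
  a candidate; candidates leaving either arm below `min_group_frac`
  (default 0.1 — a common convention in cutoff-scanning tools, not a
  published value) are skipped; each candidate gets a Mantel–Cox log-rank
  test and observed/expected hazard ratio; the optimum is the minimal p,
  ties broken towards the candidate nearest the median.

`select_threshold()` arbitrates: a significant median split (p < 0.05)
always wins as the unbiased choice; otherwise a significant scanned
optimum that is notably different (by default > 20% of the observed score
range) replaces it; failing both, the median is kept and flagged
non-informative. The selection rationale is recorded on the result row.

The scanned minimal p is *optimistic*: it is a minimum over many
correlated tests. The package deliberately does not correct it by default
(matching the behaviour of the scanning tools practitioners use) but
exposes `adjust` for reporting, and the test suite demonstrates the
selection bias by simulation: on null data the minimal p concentrates far
below its nominal level.

Shipped fixed thresholds reproduce the published cutoffs: TOP2A 45%
(ER-negative), PTEN 100 (HER2-positive and Luminal B HER2-negative),
IGF1R 219 (Luminal B HER2-negative), whole-cell p-mTOR 100 (Luminal B),
perinuclear p-mTOR 1% (HER2-positive). EGFR's published description is
qualitative ("extremely strong staining"); this package operationalises
it as the 95th percentile of the non-Luminal-A cohort, resolved from the
data at run time and flagged as a convention. The published subtype
groupings for PTEN and IGF1R differ between the source's narrative text
and its summary tables; the shipped defaults follow the tables, and the
discrepancy is surfaced here rather than resolved.

## The composite signature

Each of the six readouts contributes +1 (high), −1 (low) or 0 (missing),
and the signature is their sum, possible range −6 to +6:

\[ S = \text{TOP2A} + \text{PTEN} + \text{EGFR} + \text{IGF1R} +
\text{p-mTOR}_{wc} + \text{p-mTOR}_{peri} \]

Missing-as-zero is an interpretive choice: it is the only reading under
which odd composite scores can arise from six ±1 terms, which is exactly
what the published score distribution (range −3 to +3) shows. The
alternative — excluding patients with any missing component — is
available via `missing = "exclude"`.

Two applicability modes are first class and reported side by side:

* `"cohort"` (package default): every biomarker is scored cohort-wide
  with its threshold.
* `"restricted"`: a biomarker contributes 0 outside its applicable
  subtype set, so e.g. a TNBC patient is scored on TOP2A and EGFR only.
  This mode reproduces a bounded, mostly-odd score distribution of the
  kind the published analysis observed, and it is the self-consistent
  mode for the synthetic cohort (whose hazard effects act only in the
  applicable subtypes).

Luminal A and unknown-subtype patients are excluded from stratified
analyses (`included = FALSE`): no biomarker captures Luminal A.
Stratification is three-group (>0, =0, <0) and binary (>0 vs ≤0).

## Survival and classification evaluation

* **Kaplan–Meier / log-rank.** `km_estimate()` wraps the product-limit
  estimator; `logrank_test()` computes the Mantel–Cox statistic with the
  hazard ratio estimated as \((O_t/E_t)/(O_r/E_r)\) and a log-scale CI
  with \(SE = \sqrt{1/E_t + 1/E_r}\) — the "log-rank HR" of common
  graphing software, so results are comparable with published tables.
  High expression / high score is always the test group; HR < 1 means
  protective. Groups with zero events give a degenerate, flagged HR with
  a one-sided CI.
* **Cox regression.** `cox_fit()` uses Efron tie handling (the more
  accurate choice; the source is silent on ties), checks design rank
  before fitting, and flags monotone likelihood. The multivariate model's
  covariate list is configuration (default: grade + subtype alongside the
  binary signature stratum).
* **Fixed-horizon ROC.** Outcome = relapse at or before the horizon;
  patients censored earlier without an event are excluded by default
  (their class is unknown) or optionally counted relapse-free. Because
  "outcome regardless of relapse time" and a 5-year summary are both
  plausible readings of the published analysis, both horizons (60 months
  and any-time) are computed. The AUC is the Mann–Whitney rank statistic
  over relapse-free/relapsed pairs; its CI uses the Hanley–McNeil
  standard error — a deliberate, documented departure from the
  Wilson/Brown proportion CI named in the source material, which does not
  define an AUC interval. Sensitivity is the fraction of relapse-free
  patients called relapse-free (score > 0); specificity the fraction of
  relapsed patients called relapsed.
* **Ancillary statistics.** Fisher's exact test (two-sided
  hypergeometric) for outcome-by-stratum tables; Kruskal–Wallis with a
  tie-corrected Dunn post hoc z test (Bonferroni-adjusted by default),
  written in-package because no installed package provides Dunn's test;
  correlations with the qualitative bands |r| < 0.4 weak, 0.4–0.7
  moderate, > 0.7 strong, matching the labelling convention of the
  published protein–gene correlation table.

## The synthetic cohort

The generator (`simulate_cohort()`) emulates the study conditions of a
293-patient adjuvant-chemotherapy TMA cohort:

* **Subtypes** drawn with prevalences 79/64/33/39/72 of 287 (Luminal A,
  Luminal B HER2−, Luminal B HER2+, HER2-enriched, TNBC), with
  ER/PR/HER2/Ki67 marker values generated to round-trip through the
  subtyping rules.
* **Biomarker scores** from truncated normals on each readout's native
  scale. Locations follow the published between-subtype ordering (TOP2A
  and EGFR highest in TNBC; PTEN and whole-cell p-mTOR lowest in TNBC;
  perinuclear p-mTOR flat with most mass near zero) and match published
  medians where printed (PTEN ≈ 100 in its pooled group, IGF1R ≈ 219 in
  Luminal B HER2−). Shape is a free choice — the source shows only box
  plots — and is exposed in the profile table.
* **Missingness** completely at random per readout, at the rates implied
  by the published per-biomarker Ns (273, 265, 271, 268, 281 of 293).
* **Relapse times** from an exponential proportional-hazards model: the
  subtype baseline hazard is multiplied by a per-biomarker hazard ratio
  when the patient is biomarker-high (defaults 0.287, 0.356, 0.2816,
  0.3832, 0.2977 for TOP2A, PTEN, IGF1R and the two p-mTOR readouts; EGFR
  defaults to a null effect, as its published association was not
  significant). Effects act only within each biomarker's applicable
  subtype group unless `restrict_to_applicable = FALSE`. This is the
  simplest model satisfying the proportional-hazards assumption that the
  downstream Cox analyses make.
* **Censoring** is administrative at 120 months — a convention, since
  the follow-up distribution is unpublished. Baseline hazards (0.0011,
  0.012, 0.013, 0.013, 0.005 events/month) were chosen once so the
  per-subtype marginal event fractions over that window land near the
  published 13–33% range after the protective effects are applied.
* **Reproducibility.** One integer seed drives a single generator in
  documented draw order; identical config + seed gives byte-identical
  tables.

What the generator does **not** emulate: spatial structure, core-to-core
heterogeneity within a patient, correlation between biomarkers beyond
their shared subtype, non-proportional hazards, informative censoring, or
the joint distribution of the real cohort beyond the stated marginals —
in particular the real composite-score frequency distribution (mode at
+1) is not matched, and the synthetic score distribution sits lower
because ~95% of patients are EGFR-low under the extreme-staining rule.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of configured effects, not clinical performance on real
data.

## Numerical choices and degenerate inputs

* Ties at a cutoff: "high" is `score >= cutoff` everywhere except the
  strict Ki67 rule (`> 14`).
* Constant score vectors: median split is flagged degenerate; scans
  refuse to run (no admissible candidate).
* Scan tie-breaks: minimal p, then proximity to the median cutoff.
* Zero-event arms: log-rank HR reported as 0/∞ with a one-sided CI and a
  degeneracy flag rather than an error.
* Cox separation: coefficient magnitude > 15 on the log scale triggers a
  monotone-likelihood flag; rank-deficient designs are rejected up front.
* Empty cores: scoring functions error on cores with no tumour cells; QC
  rejects them before scoring in the pipeline.

## Problem sizes used by the test suite

Distributional checks run at n = 10⁵ draws (subtype prevalences within
1%, intensity mixes within 1%, H-score expectation within 2 points).
Parameter recovery uses 50 cohorts of n = 2000 with a single active
hazard ratio of 0.25 and asserts ≥ 90% CI coverage. Oracle-equivalence
checks use exact permutation log-rank on fixtures of n ≤ 12 and
brute-force cutoff scans at n ≤ 30. Pipeline determinism is checked at
n = 150–300 patients. These sizes make the whole suite run in about a
minute while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The per-biomarker OD→intensity thresholds, the triplicate aggregation
  rule, the EGFR cutoff and the scanning group-size floor are
  conventions, clearly flagged and overridable, not published values.
* The log-rank HR (O/E method) is a first-order approximation; it agrees
  with Cox to ~5% at large n (tested) but can drift for extreme
  imbalance.
* The scanned-cutoff p value is optimistic by construction; treat it as a
  selection heuristic, not an inferential result.
* Cohort-wide reuse of a subtype-specific threshold (the `"cohort"`
  applicability mode) applies published cutoffs to subtypes where no
  association was demonstrated; the restricted mode is the conservative
  alternative.
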