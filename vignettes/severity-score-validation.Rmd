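---
title: "Validating clinical severity scores against mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating clinical severity scores against mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fevscore)
```

## The problem

Fever is among the commonest reasons adults seek care in low-resource
settings, and a minority of febrile illnesses progress to sepsis and death.
Bedside severity scores promise cheap, fast risk stratification: MEWS (the
Modified Early Warning Score), qSOFA (the quick Sequential Organ Failure
Assessment) and UVA (the Universal Vital Assessment, developed from
sub-Saharan African inpatient cohorts and the only one of the three to use
oxygen saturation and HIV status). fevscore implements the three
calculators exactly as specified by their published component bands, and
the statistical machinery used to validate them against a binary 28-day
mortality outcome in a multicentre febrile cohort: tie-corrected AUCs with
DeLong inference, operating-characteristic tables, logistic odds-ratio
models, and missing-outcome sensitivity analyses. A seeded synthetic
cohort generator emulating the four-site study structure makes every
pipeline stage testable without access to patient data.

## Score calculators

Each score is the sum of integer points over components (vital signs,
consciousness, and for UVA also HIV status). The band definitions live in
data-driven tables (`mews_band_table()`, `qsofa_band_table()`,
`uva_band_table()`) that serialise to JSON, so the defaults can be pinned
bit-exactly in tests and alternative weightings expressed without touching
code.

Decisions the published band tables leave open, and how they are closed
here:

* **Boundary gaps.** The published MEWS bands leave heart rate exactly 40
  (between "<40" and "41–50"), SBP exactly 70, and respiratory rate 8/9
  unassigned. The more severe band is extended to the boundary (HR ≤ 40
  scores 2, SBP ≤ 70 scores 3, RR ≤ 8 scores 2): a triage instrument
  should never under-score the sicker patient.
* **Measurement resolution.** Temperature bands are real intervals at
  0.1 °C (clinical thermometers report 0.1 °C); other vitals are integer.
  Non-grid inputs are rounded *half-up* to the component's resolution
  before banding (`round_to_resolution()`), because R's default
  round-half-to-even would make banding depend on the parity of the
  neighbouring grid value.
* **SBP ≥ 200.** Typographically ambiguous in the source table; scored 2,
  matching the standard MEWS instrument.
* **Stated ranges.** The source describes MEWS as 0–11 and UVA as 0–12,
  but the printed components sum to maxima of 14 and 13 under any
  consistent parse. The calculators follow the printed bands; the
  discrepancy is documented, not silently reconciled.
* **Modified GCS.** The motor examination records only three categories
  (spontaneous/verbal movement, pain only, none), scored 6/3/1; eye (1–4)
  and verbal (1–5) are conventional. The GCS→AVPU conversion needed for
  MEWS is not stated in the source; the standard teaching correspondence
  is used: A ⇔ 15, V ⇔ 9–14, P ⇔ 4–8, U ⇔ 3.
* **"+HIV" exploratory variants.** `score_plus_hiv()` adds a configurable
  number of points (default 2, the weight HIV carries inside UVA) for
  HIV-positive participants; the published analysis does not state the
  weight it used.
* **Unknown HIV status** scores 0 in UVA, identically to negative, per the
  published band table.

## ROC machinery for ordinal scores

An ordinal score with m deaths and n survivors is fully summarised, for
ROC purposes, by its per-level outcome counts (`score_counts`). The AUC is
the tie-corrected Mann–Whitney statistic

$$\widehat{AUC} = \frac{1}{mn}\sum_{i=1}^{m}\sum_{j=1}^{n}
  \left[\mathbb{1}(x_i > y_j) + \tfrac12\,\mathbb{1}(x_i = y_j)\right],$$

identical to the trapezoidal area under the empirical ROC step curve with
ties traversed along diagonals (`roc_points()`/`trapezoid_auc()` verify
this identity to machine precision in the tests).

Variance and tests use the DeLong structural components: for case $i$,
$V^{10}_i$ is the mean of the pair kernel over all controls, and for
control $j$, $V^{01}_j$ the mean over all cases. Then
$\widehat{Var} = S_{10}/m + S_{01}/n$ with $S_{10}, S_{01}$ the sample
variances of the components, and the paired two-score test statistic is

$$z = \frac{\widehat{AUC}_A - \widehat{AUC}_B}
  {\sqrt{Var(A) + Var(B) - 2\,Cov(A,B)}},$$

with covariances from the same components and a two-sided normal p-value.
On grouped counts the components are computed per level and weighted by
counts, which makes the whole engine O(levels) rather than O(mn).

Design choices:

* **Positivity convention** is score ≥ threshold. This is verified to
  reproduce the published operating-characteristic rows exactly and is
  deliberately not configurable.
* **Confidence intervals** are Wald intervals on the DeLong standard
  error, clipped to [0, 1]. The source does not state its CI method; the
  DeLong–Wald interval reproduces the published qSOFA interval
  (0.64–0.72) from the published contingency table, so it is adopted as
  the package's method (an inference, documented as such).
* **No continuity correction** on normal approximations; percentages are
  rounded half-up to 2 dp only at the reporting layer, all internal math
  is full precision.
* **Degenerate cells.** PPV at a threshold above the maximum observed
  score (no test-positives) and NPV at the minimum (no test-negatives)
  are reported as undefined flags, mirroring blank cells in published
  threshold tables, never as zeros.
* **Ladder inversion.** `reconstruct_counts_from_ladder()` inverts a
  printed sensitivity/specificity ladder to per-level counts by rounding
  cumulative class totals half-up and differencing. With ladders printed
  at 2 dp and class sizes in the low thousands, rounding recovers the
  integer counts exactly; the round trip
  `reconstruct ∘ threshold_table = identity` is property-tested.
* The Mann–Whitney U test (`mann_whitney_test()`) shares the AUC's pair
  kernel, so $U/(n_x n_y)$ equals the AUC by construction; its
  tie-corrected normal p-value is cross-checked against
  `stats::wilcox.test`.

## Regression models

`fit_logistic()` is binomial maximum likelihood via IRLS (delegating the
iteration to `stats::glm.fit`) with Wald standard errors from the inverse
observed information. Rank deficiency is an error naming the collinear
columns; perfect separation flags the fit as non-converged with a
diagnostic instead of emitting divergent estimates (no Firth-type
correction is applied — separation is reported, not repaired).

The published modelling choices that need interpretation:

* **Sparse-level grouping.** Score levels are grouped "from the top of
  the scale downward" until every retained level has at least `min_count`
  observations in a criterion cell. The source is ambiguous about whether
  the criterion counts participants ("fewer than five data points") or
  deaths ("less than 5 outcomes"); both are supported
  (`cell = "total"`/`"dead"`), with participants as the default. The
  grouping is surjective, order-preserving and idempotent
  (property-tested).
* **Reference levels.** Score entered as a categorical factor; reference
  0 for qSOFA and UVA, 1 for MEWS, per the published specification.
* **Covariates.** A priori adjustment for age group, sex, and HIV status —
  except that HIV is refused (an explicit error) as a covariate for UVA,
  because HIV status is a component of that score. Age enters as the
  six-band grouping 15–<25 … 65+ (reference 15–<25); the source's printed
  bands contain an obvious typographical gap (35–<40 followed by 45–<55),
  read here as 35–<45.
* **Wald CIs** throughout, consistent with the AUC machinery.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the four-site
study; it is first-class, tested code, not a fixture.

**Construction.** Each participant carries one latent severity factor
$z \sim N(0,1)$. Site (enrolment-weighted), age band, sex and HIV status
follow the published per-site distributions; admission (inpatient status)
is logistic in $z$; 28-day death is logistic in $z$, HIV, age and
inpatient status; vital signs load on $z$ with idiosyncratic noise. The
generator keeps `latent_severity` in its output so parameter-recovery
tests can fit the true model.

**Calibration, all done at design time and frozen as defaults:**

* Site-level admission and mortality intercepts are *computed*, not
  hand-tuned: `sim_config()` solves
  $E[\text{logit}^{-1}(\cdot)] = \text{target}$ by numerical integration
  over the latent severity and covariate distributions, against the
  published per-site inpatient fractions (43%/23%/45%/42%) and mortality
  (5.6%/2.2%/11.7%/6.0%). The implied overall mortality is 6.6%
  (printed as 7% in the source).
* Vitals are located and scaled to the published medians/IQRs (overall
  HR median 99, RR 20, SBP 117, SpO2 97, temperature 38.0), using
  log-normal forms for heart and respiratory rate (heavy right tails
  match clinical data) and a folded-normal deficit for SpO2.
* Severity loadings were calibrated so the three scores' AUCs on
  study-sized cohorts match the published triple (MEWS 0.67, qSOFA 0.68,
  UVA 0.82): oxygen saturation and consciousness — UVA's heavily weighted
  components — carry most of the severity signal, with HIV contributing
  through the mortality model directly (coefficient 1.6, an adjusted odds
  ratio near 5, as published). On 20 seeded cohorts of n = 2797 the
  generator yields mean AUCs of about 0.66/0.64/0.80 and UVA
  significantly outperforms both other scores in every replicate.
* The HIV coefficient, age slope (0.30 per decade) and inpatient effect
  (1.0) are fixed modelling choices exposed in `sim_config()`.
* Altered consciousness (GCS < 15) is logistic in severity
  (intercept −6.6, slope 3.5), giving ~3–5% prevalence overall and
  ~25–30% among deaths.
* Time to death is log-normal with median 10 days, for report realism
  only; no statistic uses it.

**Missingness.** `apply_missingness()` marks outcomes missing at the
loss-to-follow-up rate (default 12%) and each of the seven score
components independently at 3.6%, so roughly 22% of followed-up records
are component-incomplete and ~68% of all records survive complete-case
filtering, matching the published participant flow. The default mechanism
is missing-completely-at-random; `ltfu_dead_odds` adds an
outcome-dependent loss mechanism for stressing the sensitivity analyses.

**What the generator does *not* emulate**, and hence what passing tests do
not show about real data: fever aetiology and treatment pathways;
within-site clustering beyond the modelled covariates; any dependence of
missingness on unobserved severity (under the default); hypothermia
(enrolment required temperature ≥ 37.5 °C, so the UVA temperature
component is structurally silent — as it was in the study population,
where this was acknowledged as a limitation); and the real cohort's exact
records. Tests against the generator validate the *machinery* under a
plausible data-generating process, not the clinical conclusions; the
published summary tables shipped with the package
(`fiebre_qsofa_counts()`, `fiebre_ladder()`) are what tie the machinery to
the study's actual numbers.

## Pipeline and reporting

`validate_scores()` is the single entry point: complete-case filtering
with flow accounting (loss to follow-up first, then incomplete
components), score computation, per-score AUCs, the three pairwise DeLong
tests, full threshold ladders, subgroup AUCs by site and patient group
(reusing the full-cohort grouping and reference levels — the source is
silent on this, so the simpler convention is documented and used), both
missing-outcome sensitivity analyses (all missing set alive; all set
dead), and odds-ratio tables. Subgroup strata with a single outcome class
yield an AUC marked undefined with a reason code; the run continues.
`render_report()` writes full-precision JSON (fixed key order, so
identical inputs give byte-identical reports), a Markdown summary with
2-dp half-up rounding and blank cells for undefined statistics, and ROC
coordinate CSVs.

## Problem sizes used by the test-suite

Chosen to make the checks sharp while keeping a full test run around half
a minute: brute-force oracle equivalence on random cohorts of ≤ 200
subjects; paired-test type-I error on 2000 null replicates of n = 500
(rejection rate required inside the binomial 99% envelope of 0.05);
generator marginal checks and parameter recovery (within 3 SE) at
n = 20,000; and the UVA-first ordering on 20 seeded cohorts of n = 2797,
the published complete-case size, requiring both pairwise comparisons
significant in at least 19 of 20.

## Known limitations

* The DeLong p-values and Wald CIs are asymptotic; with very few deaths
  (small strata) they are anti-conservative, and subgroup output should
  be read accordingly.
* `reconstruct_counts_from_ladder()` assumes the printed ladder was
  computed on the same positivity convention (score ≥ threshold) and at
  full precision before rounding; a ladder printed from a different
  convention will fail its monotonicity checks rather than silently
  invert.
* The generator's single-factor severity structure cannot represent two
  scores carrying independent prognostic signals; it is sufficient for
  the ordering and calibration properties tested here, not a general
  febrile-illness simulator.
* Logistic models use complete cases only; no imputation machinery is
  provided beyond the two outcome-imputation sensitivity analyses.
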