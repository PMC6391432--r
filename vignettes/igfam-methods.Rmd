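---
title: "Methods: familial immunoglobulin biomarkers in high-risk CLL pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial immunoglobulin biomarkers in high-risk CLL pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igfam)
```

## The scientific problem

Family history is the strongest known risk factor for chronic lymphocytic
leukemia (CLL). In families with a statistical excess of CLL ("high-risk
pedigrees"), unaffected relatives can be screened for serum immunoglobulin
(Ig) phenotypes that may mark inherited susceptibility before any disease is
detectable. Two kinds of variables are derived from an eight-analyte serum
panel — free light chains (FLC κ and λ) and heavy/light chains (HLC: IgAκ,
IgAλ, IgGκ, IgGλ, IgMκ, IgMλ), all in mg/dL:

* **polyclonal variables**: the κ+λ sum per analyte class, e.g.
  IgM(κ+λ), indicating broad B-cell expansion;
* **monoclonal variables**: the κ/λ ratio per class, where a skewed ratio
  indicates clonal development.

`igfam` implements the full analysis pipeline around these variables:
abnormality classification against reference ranges, propensity-adjusted
comparisons of sampled pedigree relatives versus population controls, and a
pedigree-level comparison of cancer configurations using exact inference.
Because the individual-level registry data that motivated the design is
restricted, the package ships a seeded synthetic-data generator that emulates
the study conditions, so that every stage is testable end to end.

## Phenotype definitions

* **aFLC**: FLC κ/λ ratio strictly outside the clinically established
  diagnostic interval [0.26, 1.65] (`FLC_DIAGNOSTIC_RANGE`). A value exactly
  on a boundary is *normal*; "beyond the range" is read strictly.
* **Abnormal HLC ratios**: strictly outside the 95% reference range of the
  control sample, defined as the 2.5th–97.5th percentiles
  (`reference_range_95()`).
* **eIgM**: polyclonal IgM(κ+λ) at or above (`>=`) the 95th percentile of
  the control distribution (`eigm_threshold()`).

Percentiles use the type-7 convention (linear interpolation between order
statistics, R's default). The convention must be fixed for reproducibility;
type 7 is the one a reader recomputing ranges in base R will get. On the
control IgM distribution used by the generator (median 68 mg/dL, 95% range
22–220), the implied eIgM threshold is about 179 mg/dL.

Quality control removes, within each group (relatives vs controls), any
individual with at least one derived variable more than 5 standard
deviations from the group mean (`exclude_outliers()`). The rule is a single
pass: means and SDs are computed once on all individuals, exclusions are
applied, and the statistics are not recomputed. Any one extreme variable
excludes the whole individual, since a grossly aberrant panel is suspect as
a specimen, not as a single analyte.

## Pedigrees, kinship and the bloodline

Pedigrees are directed acyclic genealogy graphs read from PED/FAM-style TSV
(`read_ped()`). Kinship coefficients use the standard recursion over
individuals ordered parents-before-children; a missing parent is treated as
an unrelated, unrecorded marry-in. Relationship degree is defined from
expected relatedness, `2φ = 2^(-d)`: parents, children and full siblings are
first degree; grandparents, aunts/uncles and half-siblings second;
first cousins and great-grandparents third. This kinship-based rule (rather
than path counting) is what makes half-siblings second degree and "out to
cousins" exactly degree ≤ 3. It includes third-degree lineal relatives
(great-grandparents), which a literal "out to cousins" might or might not
intend; the kinship rule is the principled reading and is applied uniformly.
In inbred pedigrees `2φ` can fall off the power-of-½ grid; such pairs are
classified by minimum meioses through common ancestors (with the usual
reduction by one when the closest link runs through a full ancestral couple)
and flagged with a warning.

The *bloodline* is the set of designated apical founders plus all their
descendants; marry-in spouses are excluded from familial cancer counts.
PED files carry no founder flag, so `pedigree()` accepts an explicit
`founders =` argument and otherwise infers founders as the parentless
members whose downward descendant depth is maximal — an apical couple both
attain the maximum, while a spouse marrying in at a later generation sits at
least one level lower. This heuristic is the package's own convention and is
overridable.

`enumerate_relatives()` returns the deduplicated union of first- to
third-degree bloodline relatives over a set of index individuals, excluding
the index individuals themselves. Restricting to third degree balances
contributions across pedigrees of very different sizes.

## Association models

Sampled relatives and population controls differ in age and sex, with
nonlinear imbalance, so comparisons are propensity-adjusted:

1. **Propensity model** (`estimate_propensity()`): logistic regression of
   group on age, age², and a male indicator. Under separation the model is
   refitted with the Firth penalty, which always yields finite
   coefficients.
2. **Optimal matching** (`optimal_match()`): pairs the smaller group into
   the larger minimizing total |score difference| over *all* feasible
   pairings — optimal assignment, not greedy. Because the cost is an
   absolute difference of scalar scores, the optimal assignment is
   non-crossing in sorted order, so an exact O(nm) dynamic program solves
   the assignment problem; this is exact, and is verified against a
   brute-force all-pairings oracle in the tests. Matching can be stratified
   exactly on sex.
3. **Adjustment form**: the default (`ps_form = "covariate"`) enters the
   score as a covariate on the full cohort — the minimal reading of
   "propensity-score-adjusted regression". `"matched"` restricts to the
   optimally matched cohort (no score covariate), `"both"` combines them.

Polyclonal variables are compared by OLS of the variable on group + score;
the group coefficient is the adjusted difference in mg/dL. Dichotomous
abnormality flags are compared by **Firth bias-reduced logistic
regression** (`firth_logistic()`), which maximizes the Jeffreys-penalized
log-likelihood `ℓ(β) + ½ log det I(β)` by Newton iterations on the modified
score, with step-halving on the penalized log-likelihood plus a local
score-norm damping phase (the curvature approximation can otherwise cycle
near the optimum). Convergence requires the largest modified-score
component below 1e-8 within 100 iterations. The penalty keeps estimates
finite under separation and reduces small-sample bias — the reason the
method is standard for sparse case counts. For a saturated 2×2 design the
Firth solution coincides exactly with the Haldane–Anscombe
add-½-to-each-cell log odds ratio; the tests verify this identity
exhaustively over all small tables.

All inference is two-sided Wald with normal quantiles, α = 0.05, no
multiplicity correction. The multivariable model is a Firth regression of
group on eIgM + aFLC + age + sex, reported as odds ratios; the flags enter
as binary by default (a standardized encoding is available via
`encoding = "standardized"`, since either convention is found in practice).
The FLC-ratio age trend is per-group least squares, with slopes reported
per 10 years and the relative:control slope ratio; a zero reference slope
flags the ratio as undefined rather than returning an infinity.

## Exact inference on 2×2 tables

The pedigree cancer comparison uses small counts, so odds ratios come from
Fisher's exact method: the estimate is the conditional maximum-likelihood
odds ratio, i.e. the ψ solving `E[X | margins, ψ] = a` under the noncentral
hypergeometric distribution (mean matching — exactly the stationary point
of the conditional likelihood). The pmf is computed in log space, so cell
counts up to ~1e6 are stable. The CMLE root is found on the log-odds scale
to 1e-10 relative tolerance. Confidence limits invert the exact tails
(Cornfield): `P(X ≥ a | ψ_lower) = P(X ≤ a | ψ_upper) = (1−level)/2`, with
boundary counts yielding 0 and ∞ limits. The inversion equations are
solved on the odds scale with the reciprocal transform and conventional
root tolerance — the same numerical convention as `stats::fisher.test`,
with which the limits agree bit-for-bit. The convention is worth fixing
explicitly: in an extremely flat tail (e.g. an upper limit in the hundreds)
the data determine the limit only to a few parts in a thousand, so solver
parametrization shows up in the last printed digit. The two-sided exact
p-value uses the point-probability rule.

## The comparison-table bookkeeping

`categorize_pedigrees()` flags each pedigree by the phenotypes its sampled
members harbor; flags are *not* exclusive (a pedigree can appear in both
the eIgM and aFLC cohorts, and each is compared against the same normal
cohort, never against each other). A "normal" pedigree has no sampled
member with any abnormal phenotype (aFLC, eIgM, or abnormal HLC ratio); its
index set is its fully-normal sampled members.

Denominators follow the published table's conventions: CLL percentages use
the relatives-only denominator (index individuals were sampled CLL-free by
design); every other category uses index + unique relatives; sex-specific
categories (prostate — male; breast, gynecological — female) use the male
and female splits of the combined set. An individual contributes at most
once per category but may contribute to several categories. The
`exclude_index_history` sensitivity analysis removes the index individuals'
own diagnoses from numerators while keeping denominators (the comparison is
"removed", not redefined); a stricter variant that removes index members
entirely can be had by rebuilding the cohort. MBL is screen-detected and is
counted only among sampled individuals; unsampled relatives are non-events
for MBL, matching registry reality.

## The synthetic-data generator

`simulation_config()` defaults define the emulated study conditions: 23
pedigrees of 2–8 generations grown from apical founder couples (Poisson
offspring, 80% marriage probability, marry-in spouses), about 117 sampled
CLL-free bloodline relatives drawn 98% from first-degree relatives of
designated CLL cases, and 160 independent controls (ages normal around 66,
SD 15).

Ig sums are lognormal per group, calibrated from a median `m` and central
95% range `(l, u)` as `meanlog = log m`, `sdlog = log(u/l)/(2·1.96)` — a
symmetric-on-log compromise, since reported ranges are not exactly
log-symmetric (control IgM: median 68, range 22–220; relatives: 92,
33–286; analogous calibrations for FLC, IgA, IgG). HLC ratios are lognormal
centered on the geometric midpoint of their reference ranges. Two design
choices deserve emphasis:

* **aFLC is injected by designation**: a Bernoulli flag at the configured
  prevalence (6.8% of relatives, 1.3% of controls) forces the FLC ratio
  out of range (4:1 high:low side), and non-designated ratios are confined
  to the diagnostic interval. This makes the programmed prevalence exact —
  essential for power and calibration tests. The residual SD of the FLC
  ratio around its age trend defaults to 0.2, calibrated for internal
  consistency: with a larger scatter the *natural* out-of-range mass of
  controls would by itself exceed the 1.3% of controls the classification
  is meant to produce.
* **eIgM is emergent, not injected**: with the calibrated group lognormals,
  the probability that a relative's IgM(κ+λ) exceeds the control 95th
  percentile is about 11% in closed form — the generator does not distort
  the IgM distribution to hit a target rate, and the truth JSON records
  the implied rate.

The FLC ratio follows `0.95 + slope·(age − 60) + N(0, sd)`, with slopes
0.010/year for relatives and 0.0038/year for controls. Because designated
out-of-range values are age-independent, the *observable* slope of the
mixture is diluted to `(1 − prevalence) · slope`; the truth bundle records
both the programmed and the marginal slope, and recovery is judged against
the marginal one (the closed-form estimand of the fit actually performed).
Within-range resampling truncates the trend slightly at the interval
boundaries; at the default SD this residual attenuation is about 1%.

Cancer diagnoses are independent Bernoulli per individual and category at
rates depending on the pedigree's cohort (eIgM > aFLC > normal precedence
when a pedigree harbors both; a single rate column per individual keeps the
generator simple — the analysis itself still treats cohort membership
non-exclusively). CLL is drawn only for non-sampled bloodline members, MBL
only for sampled ones, sex-specific categories gated on sex, and marry-ins
receive nothing. Default rates mirror the published comparison table
(e.g. B-cell 1.0% normal vs 4.8% eIgM — implied odds ratio ≈ 5.0; male
prostate 8.0% vs 21.8% near aFLC). MBL rates are expressed per sampled
index member, because that is where MBL can be observed.

What the generator does **not** emulate: genetic transmission of liability
(cancer correlates within a pedigree only through its cohort), ascertainment
of high-risk pedigrees, assay noise structure, renal effects on FLC, or
realistic ages of onset. Passing the pipeline's tests on synthetic data
therefore demonstrates correctness of the *computations and bookkeeping*
under the stated model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Ratio boundaries are closed (boundary = normal); eIgM uses `>=`.
* A constant or group-collinear propensity score is dropped from the linear
  model with a warning (the estimate then reduces to the raw difference in
  means); matched-cohort fits omit the score covariate by construction.
* Degenerate 2×2 margins (a zero row or column total) are inestimable and
  error; boundary cells yield 0/∞ estimates and one-sided intervals.
* Firth fits error after 100 Newton iterations without convergence,
  reporting the last iterate; rank-deficient designs are rejected.
* Zero variance in an outlier-exclusion group excludes nobody for that
  variable; constant phenotype flags are dropped from the multivariable
  model with a warning.
* Reference ranges require ≥ 40 controls; degenerate (zero-width) control
  distributions error.

## Problem sizes used in the test-suite simulations

Replicated checks run at the study's own scale (120 relatives / 160
controls) with 500–1500 replicates for bias, coverage and type-I
calibration, and exhaustive scans cover all 2×2 tables with margins ≤ 12
(exact-method oracle) and all cell counts ≤ 20 (Firth–Haldane identity).
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full run in minutes.

## Known limitations

* Wald intervals throughout; no profile-likelihood or bootstrap CIs.
* The exact machinery covers single 2×2 tables only — no mid-p variants,
  r×c tables, or stratified (Mantel–Haenszel) exact inference.
* The founder heuristic can misclassify unusual topologies (e.g. two
  apical couples joined several generations down); pass `founders =`
  explicitly in such cases.
* OLS Wald coverage is slightly below nominal when group variances differ
  markedly (as with two differently-calibrated lognormal groups); the
  package follows the conventional homoskedastic form.
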