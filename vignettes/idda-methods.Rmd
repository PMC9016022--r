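---
title: "Scoring immune dysregulation activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring immune dysregulation activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iddakit)
```

## The score

The IDDA2.1 score is a physician-reported, per-visit activity measure for
inborn errors of immunity (IEI) with immune dysregulation. A visit record
holds 22 items: 14 organ/feature involvements graded 0–4 (0 absent; 1 mild,
transient, no treatment; 2 moderate, intermittent therapy; 3 severe,
continuous therapy; 4 life-threatening, refractory, irreversible), the
Karnofsky/Lansky performance scale (%), hospitalization and ICU days out of
the last 100 days, four supportive-care items (IgG substitution, chronic
infestation, any other organ dysfunction, nutrition status), and a
malignancy flag that is noted but never scored. The total is

$$
\mathrm{IDDA2.1} = \Big( \sum_{i=1}^{14} g_i \;+\; H \;+\; U \;+\;
\sum_{j=18}^{21} s_j \Big) \times M,
$$

with the hospitalization term $H = 0.1\,d_{16}$ capped at 4 from 40 days
on, the ICU term $U = 0.8\,d_{17}$ capped at 8 from 10 days on, and the
performance multiplier $M = 150/p$ for a performance scale $p > 29\%$ and
$M = 6$ otherwise. All three branch conditions are strict (`< 40`, `< 10`,
`> 29`), matching the published spreadsheet expression; `idda_hosp_term()`
and `idda_icu_term()` are continuous at their caps, while the multiplier
deliberately jumps from 5.0 at 30% to 6 at 29% — the fixed floor exists to
stop the division from inflating scores without bound in moribund patients.
The attainable range is 0 to $(56 + 4 + 8 + 15) \times 6 = 498$; the score
is monotone in every additive item and antitone in the performance scale.
The IgG substitution item contributes 0 (none), 2 (sporadic) or 3 (regular
IV or SC — the route does not change the value).

Grades use integers only. The performance scale is accepted as any integer
in 10–100, not only the conventional deciles, because the formula divides
by the raw value; non-decile entries yield a warning-severity finding so
data-entry slips remain visible without blocking scoring. Hospital and ICU
days may be fractional (they are rates over a 100-day observation window)
and must jointly fit in that window. Performance below 10% is rejected.

### Missing data

Graded items (lines 1–14, 19–21) may be recorded as `NA`, "not assessed",
which is distinct from grade 0. A visit containing `NA` items is not
scoreable by default (`missing_policy = "refuse"`); opting into
`missing_policy = "zero"` imputes absence, which makes the resulting total
a lower bound on the true score. Performance, hospitalization, ICU, IgG
status and the malignancy flag are always required.

## Cohort kaleidoscope profiles

The kaleidoscope view reduces the graded record to qualitative presence
and aggregates a cohort into the percentage of patients showing each of 17
features, plotted on a fixed circular axis order: the 14 organ items, then
any-other-organ dysfunction (line 20), then hypogammaglobulinemia/IgG
substitution (line 18), then malignancy (line 22). Lines 15–17
(percentages), 19 (chronic infestation) and 21 (nutrition) are excluded
from the radar. Presence means grade ≥ 1 for graded items — the minimal
faithful reading of "qualitative involvement"; any substitution (numeric
value > 0) for the IgG axis; and the flag itself for malignancy.

Aggregation is patient-level, not visit-level. By default each patient is
represented by their most recent visit (`visit_policy = "latest"`); the
alternative `"worst"` policy builds a lifetime phenotype from the maximum
grade per item across visits, which matches how case series report
ever-present features. Both are provided because published cohort figures
rarely state which convention they used. Every axis carries its own
denominator — the number of patients in whom that feature was assessed —
so partially documented cohorts do not fabricate absence; an axis with
denominator 0 is drawn as a gap, not as 0%.

## Phenotype clustering

Disease-by-feature frequency matrices (proportions in $[0,1]$) are
transformed with a truncated logit, $f(p) = \ln(q/(1-q))$ with
$q = \min(\max(p, \varepsilon), 1-\varepsilon)$ and $\varepsilon = 0.01$
("truncated at 1%"), then rows and columns are clustered independently by
agglomerative complete linkage on Euclidean distances. The transform
spreads the compressed ends of the percentage scale, so a feature moving
from 1% to 10% counts as much as one moving from 50% to 85%, and the
clamping keeps 0% and 100% finite. The natural-log base is our choice —
the convention of the original analysis tool is unstated — and only scales
all distances by a constant, leaving the dendrogram topology unchanged.
Feature scaling before the distance computation is off by default
(`scale = "none"`): the transformed values already share one scale, and
centering would discard overall-burden information; `"rows"` and `"cols"`
are exposed for users who want the standard heatmap-package behaviour.
Rows with an unavailable axis are imputed at the clamp floor
$\varepsilon$, with a warning, before clustering.

Complete linkage guarantees non-decreasing merge heights (an ultrametric),
which the test suite asserts, and the whole merge sequence is checked
against a naive $O(n^3)$ agglomeration oracle on randomized small
matrices. Distance ties are broken by `stats::hclust`'s deterministic
lowest-index rule; random continuous inputs make ties measure-zero, and
the duplicate-row case (merged at height 0 first) is tested explicitly.
Dendrograms export to Newick with merge heights as branch lengths; the
heatmap renders the transformed values with a red-high/blue-low diverging
palette and the dendrograms on the margins.

## The synthetic cohort generator

No single-patient data accompany published cohort kaleidoscopes, so the
generator exists to make every pipeline stage testable and to state the
study conditions explicitly. An archetype is a generative description of
one disease: 17 per-axis presence probabilities (independent Bernoulli
draws per patient), a severity distribution over grades 1–4 given presence
(default uniform), a baseline performance scale eroded by 4 points per
present feature with Gaussian noise (SD 5, clamped to 10–100 and rounded),
truncated-normal hospitalization and ICU day counts whose means scale with
the fraction of present features (rescaled if they would jointly exceed
the 100-day window), and categorical distributions for the infestation,
nutrition and IgG-route items. All randomness flows from a single integer
seed; per-cohort seeds in a multi-cohort study are derived
deterministically from it.

The three bundled archetypes sketch a Tregopathy-like profile (dominant
enteropathy, autoimmune cytopenia, skin/endocrine involvement), a
CVID-like antibody deficiency (near-universal hypogammaglobulinemia,
lung disease, granulomas) and an EBV-susceptibility profile (HLH,
lymphoproliferation, lymphoma risk). They are illustrative, not calibrated
to any published cohort, and every pair differs by at least 0.45 presence
probability on six or more axes — a margin chosen so that archetype
recovery by clustering is well-posed and so the separation precondition is
robust to floating-point representation of the probabilities. Features are
sampled independently; real phenotypes are correlated (e.g. enteropathy
with failure to thrive), so passing recovery tests shows the pipeline
separates frequency profiles as designed, not that it would resolve any
real pair of diseases.

## Problem sizes and verification

The test suite verifies the formula against an independent line-by-line
transcription of the published spreadsheet expression on 10,000 random
admissible records (tolerance $10^{-9}$), checks the 0–498 range on an
extreme-value grid (justified by monotonicity in every item), runs the
naive complete-linkage oracle on 200 random matrices of up to 6 rows, and
checks logit antisymmetry/monotonicity on a 10,000-point grid. The
archetype-recovery experiment uses 3 archetypes × 8 cohorts × 50 patients
(seed 42) and requires an adjusted Rand index of at least 0.9 after
cutting the disease dendrogram at $k = 3$; empirical-frequency convergence
is checked at $n = 2000$ within 3 percentage points. These sizes give
stable stochastic checks while keeping the default test run fast.

## Known limitations

* The package implements the 2.1 formula only; the original IDDA v1
  calculation is not reproduced here.
* Cohort percentages from published figures cannot be regenerated — the
  underlying single-patient data are not public — so cohort-level checks
  are property-based on synthetic data.
* "Presence" for cohort statistics is grade ≥ 1; if a registry treats
  grade-1 findings as clinically silent, frequencies will read higher than
  that registry's convention.
* No survival analysis, no principal-component or bootstrap support for
  the clustering, and no diagnosis prediction: the clustering output is
  descriptive.
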