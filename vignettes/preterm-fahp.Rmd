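---
title: "Fuzzy AHP risk assessment of preterm birth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy AHP risk assessment of preterm birth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretermrisk)
library(dplyr)
```

## The problem and the model

Assessing an individual pregnant woman's risk of preterm birth is a
multi-criteria problem: the relevant factors span socio-economic
circumstances, lifestyle, clinical and obstetric history, and findings made
during the current pregnancy, and for many of them only an expert's
qualitative reading is available. The model implemented here treats the
problem as a two-level weighted aggregation of linguistic judgments:

1. **Weights.** Obstetricians compare risk *dimensions* (and, within each
   dimension, risk *factors*) pairwise on a fuzzy Saaty scale. Each
   comparison is a triangular fuzzy number (TFN) `(a, m, b)`, membership
   rising linearly from `a` to 1 at the mode `m` and falling to 0 at `b`.
   Weights are derived by extent analysis (see below).
2. **Scores.** For a given case, each expert labels every factor on a
   six-term linguistic scale. Labels are aggregated across the panel and
   defuzzified into a degree per factor; the model-based diagnosis is
   `MBD = sum_j w_j sum_i w_ij degree_ij`, a convex combination of the
   degrees when the weights are normalized, hence a score in [0, 1].
3. **Diagnosis.** The score is fuzzified back over the case scale and the
   maximal-membership term is reported as the linguistic diagnosis.

The package keeps every intermediate (synthetic extents, possibility
matrices, consistency reports, aggregated judgment TFNs) attached to its
result objects so that each stage can be audited.

### Extent analysis

For a reciprocal fuzzy pairwise matrix `M` over `n` criteria the fuzzy
synthetic extent of criterion `i` is its fuzzy row sum multiplied by the
fuzzy reciprocal of the grand total, so
`S_i = (rowsum_i.a / total.b, rowsum_i.m / total.m, rowsum_i.b / total.a)`.
Extents are compared by the degree of possibility

```
V(S2 >= S1) = 1                                      if m2 >= m1
            = 0                                      if a1 >= b2
            = (a1 - b2) / ((m2 - b2) - (m1 - a1))    otherwise,
```

the height of the intersection of the falling edge of `S2` with the rising
edge of `S1`. The weight of criterion `i` is
`d'(A_i) = min_{k != i} V(S_i >= S_k)`, normalized over criteria.

Extent analysis is used because it is the established weight-derivation
method for this model family, but it has a well-documented pathology: a
criterion whose extent lies entirely below another criterion's support
receives weight exactly zero, even though its judgments are informative.
The package keeps the canonical behaviour, warns whenever a zero weight is
produced, and offers `zero_floor = TRUE` (a floor of 1e-6 on the minimum
degrees before normalization, off by default) for users who prefer strictly
positive weights. Alternative weighting schemes (fuzzy geometric
mean/Buckley, fuzzy eigenvector) are out of scope.

### Consistency

Judgment consistency is checked on the crisp matrix of modal values:
`lambda_max` is its principal eigenvalue, `CI = (lambda_max - n)/(n - 1)`,
and `CR = CI / RI(n)` with Saaty's random-index table (`n = 3..15`;
`CR = 0` by convention for `n <= 2`, where a reciprocal matrix is always
consistent). Judgments are accepted when `CR < 0.1`;
`build_hierarchy()` refuses inconsistent matrices unless `force = TRUE`.
Whether a multi-expert consistency figure should be computed per expert or
on the aggregated matrix is not fixed by the protocol; the package exposes
`consistency_ratio()` for any single matrix, so both conventions are one
`lapply` away, and `build_hierarchy()` reports the aggregated-matrix CR in
its audit attributes.

### Group aggregation

Experts' case judgments are combined per factor as
`e_agg = (min, geometric mean, max)` of the labels' scalar values. The
protocol prescribes the geometric mean only for case judgments; for
pairwise *matrices* the package extends it componentwise (each of `a`, `m`,
`b` averaged geometrically across experts), the standard group-AHP choice,
because it is the unique simple aggregate that preserves matrix
reciprocity exactly. A `(min, geomean, max)` aggregate across experts'
matrix entries would not.

The scalar value of a linguistic label is its **modal value**, consistent
with the modal-value convention used for the consistency check. This is
also the defuzzifier for `e_agg`: the degree entering the MBD sum is
`e_agg.m`, the maximum-membership defuzzification and the only component of
`e_agg` produced by the geometric-mean consensus. Whether the original
protocol used the mode or a centroid is not recoverable; the centroid
`(a + m + b)/3` is available via `defuzz = "centroid"` in
`aggregate_case()`/`assess_cases()`, with modal as the default.

**Floor annihilation.** The lowest case-scale term ("none") has modal value
0; a single such judgment would zero the geometric mean of an otherwise
non-trivial panel. Zero values are clamped to `1e-6` with a warning. The
clamp keeps the arithmetic finite but the consensus still collapses toward
the floor (e.g. one "none" among 35 judgments of "low" multiplies the
consensus by roughly 0.7); this is a property of geometric-mean consensus
on a scale with a zero modal point, not of the implementation, and it
shapes the simulator defaults described below.

## Linguistic scales

The case scale is the evenly spaced triangular Ruspini partition on [0, 1]:

| term | a | m | b |
|---|---|---|---|
| none | 0 | 0 | 0.2 |
| low | 0 | 0.2 | 0.4 |
| medium | 0.2 | 0.4 | 0.6 |
| high | 0.4 | 0.6 | 0.8 |
| very_high | 0.6 | 0.8 | 1 |
| extreme | 0.8 | 1 | 1 |

Adjacent memberships sum to 1 at every interior point, so fuzzification of
a crisp score is an exact linear interpolation between the two neighbouring
terms. This term set is a *reconstruction*: the published scale table is
only available as an image, and only the "low"/"medium" pair is attested
numerically (a score of 0.36120376 must fuzzify to 0.19/0.81 at two
decimals, which pins the modal points to multiples of 0.2). The edge terms
are shoulders (`a = m` or `m = b`) so the scale saturates at the domain
boundary. Every function that touches a scale accepts a replacement built
with `linguistic_scale()`, and scales are serialized in the hierarchy JSON
config.

The comparison scale is Saaty-style: intensity `i = 1..9` maps to
`(max(1, i - 1), i, min(9, i + 1))`, except "equal" which stays crisp
`(1, 1, 1)` (the diagonal convention); reciprocals are fuzzy inverses of
these and are not scale terms. Labels are matched case-insensitively with
whitespace trimmed, since judgment CSVs are typically hand-entered, and
numeric strings "1".."9" alias the verbal terms.

## The packaged hierarchy

`preterm_hierarchy()` ships the six published dimension weights
(information during pregnancy 0.339, previous-pregnancy history 0.306,
clinical history 0.166, gynecological/obstetric history 0.1342,
behavioural/lifestyle 0.042, socio/personal/economic 0.0115). The printed
weights sum to 0.9987; they are kept as printed, and the hierarchy
validator tolerates weight sums within 0.01 of 1 for exactly this reason
(published tables are rounded). Per-factor weights were never published in
machine-readable form, so the fixture's local weights are a clearly
labelled uniform reconstruction; users supply their own via
`risk_hierarchy()` or derive them from matrices via `build_hierarchy()`.

## Classification and ranking conventions

- `classify_mbd()` breaks exact membership ties toward the later
  (higher-risk) term: at a score of 0.5 the diagnosis is "high", not
  "medium". Clinically conservative defaults are preferable for a
  screening-style score.
- `rank_cases()` sorts by decreasing score with a stable order for ties.
- Reports round to 2 decimals only at display time; all computation and all
  machine-readable output keep full double precision.

## Numerical choices

- `lambda_max` is computed by power iteration (tolerance 1e-12 on both the
  eigenvalue and the iterate, cap 1e5 iterations); a modal matrix is
  strictly positive, so the Perron root is simple and the iteration
  converges. The test suite cross-checks against a dense eigensolver.
- Reciprocity is validated at 1e-9 relative tolerance; CSV inputs that
  supply both triangle halves are checked at 1e-6 (hand-entered data).
- TFN inversion requires strictly positive support; nonpositive comparison
  values are rejected as invalid rather than silently clamped.
- Minimum possibility degrees use the exact minimum; no jitter is applied
  to break ties.
- All simulators derive one substream seed per expert/case from the root
  seed, so outputs are byte-identical for a fixed seed and insensitive to
  evaluation order.

## What the simulators emulate

`simulate_panel()` emulates a questionnaire-based elicitation: each
expert's latent ratio for a pair is the true weight ratio perturbed by
multiplicative lognormal noise (`exp(sigma * z)`, the standard AHP
simulation model), then *snapped* to the nearest 1..9 intensity —
questionnaires collect discrete intensities, and snapping is what makes
small planted weights recoverable only up to the scale's resolution. With
the default panel size of 35 and `sigma = 0.05`, aggregated extent weights
reproduce a planted 6-dimension ranking exactly in the seeded tests — with
the caveat that the two smallest planted dimensions receive extent weight 0
(the pathology above) and tie; their printed order falls back to input
position, which the recovery test documents.

`simulate_cases()` emulates a validation exercise: each case draws a latent
label per factor from `risk_mix`; each expert echoes the latent label with
probability `concordance` and otherwise reports an adjacent term (experts
rarely mislabel by more than one severity step). The latent *overall*
diagnosis of a case is sampled from the fuzzified membership degrees of the
latent MBD: under a Ruspini scale those degrees are the linear
interpolation weights between the two neighbouring terms, so the sampled
term's modal value is unbiased for the latent score. Deterministic
nearest-term rounding would systematically bias the simulated expert
diagnoses whenever the population-mean MBD falls between modal points, and
the paired t-test at `n = 153` is sensitive enough to flag a bias of a few
thousandths.

The default `risk_mix` (medium 0.45, high 0.30, very_high 0.15, extreme
0.10) concentrates on the informative upper range of the scale and places
no mass on the floor terms. This is deliberate: because of floor
annihilation, a population with latent "low"/"none" factors is *not*
score-concordant under geometric-mean consensus — an expert occasionally
mislabelling a low factor as "none" drags the model score well below the
experts' overall score — so a simulated "concordant regime" that included
floor mass would contradict its own premise. Floor behaviour is exercised
separately (degenerate all-"none" populations, clamp warnings) rather than
mixed into the concordance study.

What the simulators do **not** emulate: real clinical covariates
(gestational ages, lab values, outcome data), correlations between factors
within a case, systematic expert biases (leniency/severity), or
informative missingness. Passing the simulation-based tests therefore shows
that the pipeline recovers known structure under its own noise model — not
that the model is clinically valid. No birth-outcome data is involved
anywhere; sensitivity/specificity against outcomes is explicitly out of
scope.

## The validation protocol

`validate_model()` compares, per case, the panel's aggregated overall
diagnosis (geometric-mean score of the "overall" judgments) with the model
score, using a two-sided paired Student t-test with sample standard
deviation and `n - 1` degrees of freedom. Degenerate branches are explicit:
identically zero differences give `t = 0, p = 1`; a constant nonzero
difference gives a divergent statistic, reported as `p = 0`. Concordance is
declared when `p >= 0.05`. (The source protocol's phrasing — no difference
at `p < 0.05` — is self-contradictory as written; a *large* p-value is what
indicates no detectable difference, and that is the reading implemented.)
Because a score-level test can mask categorical disagreement, the report
also carries per-case label agreement between the model diagnosis and the
term nearest the expert score. One pooled test over all cases is computed
(per-case testing is not meaningful with a single score pair per case).

## Problem sizes in the test suite

The suite runs the oracle comparisons on 100 random matrices of orders
3–7, the MBD property checks on 200 random hierarchies, weight recovery on
20 replicates of 35-expert panels, and the validation study on 100
replicates of 153-case, 35-expert populations plus 1000 null replicates for
the empirical type-I error — sizes chosen to match the study's stated panel
and cohort while keeping a laptop test run in a few minutes.

## Known limitations

- Extent-analysis zero weights: small criteria can be assigned exactly
  zero; warned about, floor-protectable, but inherent to the method.
- The case scale and the per-factor local weights are reconstructions
  (documented above); analyses that depend on the *exact* published
  per-factor weights cannot be reproduced from published sources.
- Geometric-mean consensus degenerates at the scale floor; the 1e-6 clamp
  is a pragmatic fix, not a fuzzy-theoretic one.
- Only triangular fuzzy numbers are supported (no trapezoidal or type-2
  sets, no Mamdani/Sugeno rule bases), and only complete pairwise matrices
  (no incomplete-matrix completion).
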