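---
title: "Adaptive regression modeling of biomarkers of potential harm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive regression modeling of biomarkers of potential harm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bophmars)
```

## The modeling problem

Large cross-sectional exposure studies measure, on each subject, a panel
of *biomarkers of exposure* (BOE — nicotine equivalents, serum cotinine,
total NNAL, 1-hydroxypyrene and other smoke-constituent metabolites),
*biomarkers of potential harm* (BOPH) on disease-relevant pathways —
white blood cell count (WBC, inflammation), urinary
8-epi-prostaglandin F~2α~ (EPI8, oxidative stress), urinary
11-dehydro-thromboxane B~2~ (DEH11, platelet activation) and HDL
cholesterol (lipid metabolism) — plus clinical labs, demographics and
lifestyle covariates. The question is which combinations of exposure and
covariates predict each BOPH, and how much of its variability they
explain.

`bophmars` implements a complete adaptive-modeling workflow for this
setting:

1. **Preparation** — below-limit-of-quantification (BLLOQ)
   substitution, an 80/20 analysis/validation split, stratified median
   imputation, categorical dummy coding, derived variables (creatinine
   clearance).
2. **Screening** — a random forest ranks all candidate predictors by
   permutation importance; nested top-*k* sets with cross-validated
   R² yield a large (30-variable), medium and small predictor set.
3. **Spline model discovery** — multivariate adaptive regression
   splines (MARS) with exact knot search, grown over a control lattice
   (3 model types × 4 basis budgets × 2 entry penalties × 3 predictor
   sets = 72 runs), pruned by generalized cross-validation (GCV), with a
   preferred model chosen for fit *and* parsimony.
4. **Interpretable refit** — the hinge basis is reparametrized exactly
   into the threshold (IFGT/IFLT) basis, then refit by complete-case OLS
   on unimputed data; the model is applied and refit on the validation
   partition.
5. **Importance** — marginal and delta R² for groups of basis
   functions sharing a source variable.

Because the original study data are proprietary, the package ships a
seeded synthetic cohort generator whose generating truth is the set of
published final models; every pipeline stage is therefore testable
against known coefficients and known population R² values.

## The spline model and its bases

MARS builds piecewise-linear models from reflected *hinge* pairs
$\max(0, x - c)$ and $\max(0, c - x)$, where the knot $c$ is always an
observed data value. The forward pass performs an exact search over all
(variable, knot) candidates, adding the pair that most reduces the
residual sum of squares; for two-way interaction models (type 2) it also
searches products of an existing degree-1 basis function with a new
hinge pair in a different variable. Model type 0 restricts the search to
untransformed linear terms, and type 1 to additive hinge
transformations.

The backward pass deletes terms one at a time (least RSS increase
first) and selects, along the deletion path, the model minimizing

$$\mathrm{GCV}(M) \;=\; \frac{\mathrm{RSS}/n}{\bigl(1 - C(M)/n\bigr)^2},
\qquad C(M) = (\#\text{terms} + 1) + d \cdot \#\text{distinct knots},$$

the average squared residual inflated by a squared complexity penalty
that prevents many-term models from winning on marginal RSS gains. The
**GCV R²** is the ordinary R² with the error variance replaced by GCV,
so it can fall below the training R² (and below zero for over-penalized
fits); `cv_r2()` provides the 10-fold cross-validated alternative.

Selected models are reported in the **threshold basis**: `X.IFGT.c`
equals $x$ when $x > c$ and $c$ otherwise; `X.IFLT.c` equals $x$ when
$x < c$ and $c$ otherwise; `RACE.EQ.BLACK`-style indicators encode
categories, and `DRINK.GT.1.PER.WK`-style cumulative indicators encode
ordinal levels. Threshold and hinge bases span the same linear space —
$\max(0, x-c) = \mathrm{IFGT}(x,c) - c$ — so `hinge_to_threshold()` is
an exact reparametrization: fitted values, RSS and R² are unchanged,
only the intercept absorbs the constants. Coefficients then read
directly as slopes on intervals. At the boundary $x = c$ both forms
return $c$, which makes the identity
$\mathrm{IFGT}(x,c)+\mathrm{IFLT}(x,c) = x + c$ hold everywhere;
strictness matters only on a measure-zero set.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_basis` | 10/20/30/60 | forward-pass basis budget (grid values) |
| `entry_penalty` | 0 / 0.01 | charge per *new variable* a candidate brings in, on the fraction-of-variance scale, applied during the forward comparison |
| `min_span` | 3 | observations required between candidate knots (and to each boundary); prevents degenerate knots |
| `gcv_d` | 2 (3 for type 2) | per-knot complexity charge in $C(M)$ |
| `tolerance` (`select_preferred`) | 0.01 | GCV-R² band within which the fewest-variables model is preferred |
| `tol_small`, `tol_medium` (`choose_set_sizes`) | 0.02 / 0.005 | cut-point tolerances on the screening cv-R² sequence |

Three of these deserve comment, because the underlying conventions were
genuinely open design choices:

* **Entry penalty semantics.** A "penalty for adding new variables"
  could be read as a per-variable GCV charge or as a forward-pass entry
  cost. The entry-cost reading is implemented: a candidate's RSS gain
  (normalized by the total sum of squares) is reduced by
  `entry_penalty` for every variable it would newly introduce. This
  directly discourages variable-count growth during search, which is
  the stated purpose, and leaves GCV comparable across cells of the
  grid.
* **GCV complexity constant.** The per-knot charge $d$ uses the
  conventional values 3 for interaction-capable models and 2 for
  additive/linear ones; both are exposed in `fit_config()`.
* **Natural cut points.** The screening stage must turn a cv-R²
  sequence into "small" and "medium" set sizes. A deterministic,
  auditable rule is used: small = smallest set within 0.02 of the
  maximum, medium = smallest within 0.005 (at least as large as small).
  Both tolerances are arguments.

Other conventions: the preferred-model rule breaks ties by fewer
parameters, then lower model type, then deterministic record order;
reflected pairs are always *added* together in the forward pass but
either side may be dropped when numerically degenerate (knot at a data
boundary) and singletons may survive the backward pass — that is how
one-sided printed transformations such as `AST.IFGT.25` arise.

## Preparation rules and their fixed order

The preparation sequence is: BLLOQ substitution → split →
missing-response dropping → stratified median imputation → encoding.
Splitting *before* imputation is forced by the requirement that medians
be computed separately for smokers/nonsmokers and for
analysis/validation subsets; the remaining order is the natural one
(substitution must precede imputation so flagged values are not
imputed; encoding last so the missing category sees post-imputation
data).

* **BLLOQ rule.** Nine exposure biomarkers carry BLLOQ flags. A flagged,
  missing value is set to 0; a flagged, present value is left
  unchanged; unflagged missing values remain missing and are imputable.
  The rule is idempotent.
* **Imputation.** Continuous predictors only, by the median of
  non-missing values within each (smoking status × partition) stratum;
  responses are never imputed — cases with missing response are
  dropped and counted. An even-count stratum uses the mean of the two
  central values.
* **Encoding.** Nominal variables emit the *full* indicator set (one
  column per level) rather than reference coding, because the spline
  stage selects individual indicators exactly as the final models do;
  ordinal variables emit cumulative `GT` indicators; a missing category
  becomes its own level before encoding. Encoding is lossless
  (`decode_categorical()` inverts it).
* **Two parallel outputs.** The imputed, encoded table feeds screening
  and spline fitting; the unimputed table feeds the final refits, where
  incomplete cases are dropped and the dropped count reported.
* **Split stratification.** Whether the original 80/20 split was
  stratified by smoking status is unknown; unstratified uniform
  sampling is the default, with `stratify_by_status = TRUE` available.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, with
defaults chosen once to be clinically plausible:

* **Cohort**: 3585 smokers and 1077 nonsmokers (the source study's
  enrolment); `small_cohort_config()` scales to 800 subjects with the
  25 core predictors for fast end-to-end runs.
* **Joint distribution**: a Gaussian copula — latent multivariate
  normal mapped through per-variable marginal quantile functions
  (lognormal for exposure biomarkers and urine outputs, normal for most
  labs and demographics, categorical by thresholding). This preserves
  rank correlations and is simple to document. Latent correlations
  default to 0.5 within the nine BOE and 0.3 between BOE and the
  smoking-sensitive labs CRP and triglycerides — enough collinearity to
  exercise the screening stage without claiming fidelity to any real
  study.
* **Marginals**: BOE are stochastically larger in smokers by one to two
  orders of magnitude (e.g. serum cotinine median 150 vs 1 ng/mL), so
  nonsmoker values fall mostly below the quantification threshold. Lab
  marginals sit at textbook reference medians with right-skewed tails
  where clinically appropriate (AST, CRP, triglycerides), which also
  guarantees observations on both sides of every printed knot.
* **Responses**: each BOPH is computed from its published final model
  under threshold-basis semantics, plus Gaussian noise with variance
  $\sigma^2 = V(1-R^2)/R^2$ (where $V$ is the linear-predictor
  variance), so the *population* R² equals the reported value (0.29
  WBC, 0.41 EPI8, 0.29 DEH11, 0.39 HDL). A 100,000-subject check in the
  test suite verifies the calibration to ±0.01.
* **BLLOQ flags**: the quantification threshold of each BOE is its
  nonsmoker 60th percentile — arbitrary, but it yields mostly-censored
  nonsmokers as intended; flagged values lose their numeric value with
  probability 0.5, exercising both branches of the substitution rule.
* **Missingness**: completely at random at rate 0.02 ("present but
  rare"); no informative mechanism is modeled because none is reported.

What the generator does *not* emulate: real marginal shapes,
inter-site variation, questionnaire structure, informative missingness,
or interactions among predictors (the generating models are additive).
Passing tests therefore demonstrate that the pipeline recovers known
structure of this kind — not that it would recover every feature of
real cohort data.

## Numerical choices

* Knot candidates are observed values thinned to every `min_span`-th
  order statistic with a `min_span` margin to each boundary; with
  `min_span = 1` the search is fully exhaustive (used by the oracle
  tests).
* The forward-pass scan runs in compiled code: prefix sums over the
  sorted variable give every candidate's Gram entries in $O(nm)$ per
  (parent, variable), plus an $O(m^2)$ projection per knot against the
  current design. Candidates whose orthogonalized norm falls below
  $10^{-9}$ of their raw norm are treated as degenerate (the other side
  of the pair may still enter); a candidate pair with an
  ill-conditioned 2×2 system falls back to its better single side.
* Backward deletion and all refits solve normal equations at $m \le 61$;
  the final OLS inference uses a QR decomposition with classical
  covariance $\hat\sigma^2 (X^\top X)^{-1}$ and two-sided p values on
  $n - p - 1$ degrees of freedom (two-sided being the default of the
  statistical environment the coefficient tables originate from).
* `validate_model()`'s applied R² uses the validation-set mean in its
  denominator, so a non-transferable model is detectable by an applied
  R² at or below zero.
* Degenerate inputs: constant responses yield intercept-only models;
  zero-variance candidates are excluded; a flat screening cv-R²
  sequence collapses small/medium to size 1 with a warning; strata with
  no observed values fall back to the global median with a warning.
* Near-adjacent knots on one variable (as in printed clusters like
  `AST.IFGT.22/24/26`) are left unmerged; `check_knot_clusters()` warns
  when knots fall within `min_span` observations of each other.

## Problem sizes used in the test suite

The suite exercises the full default cohort (4662 subjects) for R² and
coefficient recovery, a 100,000-subject cohort for the noise-variance
calibration check, 20 seeded replicates for coefficient recovery, and
an 800-subject, 25-predictor cohort for the end-to-end 72-cell grid
run — sizes chosen so each property is tested at a scale where its
expected noise is well below the asserted tolerance.

## Interfaces

The package's functions are the interface: cohorts move as plain data
frames with a metadata sidecar (`write_cohort()`/`read_cohort()` for
CSV), models serialize through `coef_table()` and the JSON manifest of
`write_pipeline_report()`, and `run_boph_pipeline()` drives the whole
workflow; `scripts/acceptance.R` reproduces the headline statistics
from the repository root.

## Known limitations

* Interaction terms pass through reparametrization unconverted (no
  threshold form exists for products); none are needed for the
  generating models, which are additive.
* The screening forest and spline engine assume complete predictors;
  they are always fed the imputed table. Only the final refits handle
  missingness (by complete-case dropping).
* `grid_search()` records GCV R² per cell; fold-based `cv_r2()` is
  available but not run for all 72 cells by default, since model
  preference is based on GCV R² and parsimony.
* Coefficient recovery holds for the generating conditions
  (MCAR missingness, additive truth); systematic BLLOQ substitution
  biases would require a censoring-aware estimator, which is out of
  scope.
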