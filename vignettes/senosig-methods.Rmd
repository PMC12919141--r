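---
title: "Deriving and scoring cell-type senescence signatures: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring cell-type senescence signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senosig)
```

`senosig` turns a catalog of senescent-versus-proliferating
differential-expression results across primary human cell types into plasma
readouts of individual senescence burden, and evaluates those readouts
against clinical traits, lifespan dynamics, survival endpoints, and
age-prediction ("seno-age") models. This vignette documents the models, the
tunable parameters and their defaults, the synthetic-data generators that
the test suite measures recovery against, and the design choices made where
the design was genuinely open.

## The classification model

The atomic evidence unit is a differential record: one (protein, cell type,
induction method) triple carrying a log2 fold-change (senescent /
proliferating) and a BH-adjusted p-value. A protein *qualifies* in a cell
type when it is elevated (log2FC > 0, adjusted p < 0.05) in two induction
methods of that cell type. Two readings of "two inductions" are supported:

- `ir_plus_chemical` (default): ionizing radiation plus at least one
  chemical inducer (etoposide or doxorubicin). This is the stricter reading
  and treats radiation as the anchor stimulus.
- `any_two`: any two induction methods.

Protein status is then a partition: **SAP** if some cell type qualifies;
**non-SAP** if the protein is elevated in no record at all; **inconclusive**
otherwise (elevated somewhere, but never under two inductions of one cell
type). Cell-type-*exclusive* signatures subtract every other cell type's
signature; the *core* signature keeps proteins that are SAPs in at least
`k_core` cell types (9 of 14 in the full universe; 6 of 9 when neonatal and
fetal cell types are excluded via `adult_cell_types()`). Proteins absent
from a cell type's records are treated as not elevated there; they can never
block or grant exclusivity silently because classification warns about
universe proteins with no records.

The differential-abundance engine is deliberately simple and fully
documented: a per-protein Welch t-test on log2 intensities with BH
correction within each (cell type, induction) stratum. The classification
layer is agnostic to the engine — any precomputed record table with the same
columns is accepted — so a moderated-variance engine can be substituted
upstream without touching the rule.

## Burden scoring

For each trait, elastic-net regression (alpha = 0.5, an equal mix of lasso
and ridge) selects proteins from a candidate pool with the covariates (age,
sex, race) included *unpenalized*, so confounder adjustment happens inside
the selection model rather than by residualization. Features are
standardized internally and effects are reported per SD, making the
"top 25 by effect size" ordering scale-free. The penalty is chosen by
10-fold cross-validation at the **one-standard-error rule** (`lambda_rule =
"1se"`, with `"min"` available). The one-SE rule is the default because, in
measured null experiments (200 signal-free candidates, n = 500), the
CV-minimum penalty admits around five spurious proteins on average while
the one-SE fit returns an empty selection at no cost in recall of planted
signal — a selection procedure intended to define biomarker panels should
be empty when there is nothing to find.

Panels apply a polarity sign filter (positively associated proteins for
negative-health traits such as frailty; inversely associated proteins for
positive-health traits such as walking pace), keep at most 25 proteins by
|effect| with ties broken lexicographically, and are condensed into the
composite senescence burden: the per-participant mean of per-protein
z-scores, using sample SD (n − 1) computed on the scoring cohort. The score
is therefore invariant to affine rescaling of any panel protein. The
High-Impact Panel keeps proteins selected for at least half (ceiling) of a
stated trait list.

The single-panel protocol — selecting once on the whole cohort and then
cross-validating the resulting score — intentionally admits a degree of
leakage in exchange for a single, nameable panel; `nested_cross_validate()`
provides the leakage-free counterpart (selection, sign filtering, and score
scaling all inside the training fold), and the test suite checks the
expected ordering (single-panel R² at least nested R² on average).

## Association, mediation, importance

Trait models are ordinary least squares or maximum-likelihood logistic
regression with the formula `trait ~ predictor + covariates`; logistic fits
flag numerically perfect separation rather than silently reporting a huge
coefficient. Repeated cross-validation uses ten independent 90/10 splits
(disjoint-fold rotation available); for binary traits both a pseudo-R²
(squared correlation of predicted probability with outcome) and the
rank-sum AUC are reported, because an R² analogue for binary outcomes is
not unique. Degenerate binary test folds (a single outcome class) are
redrawn, with a cap of 100 retries.

Paired SAP-versus-non-SAP metric comparisons are gated by a Shapiro–Wilk
test on the iteration-matched differences: normal-looking differences
(p > 0.05) get a paired t-test; otherwise a Wilcoxon signed-rank test is
used and flagged. Identical vectors and zero-variance differences take an
explicit degenerate path.

Relative importance of two composite scores is the LMG decomposition
restricted to two focal regressors: each score's R² increment averaged over
both entry orders, covariates always in the base model. The two importances
sum exactly to the joint incremental R², and reduce to the marginal R²s
when the scores are orthogonal — an identity the tests verify to 1e-10.

Mediation uses the potential-outcomes plug-in estimator: a linear mediator
model and a linear or logistic outcome model; ACME and ADE are averaged
over both exposure arms. For linear outcomes the plug-in is exact and
equals the product of coefficients, so total = ACME + ADE holds to solver
tolerance; for binary outcomes, expectations on the probability scale are
obtained by integrating the mediator residual distribution with a fixed set
of standard-normal draws (default 100), making the estimator deterministic
given the seed. Confidence intervals are nonparametric percentile bootstrap
(default 1000 iterations; at least 100 required). Sensitivity analysis for
sequential ignorability is out of scope.

## Lifespan dynamics

To undo an uneven age distribution before scanning, the cohort is
downsampled to the same number of participants per decade of life within
50–90 (default 120 per decade, 480 total, 50% per sex), without
replacement, and a standardized-mean-difference report compares the
selection to the eligible pool. The sliding-window scan then compares, at
each 1-year center t from 60 to 80, the participants aged [t − 10, t)
against [t, t + 10) with a linear model per protein (upper-window indicator
plus covariates), BH-corrected **within each center across proteins** (the
natural family: each center is one question), counting proteins elevated
and depressed at q < 0.05. Windows are half-open with the boundary
participant assigned upward, so a participant at exactly the center age is
in the upper window and every participant within ±10 years belongs to
exactly one window. The peak is the center with the maximal elevated count;
ties resolve to the smallest center and are flagged. Skipped (empty-window)
centers are ignored by peak detection.

## Longitudinal models

Cox models use age — not follow-up time — as the time scale, with delayed
entry at the proteomics measurement age: a participant contributes to the
risk set only between entry and exit age. Models are stratified by sex and
race and use the Efron tie approximation (exact available). Monotone
likelihood (infinite estimates) is flagged. The Schoenfeld proportionality
test regresses scaled Schoenfeld residuals on event time with the identity
time transform (KM transform available). Quartile trajectories assign
participants to composite-score quartiles with deterministic tie-breaking
(score rank, then participant identifier) and report delayed-entry
Kaplan–Meier cumulative incidence, 1 − S(age), for the top and bottom
quartiles. Participants already past an onset endpoint at entry should be
excluded by the caller; competing risks and time-varying covariates are out
of scope.

## Seno-ages

Per signature, a seno-age model is unpenalized least squares of
chronological age on the signature's elastic-net-selected panel (selection
and estimation separated). The seno-age gap is the residual of the
regression of predicted age on chronological age — the "trend line" is an
ordinary least-squares line, chosen over a scatterplot smoother for
determinism, and refit in whatever cohort is being scored so gaps are
mean-zero within each study. Gaps are therefore mean-zero, uncorrelated
with age on the scoring cohort, and invariant to affine transformation of
the predictions. Gap–trait models exclude age from the covariates by
default (the gap is already age-decorrelated); a switch re-includes it.
Inter-signature correlations are emitted for both seno-ages and gaps,
since the two answer different questions (shared age trend versus shared
age-independent deviation).

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
tested; they emulate the statistical structure of the real inputs, not
their scale.

**Catalog.** Replicate log2 intensities are Gaussian on the log2 scale
(log-normal abundances), so the log2 fold-change is the difference of arm
means. Planted members — disjoint exclusive sets per cell type plus core
proteins shared by at least `k_core` cell types — carry a mean effect of
1.5 log2FC with replicate SD 0.5 and 4 replicates per arm by default; the
replicate count is a free design choice since typical catalogs do not fix
it. Note the power implication measured by the acceptance suite: with
n = 4 per arm the standard error of a log2FC is 0.35, and the
two-induction qualification squares the per-induction BH-level power, so
member-level recovery at q < 0.05 is low at these settings; at 6–8
replicates per arm recovery becomes near-complete. The end-to-end demo
configuration therefore uses 8 replicates per arm so the derived signature
sets are well populated, while the generator default records the leaner
design.

**Cohort.** Ages are uniform in 22–96; each participant carries a
biological-age offset delta ~ Normal(0, 5 years). Planted SAPs split into a
"smooth" set, drifting with biological age at 0.05 SD-units per year and
loading on a burden factor, and a change-point set carrying a step of 0.6
SD-units at the change-point age (default 70; optionally sex-specific, e.g.
72 for females and 78 for males). Per-protein slopes and loadings are drawn
uniformly around the configured means: heterogeneity is what makes the age
factor and the burden factor separately identifiable from a protein panel —
with identical loadings the planted SAPs collapse to a single latent factor
and no age model can separate biological age from burden. The step is
locked to chronological age because the sliding-window scan compares
calendar-age windows; a biological-age-locked step would be smeared by the
offset SD and the change-point would not be localizable to ±1 year. The
change-point is a step rather than a slope kink: the adjacent-window mean
contrast of a kink grows monotonically up to one window-width past the
change-point, so a kink's elevated-count curve peaks at the wrong age by
construction; a step's contrast is maximal exactly at the change-point.
The mediation path plants mediator = a·sex + noise with a = 0.5, and a
logistic outcome with b = 0.8 per SD of burden and direct effect c' = 0.4;
onset and death ages come from a Weibull proportional-hazards model (shape
5, median 85 at zero burden, planted log-HR 0.5 per SD) drawn conditional
on survival past the entry age, so delayed entry is built into the
sampling. Administrative censoring is at age 100.

**Tissue atlas.** Categorical expression levels with a planted enrichment
of medium/high calls (+0.35 over a 0.30 baseline) for signature proteins in
their matched section.

What passing tests show — and what they do not: the generators produce
independent Gaussian noise, a single latent burden factor, and no batch,
platform, or cross-reactivity structure. Recovery of planted truth
demonstrates the estimators are implemented correctly and calibrated under
their assumed models; it does not demonstrate robustness to aptamer
cross-reactivity, normalization artifacts, or confounding present in real
plasma proteomics.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the planted effects are comfortably identifiable:
catalogs of 400 proteins × 14 cell types × 2 inductions, cohorts of
600–2400 participants, 10-seed recovery loops, bootstrap sizes of 150–500
(mediation coverage is checked at 200 bootstrap iterations over 100
datasets), and 200-replicate null calibrations. Ties in panel ranking break
lexicographically; zero-variance proteins are excluded from composite
scores with a warning (all-constant panels are an error); degenerate
differential rows (zero variance in both arms) get p = 1 when the means are
equal and p = 0 otherwise; empty scan windows skip their center with a
warning. Every stochastic step is seeded, and pipeline sub-stage seeds are
derived deterministically from the master seed, so a pipeline rerun is
byte-identical.

## Known limitations

The differential engine is an unmoderated t-test, which is conservative at
small replicate counts relative to empirical-Bayes engines. The elastic-net
protocol implements a single selection per trait, not stability selection.
Mediation assumes sequential ignorability and reports no sensitivity
analysis. The survival layer has no competing risks. Seno-age trend removal
is linear; a smoother can change gap values in cohorts with strongly
nonlinear age trends.
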