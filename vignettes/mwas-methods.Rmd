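---
title: "Methods: medication-wide association screening of pregnancy outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-wide association screening of pregnancy outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwascreen)
```

## Overview

`mwascreen` screens every prescribed medication against a set of binary
delivery outcomes — cesarean section, preterm birth, stillbirth — in
EHR-style event tables. The package covers the full path from raw event
tables to adjusted odds ratios: ICD code-set phenotyping, exposure-window
construction with brand/generic merging, a comorbidity adjustment matrix
from diagnosis history, per-medication logistic regression with Wald
inference and Bonferroni family-wise control, and privacy-aware reporting.
A synthetic obstetric-EHR generator provides the test bed, since real
obstetric EHR data cannot be shared.

This vignette documents the statistical model, the tunable parameters and
their defaults, the generator's design, the numerical choices, and what the
package's validation does and does not establish.

## The screening model

For medication $j$ and outcome $k$, over deliveries $i$:

$$\operatorname{logit} P(Y_{ik}=1) = \beta_0 + \beta_1 X_{ij} +
\beta_2\,\mathrm{age}_i + \boldsymbol{\gamma}^\top \mathbf{C}_i$$

* $X_{ij}$ — binary pregnancy exposure: at least one order of medication
  $j$ dated in $[\text{delivery}-280, \text{delivery}-1]$ days, bounds
  inclusive. The endpoints encode a full-term gestation (280 days) and the
  exclusion of delivery-day orders, which typically treat the delivery
  itself. Inclusivity at both ends was chosen so that "280 days before"
  and "1 day before" are both in-window; whole-day arithmetic is used
  throughout.
* $\mathbf{C}_i$ — sixteen binary comorbidity flags (infectious disease,
  obesity, cancer, cardiovascular, circulatory, cerebrovascular,
  respiratory, immune disorders, organ transplant, obstetric history,
  maternal care, preeclampsia, multiple birth, drug allergies, procedures,
  drug resistance), each set by at least one matching diagnosis in the
  two-year pre-delivery lookback $[\text{delivery}-730,
  \text{delivery}-1]$. Delivery-day diagnoses are excluded because they
  usually describe the delivery, not a pre-existing condition. "Two
  years" is implemented as 730 days for determinism across leap years.
  The covariate set is config-driven: published cohort tables in this area
  sometimes tabulate 17 comorbidity rows while describing 16 adjustment
  covariates, so the default follows the described set and users can load
  their own.
* $\mathrm{age}$ — maternal age in whole years (floored) at delivery,
  entered untransformed as a continuous main effect.

Each medication is assessed separately; deliveries from the same patient
are treated as independent observations, matching the analysis this
package operationalizes. Outcome flags are ascertained from delivery-day
diagnosis codes (a configurable window is available, default 0 days),
because delivery billing codes are issued on the delivery encounter.

Inference per test is Wald: $\mathrm{OR} = e^{\hat\beta_1}$, 95% interval
$e^{\hat\beta_1 \pm 1.959964\,\mathrm{SE}}$, two-sided p-value from the
normal approximation. The interval type is a design choice; the Wald form
is the standard output of logistic screens. Family-wise control is the
Bonferroni correction $p_{\text{bonf}} = \min(1, m\,p)$ with
$m = |\text{medications}| \times |\text{outcomes}|$ by default; the family
choice is a reporting convention, so $m$ is configurable and echoed in
every output header. A result is marked `*` when the nominal $p \le
\alpha$ and `**` when the Bonferroni-adjusted $p$ also passes, with
$\alpha = 0.05$.

### ICD code sets

Codes are normalized (uppercase, periods stripped) and matched
exact-first, then by prefix. Prefix semantics are the safe general
contract for ICD vocabularies, where child codes refine parents; users can
disable prefixes per set. The coding system (ICD-9 vs ICD-10) is inferred
from the leading character — digits imply ICD-9, letters other than the
ambiguous E/V imply ICD-10 — and is informational only; it never affects
matching. The bundled vocabulary is an illustrative toy: real analyses
must load clinically validated code lists with `read_codesets()`.

### Candidate-drug rule engine

`apply_exclusions()` reduces an annotated candidate list (e.g. drugs in
repurposing trials) with first-match-wins rules, in order: no FDA
approval; approval after the cutoff year (default 2017, i.e. after the
cohort window closes); not a pharmaceutical or biological product; sole
approved indication HIV (no HIV-status proxy is available for
adjustment); no reproductive-age female trial participants. The registry
query and manual annotation that produce the candidate table are outside
the package's scope; the bundled 20-record candidate table is a synthetic
toy fixture.

## The synthetic generator

`simulate_cohort()` draws from a generative model that mirrors the
analysis model, per delivery:

1. covariates $C \sim \mathrm{Bernoulli}(\text{prevalence})$;
2. maternal age $\sim N(\mu, \sigma)$ truncated to $[12, 55]$ years;
3. each exposure $\sim \mathrm{Bernoulli}(\operatorname{logit}^{-1}(
   \operatorname{logit}(\text{base}) + \mathbf{C}^\top
   \boldsymbol{\delta}_j))$ — the $\boldsymbol{\delta}$ matrix creates
   confounding;
4. each outcome $\sim \mathrm{Bernoulli}(\operatorname{logit}^{-1}(
   \operatorname{logit}(\text{base}) + \beta_{\text{age}}(\text{age}-\mu)
   + \mathbf{C}^\top\boldsymbol{\gamma}_k + \sum_j \theta_{jk} X_j))$,
   with $\theta$ the planted log odds ratios echoed back as `truth`;
5. events: 1–3 orders per exposed medication uniformly inside the
   exposure window, with a brand or generic raw name; one diagnosis per
   covariate flag dated uniformly in the lookback (a configurable
   fraction can be dated 731–1095 days back to exercise lookback
   truncation; the default is 0 so the generative covariates equal the
   recoverable ones); outcome diagnoses coded with the toy vocabulary on
   the delivery date.

The defaults are the package's reference study conditions: outcome
prevalences 32.99% / 6.15% / 0.81%, the sixteen comorbidity prevalences of
`default_covariate_prevalence()` (two suppressed cells default to
5/63,334 and are flagged as guesses), maternal age 29.48 ± 6.08 years,
ten candidate medications at 0.45% baseline exposure each (≈ 4.4%
any-candidate exposure), and a moderate clinically-oriented confounding
structure (preeclampsia → anticoagulants and all outcomes; infection →
antibiotics and preterm birth; obesity → famotidine, cesarean and
stillbirth; multiple birth → cesarean and preterm). Deliveries per patient
follow a 78/19/3 split over 1/2/3 with ≥300-day spacing, giving ≈1.25
deliveries per patient; a patient-level random intercept is available
(default off, matching the independence assumption of the screen).

Determinism: the master seed fully determines the output, with per-stage
sub-seeds so the patient, date, covariate, exposure, outcome and event
draws are separately reproducible.

**Exact-margins fixture mode** assigns outcome and covariate flags to
exactly `round(prevalence × n)` deliveries, one delivery per patient, with
integer ages whose mean reproduces the configured mean at two decimals.
It exists to reproduce printed cohort margins exactly in tests and makes
no generative claim (no effect terms are applied, ages are not
truncated).

What the generator does **not** emulate: visit-level utilization,
inpatient/outpatient structure, dose/route/duration, adherence (orders,
not ingestion), coding noise and miscoded dates, informative missingness,
and patient-level dependence beyond the optional random intercept.
Passing tests therefore demonstrate that the machinery is correct under
its own assumptions — unbiasedness, calibration, confounding removal —
not that the assumptions hold in any particular health system's data.

One realistic artifact is retained: when a patient has several
deliveries, a diagnosis emitted for one delivery may fall inside a later
delivery's lookback, so recovered covariate flags can be a superset of the
latent ones. Validation experiments that need exact generative/recovered
correspondence use single-delivery configurations.

## Numerical choices

* Fits use iteratively reweighted least squares (`stats::glm.fit`,
  binomial family) with deviance tolerance `1e-10` and up to 60
  iterations; standard errors come from the inverse Fisher information of
  the final IRLS QR factorization.
* Inside `run_screen()`, deliveries sharing an identical
  (outcome, exposure, covariate) pattern are collapsed into weighted rows
  before fitting. For a 0/1 response this is an exact reformulation —
  coefficients, standard errors, log-likelihood and AIC are unchanged (a
  test asserts agreement with the unaggregated fit to 1e-9) — and each
  fit is warm-started from the per-outcome baseline model, which changes
  the iteration path but not the maximum.
* Separation and non-convergence are flag-and-null: a non-converged fit
  or $|\hat\beta_1| > 10$ nulls the estimate and sets
  `separation_flag`/`converged` rather than reporting a diverging MLE.
  Penalized (Firth-type) likelihood was deliberately not substituted, to
  keep the core estimator the plain MLE the screen describes.
* Degenerate inputs (constant outcome or exposure) raise structured
  conditions; `run_screen()` converts them to flagged result rows and
  continues, so one degenerate pair never aborts a screen.
* Percentages round half-up to two decimals, matching the formatting
  convention of published cohort tables; ties like 0.125 round away from
  zero.
* Same-day duplicate deliveries for a patient collapse to one event with
  a warning (a twin birth is one delivery with a multiple-birth
  covariate).

## Validation experiments and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R`) runs:

1. **Summary arithmetic** — percentage recomputation from the reference
   cohort's printed counts, and an exact-margins fixture of 63,334
   deliveries run through the full pipeline.
2. **Oracle equivalence** — 1,000 random 2×2 tables (cells 5–500): the
   covariate-free logistic OR must match the closed-form cross-product
   ratio $ad/bc$ to ≤ 1e-6 relative error.
3. **Type-I calibration** — 200 replicate null screens (all planted ORs
   1, confounding on) of 10 medications × 3 outcomes at n = 20,000
   deliveries: pooled per-test rejection within [0.035, 0.065] and
   Bonferroni FWER ≤ 0.05 plus Monte-Carlo slack. The calibration
   configuration uses 2% baseline exposure per medication (≈18%
   any-exposure, in line with overall prescription exposure in obstetric
   cohorts rather than candidate-only exposure) so that each test —
   including the 0.81%-prevalence stillbirth outcome — carries enough
   exposed cases for the Wald approximation under test to be in its
   regime; at candidate-level exposure the expected number of exposed
   stillbirths would be below one and the experiment would measure sparse-
   data conservatism rather than calibration. Screens with so few exposed
   cases that the MLE separates report no p-value, and such tests are
   excluded from the denominator (you cannot reject with a nulled
   estimate). Even so, stillbirth tests remain somewhat conservative —
   a real property of Wald screens at rare outcomes that practitioners
   should expect.
4. **Parameter recovery** — planted OR 2.0 at 5% exposure and 30% outcome
   prevalence, n = 50,000, 30 replicates: ≥ 25/30 intervals must cover
   2.0 and mean log-OR bias must be < 0.05.
5. **Confounding removal** — strong planted covariate → exposure and
   covariate → outcome effects (log 3 each, confounder prevalence 25%)
   with true OR 1 at n = 100,000: the adjusted estimate must be closer to
   the null than the unadjusted one and its interval must cover 1.
6. **Rule and window exactness** — boundary offsets (0, 1, 280, 281,
   729, 730, 731 days) against the stated inequalities; byte-stable
   exclusion partitions.
7. **Privacy** — 100 fuzzed configurations: no rendered user-facing table
   may contain an unmasked count below 10.

These sizes were chosen so the whole suite runs in minutes on one CPU
while keeping Monte-Carlo error well inside each acceptance band.

## Known limitations

* Exposure is prescription, not ingestion; no dose, duration or route.
* Outcome ascertainment is delivery-day code matching; the bundled code
  lists are illustrative toys.
* The screen replicates the independence assumption across deliveries of
  the same patient; a patient-clustered robust-variance option is a
  natural extension and is not provided in the core.
* Trimester-specific exposure windows are out of scope; the single
  280-to-1-day window is the only exposure definition.
* Bonferroni control is conservative by construction; with correlated
  tests the realized FWER is well below the nominal level.
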