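# mwascreen

Medication-wide association screening (MWAS) of pregnancy outcomes from
EHR-style event tables.

## The problem

Pregnant patients are systematically excluded from clinical trials, so when
existing drugs are repurposed for a new indication there is usually no
evidence about their safety in pregnancy. Retrospective electronic health
record (EHR) data can fill part of that gap: for every medication actually
prescribed during pregnancies in a health system, one can ask whether
exposed deliveries had higher odds of adverse outcomes — a medication-wide
association study, the pharmacoepidemiologic analogue of GWAS/PheWAS.
`mwascreen` implements that screen as a reusable, tested pipeline for three
delivery outcomes: **cesarean section**, **preterm birth**, and
**stillbirth**.

Because real obstetric EHR data cannot be shared, the package ships a
configurable synthetic obstetric-EHR generator whose generative model
mirrors the analysis model (known prevalences, covariate-driven
confounding, planted medication effects), so every stage of the pipeline is
testable end to end.

## The model

For each retained medication *j* and outcome *k*, the screen fits an
adjusted logistic regression over deliveries *i*:

```
logit P(Y_ik = 1) = β0 + β1 X_ij + β2 age_i + γᵀ C_i
```

where `X_ij ∈ {0,1}` indicates **pregnancy exposure** — at least one order
of medication *j* (brand and generic equivalents merged) dated between 280
and 1 days before delivery, both bounds inclusive — and `C_i` are 16 binary
comorbidity covariates ascertained from ICD-9/ICD-10 diagnoses within a
2-year pre-delivery lookback that excludes the delivery day. The report per
test is `OR = exp(β1)` with the 95% Wald interval
`exp(β1 ± 1.959964·SE)`, a two-sided Wald p-value, and the Bonferroni-
adjusted p-value `min(1, m·p)` with `m` = medications × outcomes.
Medications prescribed to fewer than 10 distinct patients in the exposure
window are dropped before screening, and every user-facing table masks
counts below 10.

## Worked example

```r
library(mwascreen)

cfg <- default_sim_config(n_patients = 10000, seed = 1)
cfg$planted_log_or["heparin", "preterm"] <- log(2)   # plant a true effect
co <- simulate_cohort(cfg)

vocab <- default_vocabulary()
cohort <- build_cohort(co$deliveries, co$diagnoses, vocab, co$patients)
expo <- apply_min_patient_filter(
  build_exposures(co$orders, cohort, default_drug_map()), 10)
covs <- build_covariates(cohort, co$diagnoses, vocab, co$patients)

spec <- screen_spec(c("cesarean", "preterm", "stillbirth"),
                    colnames(expo$matrix),
                    setdiff(colnames(covs), "maternal_age"))
res <- run_screen(spec, expo, covs, cohort)
subset(res, medication == "heparin",
       select = c(outcome, n_exposed, or_estimate, ci_low, ci_high,
                  p_nominal, p_bonferroni, sig_bonferroni))
```

prints (seed 1):

```
      outcome n_exposed or_estimate    ci_low   ci_high  p_nominal p_bonferroni sig_bonferroni
19   cesarean        56   0.8272493 0.4697819  1.456721 0.51123725    1.0000000              0
20    preterm        56   2.3003284 1.1151293  4.745199 0.02413784    0.7241353              0
21 stillbirth        56   1.7910591 0.2447107 13.108918 0.56605545    1.0000000              0
```

The planted preterm effect (true OR 2) is recovered with a confidence
interval covering 2; at 56 exposed deliveries it is nominally significant
(p = 0.024) but does not survive the Bonferroni correction across the
screen's tests — the expected behavior of a conservative family-wise
screen at this sample size. The stillbirth interval is wide because only
~0.8% of deliveries are stillbirths.

The same pipeline runs from delimited files via a YAML config with
`run_pipeline()`, or from the thin CLI in `inst/cli/mwascreen.R`
(`simulate`, `filter-trials`, `run-all`), writing a cohort summary table,
an association table with `*`/`**` significance markers, forest-plot
exports, and a JSON run manifest.

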