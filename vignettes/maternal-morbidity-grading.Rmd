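---
title: "Grading maternal morbidity from routine birth registries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading maternal morbidity from routine birth registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matgrade)
```

## The problem and the model

Maternal deaths have become rare enough in many settings that mortality
alone is a poor surveillance signal. The WHO framing instead treats
pregnancy complications as a *continuum of severity*: a woman may pass from
a less severe morbidity through a potentially life-threatening condition to
a near miss (she almost died but survived) or to death. `matgrade`
operationalises that continuum for registries that were never designed to
record the full WHO clinical/laboratory/management criteria: each severity
level is defined by a list of *pragmatic criteria* — diagnoses and events a
routine registry does record — and each woman receives the most severe level
whose criteria she meets.

Formally, a record is graded by fixed precedence
`MD > MNM > PLTC > LSMM > NONE`. `MD` is defined by vital status alone
(death at the facility or during transport/referral). The other levels are
rule sets over tri-state condition flags (`present` / `absent` / missing):
a set is met when any single rule holds or when all members of a *combined*
rule group hold jointly. Two consequences follow by construction and are
enforced by tests: the five classes partition any cohort, and adding a
higher-severity condition to a record can never lower its class.

Missingness is treated as *criterion-not-met* everywhere: a registry can
only act on recorded diagnoses. The analysis assumes missingness is
randomly distributed (not associated with predictors or outcomes); under
that assumption complete-case tables and models are unbiased, and the
per-variable missing fractions are always reported alongside.

## Default criteria and their ambiguities

The default MNM list is: blood transfusion *together with* haemorrhage (any
trimester or postpartum); eclampsia or magnesium sulfate use; cardiac
disease; renal disease; hospital stay > 7 days. The default PLTC list
contains the haemorrhagic/hypertensive/infectious complications plus *any*
blood transfusion; the LSMM list the remaining recordable morbidities
(anaemia, HIV+, diabetes, antenatal admission, ovular infection, urinary
tract infection, other condition, retained placenta, referral).

Two genuinely open design points are resolved as follows:

* **Transfusion vs. haemorrhage.** Transfusion appears both as an MNM
  marker and, as "any blood transfusion", in the PLTC list. If transfusion
  alone were MNM, the PLTC transfusion rule could never fire (precedence
  would always grab the record first). The default therefore requires
  transfusion AND haemorrhage *jointly* for MNM; either alone grades as
  PLTC. `default_criteria(mnm_transfusion_joint = FALSE)` selects the other
  reading, and the YAML config makes any variant expressible.
* **Prolonged stay.** `hospital_stay_days` measures the *total* facility
  stay for the childbirth admission (nothing in the source registries
  separates antepartum days), and the 7-day threshold is an editable rule
  parameter, not a constant.

History-only conditions (previous diabetes, hypertension, preeclampsia,
eclampsia, cardiac/renal disease) are separate `prev_*` fields and never
enter the severity criteria: a registry cannot reliably distinguish a
historical flag from an index-pregnancy event, so we do not guess.

## Indicator panel

With `n` women, `LB` live births and class counts `N_c`: percentages are
`100 N_c / n` (denominator: all women), `MMR = 10^5 MD / LB`, and the
morbidity ratios are `10^3 N_c / LB` (denominator: live births — the
convention that makes the panel internally consistent, e.g.
`SMOR = MNMR + MMR/100` exactly on unrounded values). All values are kept
unrounded; display rounding is 1 decimal for ratios, 2 decimals for the MD
percentage, 1 for the others, and the morbidity-to-death ratio
`(AMM - MD)/MD` rounds to an integer. `LB <= n` is *not* enforced (a
registry with multiple births can violate it); a warning is emitted
instead.

## Cluster-corrected chi-square

Registry data arrive clustered by country/site; each cluster is a primary
sampling unit (PSU). Ignoring that clustering makes the Pearson chi-square
anticonservative whenever the compared factor varies between PSUs. The
correction implemented is the first-order Rao–Scott adjustment: for each
cell of the two-way table, the design effect is the ratio of the
with-replacement PSU variance of the cell proportion to its simple-random-
sampling variance; the Pearson statistic is divided by the unweighted mean
of the cell design effects and referred to the same degrees of freedom.
Choices worth stating:

* With one cluster the design effect is 1 by definition and the procedure
  reduces *exactly* to the uncorrected Pearson test (verified against the
  closed-form statistic).
* Cells with proportion 0 or 1 carry no variance information and are
  excluded from the average.
* The estimated design effect is not floored at 1, so the corrected
  statistic may exceed the uncorrected one when clusters are more
  homogeneous than random sampling. With moderately many PSUs the division
  by a noisy design-effect estimate leaves the test close to, but not
  exactly at, the nominal 5% level under an i.i.d. null — the test suite
  checks calibration by Monte-Carlo (2,000 replicates, 20 clusters of 50).
* No second-order (Satterthwaite) correction and no survey weights: the
  registry is unweighted, and the first-order correction is the standard
  reading of "corrected for the cluster design effect".
* Significance is reported at 0.05 with no multiple-testing adjustment,
  matching surveillance practice for descriptive tables.

## Prevalence ratios

The association analyses compare each outcome class against the
no-morbidity group only (records of other classes are excluded from that
model). Crude PRs are risk ratios from the 2x2 counts with the Katz
log-normal interval. For adjusted PRs the deliberate choice is to estimate
PRs *directly* rather than report logistic odds ratios (which overstate
PRs at these outcome prevalences): a log-link binomial GLM of class
membership on all covariates simultaneously, falling back to a log-link
Poisson ("modified Poisson") when the log-binomial fails to converge or
hits the boundary. Fitting is deterministic: convergence tolerance 1e-8,
at most 100 IRLS iterations, starting values at the marginal log-rate.

Variance is cluster-robust: a PSU-grouped sandwich covariance
(`sandwich::vcovCL`), with t critical values on K - 1 degrees of freedom
(K = number of PSUs) — the standard small-cluster practice, and the reason
interval coverage holds with as few as 12 clusters. With fewer than 2
clusters an unclustered robust (HC0) covariance is used with a warning; for
the modified-Poisson path a robust covariance is required in any case.
Reference categories are fixed to the conventional ones (age 20–24, white,
secondary+ schooling, married/stable, multipara, > 4 visits, no risk
exposure, spontaneous onset, vaginal delivery). Complete-case restriction
is per model for the adjusted PRs and per covariate for the crude ones,
consistent with reporting per-variable missingness.

A saturated one-covariate model reproduces the crude 2x2 ratio to 1e-6,
which the tests use as an oracle-equivalence check between the two routes.

## What the synthetic registry emulates — and what it does not

`generate_cohort()` is first-class, tested code, not a fixture. Its
defaults *are* the study conditions: 12 clusters; severity mixture
MD 0.14%, MNM 3.1%, PLTC 15.5%, LSMM 19.3%, none 62%; a neonatal
near-miss gradient of 4.9/6.4/5.2/14.5/13.1% for none/LSMM/PLTC/MNM/MD;
class-conditional stillbirth rates around 2–5%; and per-field MCAR
missingness from 0.4% (age) to 31.1% (the smoking/drugs/alcohol/violence
composite), with the previous-condition block masked jointly so the derived
any-previous flag stays consistent with its components. Covariate
prevalences default to realistic registry margins (e.g. 38% nulliparae,
~22% white / 73% mixed / 5% other ethnicity).

Class assignment is a covariate-tilted multinomial: each morbidity class
probability is the mixture value times `exp(beta)` for every configured
covariate effect (log-PR scale), optionally times a log-normal per-cluster
factor (`cluster_sd`); the no-morbidity probability is the remainder, and a
configuration whose tilts push any probability outside [0, 1] is rejected
before generation. Records then receive condition flags that realise their
class under the default criteria — one criterion drawn at random within the
class's list (deaths also carry a severe condition, and non-MNM records
keep stays <= 7 days so no lower class can accidentally satisfy a higher
rule). Criterion flags are never masked, so the classifier recovers the
intended class for 100% of records — the property every downstream
parameter-recovery test relies on. A `mask_criteria` switch lifts that
guarantee for robustness experiments.

What it does **not** emulate: real between-country heterogeneity (the
magnitude is a free parameter, defaulting to homogeneous), MAR/MNAR
missingness, multiple gestation, correlated comorbidity profiles (each
record realises one criterion, not a clinically coherent bundle), or
longitudinal linkage across pregnancies. Passing tests therefore show the
*methods* are correct under known generative conditions; they do not show
that any particular real registry satisfies those conditions.

## Simulation sizes and numerical tolerances

The test-suite simulations are sized to be decisive yet quick: mixture
recovery at n = 100,000 against 3-standard-error binomial bands; adjusted-
PR parameter recovery at n = 50,000 with 12 clusters and a ±10% band
(a clean designed simulation: exposure prevalence 30%, no masking, true
log-PRs log 2.0 and log 1.3); null CI coverage over 500 replicates of
n = 3,000 against a 93% floor; chi-square calibration over 2,000 replicates.
Oracle equivalences (crude-vs-model, single-cluster Pearson) are asserted
at 1e-6 or exactly. The brute-force classifier oracle used in the property
tests is an independent per-record, per-rule evaluator that shares no code
with the vectorised implementation.

## Known limitations

* The severity grades are proxies; without the full WHO organ-dysfunction
  criteria, MNM identification leans on transfusion/haemorrhage, eclampsia,
  cardiac/renal disease and prolonged stay, and will misgrade conditions a
  registry does not record.
* Complete-case analysis is only defensible under the random-missingness
  assumption stated above; the package reports missingness but does not
  impute.
* Adjusted PRs from different model families (log-binomial vs. logistic)
  are not interchangeable; published adjusted estimates obtained with
  unspecified software defaults should be treated as comparison points, not
  as exact reproduction targets.
* The first-order design-effect correction addresses the mean variance
  inflation only; with few PSUs and very unequal cluster sizes a
  second-order correction would be more accurate.
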