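# matgrade

Surveillance of maternal health increasingly relies on the full *continuum of
maternal morbidity* rather than on maternal deaths alone: for every woman who
dies of a pregnancy-related cause, hundreds survive complications ranging from
mild to nearly fatal. `matgrade` turns a routine perinatal registry (one row
per woman/delivery, with condition flags recorded during the childbirth
admission) into that surveillance picture. It is aimed at epidemiologists and
public-health analysts working with multi-country or multi-facility birth
registries where the clustered, incomplete, rule-identifiable nature of the
data has to be handled explicitly.

## What it computes

**Severity grading.** Each record is assigned exactly one class by a
configurable rule engine with fixed precedence

> MD (maternal death) > MNM (maternal near miss) > PLTC (potentially
> life-threatening condition) > LSMM (less severe maternal morbidity) > none,

so a woman is graded by the most severe criterion she meets. The default
criteria are pragmatic, registry-recordable proxies (e.g. MNM: transfusion
together with haemorrhage, eclampsia or MgSO4 use, cardiac or renal disease,
hospital stay > 7 days), shipped as an editable YAML config so a registry
that records richer clinical/laboratory criteria can extend them. Derived
unions: SMO = MD + MNM, AMM = all morbidity classes. A neonatal near-miss
composite (birthweight < 1750 g, or 5-min Apgar < 7, or gestational age
< 33 weeks) is computed alongside. Unrecorded diagnoses never satisfy a
criterion; missingness is a first-class tri-state flag value.

**Indicator panel.** With `LB` live births, `n` women and class counts
`N_c`: percentages are `100 * N_c / n`; `MMR = 100000 * MD / LB`; and
`MNMR, SMOR, PLTCR, LSMMR, AMMR = 1000 * N_c / LB`; plus the
morbidity-to-death ratio `(AMM - MD) / MD` — survivors with any morbidity
per maternal death.

**Cluster-corrected tables.** Severity-stratified cross-tabulations with
per-variable missingness and a chi-square test corrected for the cluster
design effect (first-order Rao–Scott: the Pearson statistic divided by the
mean cell design effect estimated from between-PSU variance).

**Prevalence ratios.** Crude PRs from 2x2 counts with the Katz log-normal
interval; adjusted PRs from a log-link binomial model (modified Poisson
fallback) of each outcome class versus the no-morbidity group, with
PSU-clustered sandwich confidence intervals.

**Synthetic registry.** `generate_cohort()` draws registry-like cohorts with
a known severity mixture, covariate-dependent class probabilities, cluster
heterogeneity, a neonatal-outcome gradient and MCAR missingness — with the
generative truth attached, so classification fidelity, parameter recovery
and interval coverage are all testable without confidential data.

## Worked example

Feeding the class counts of a large Latin American/Caribbean birth registry
(712,081 childbirths, 12 countries) into the panel:

```r
library(matgrade)
indicator_panel(counts = c(MD = 1028, MNM = 21985, PLTC = 110038,
                           LSMM = 137589, NONE = 441441),
                n_live_births = 697820)
#> Maternal morbidity indicator panel
#>   Women: 712,081   Live births: 697,820
#>   MD         1,028   0.14%   MMR = 147.3/100,000 LB
#>   MNM       21,985    3.1%   MNMR = 31.5/1000 LB
#>   SMO       23,013    3.2%   SMOR = 33.0/1000 LB
#>   PLTC     110,038   15.5%   PLTCR = 157.7/1000 LB
#>   LSMM     137,589   19.3%   LSMMR = 197.2/1000 LB
#>   AMM      270,640   38.0%   AMMR = 387.8/1000 LB
#>   NONE     441,441   62.0%
#>   Survivors with any morbidity per maternal death: 262
```

A maternal mortality ratio near 150 per 100,000 live births with 38% of
women experiencing some morbidity — 262 survivors with morbidity per death —
is the kind of profile that motivates grading morbidity instead of counting
deaths. A crude prevalence ratio from stratified counts (maternal death by
any previous pathological condition):

```r
crude_pr(90, 14493, 897, 398396)
#> PR 2.75 (95% CI 2.21-3.41)
```

End to end on a synthetic registry:

```r
coh <- generate_cohort(sim_config(n = 10000, seed = 7))
run_pipeline(coh, "out/")   # classified.csv, panel.json, tables.json,
                            # prevalence_ratios.json, manifest.json
```

A thin command-line front-end over the same functions lives in
`exec/matgrade` (subcommands `validate`, `classify`, `indicators`, `tables`,
`associate`, `simulate`, `run`).

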