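# jointmsm

Marginal structural Cox models (Cox-MSM) for **two concurrent time-varying
treatments with an interaction**, estimated by stabilized
inverse-probability-of-treatment weighting (IPTW), together with the
simulation machinery needed to study when they beat the standard
time-dependent Cox model.

## Who this is for

Biostatisticians and epidemiologists studying the joint causal effect of
two treatments given in combination (e.g. two antiretroviral classes and
the risk of an adverse event) when a time-dependent confounder — a
CD4-like disease marker that predicts treatment initiation, predicts the
outcome, and responds to past treatment — makes conventional covariate
adjustment biased.

## The model

With monthly visits `m`, monotone treatment indicators `A1(m)`, `A2(m)`
(once started, never stopped) and baseline covariate `V = L(0)`, the
marginal structural hazard for the counterfactual time under treatment
history `ā` is

    λ_{T_ā}(t | V) = λ0(t) · exp(β1·a1(t) + β2·a2(t) + β3·a1(t)·a2(t) + β4·V)

`exp(β1)`, `exp(β2)` are the causal rate ratios of each treatment alone,
`exp(β3)` the extra multiplicative effect of the combination. Fitting uses
stabilized weights

    SW_i(m) = SW_i^{A1}(m) · SW_i^{A2}(m) · SW_i^{C}(m)

where each treatment factor is a cumulative product over visits of
numerator (history + baseline only) over denominator (history + current
confounder) probabilities of the observed treatment value from pooled
logistic models, and the censoring factor is 1 under purely administrative
censoring. The weighted Cox partial likelihood (Breslow ties) with a
cluster-robust sandwich variance gives estimates and 95% Wald intervals.

The package covers the full loop: a data generator whose marginal
structural hazard is *exactly* the model above (counterfactual-budget
construction with a remaining-survival-anchored confounder), weight
estimation and truncation, weighted/unweighted fits, confounding
diagnostics, and a replication harness computing bias, SD, RMSE and
coverage over a 15-scenario grid (3 confounding strengths × 5 true-effect
sets). See the vignette `vignettes/cox-msm-simulation.Rmd` for the design
rationale.

## Worked example

```r
library(jointmsm)

cfg   <- scenario_config("1B", n_subjects = 1000, seed = 7)  # strong confounding, true beta = (0.5, 0.5, 0.5)
panel <- simulate_dataset(cfg)
panel
#> <long_panel> 11186 person-months, 1000 subjects, 160 events (1.43%/month)

w <- estimate_weights(panel)
mean(w$sw)
#> [1] 0.9997                      # stabilized weights center near 1

fit_weighted_cox(panel, w)
#> <msm_fit> weighted (MSM) Cox model with interaction; covariates: L0; ties: breslow
#> 1000 subjects, 11186 person-months, 160 events
#>          coef     HR robust_se lower95 upper95
#> a1     0.4552 1.5765    0.3245 -0.1809  1.0913
#> a2     0.0423 1.0432    0.3336 -0.6115  0.6960
#> L0    -0.0003 0.9997    0.0005 -0.0012  0.0007
#> a1.a2  0.8144 2.2578    0.4365 -0.0411  1.6699

fit_unweighted_td_cox(panel)
#>          coef     HR robust_se lower95 upper95
#> a1     1.1129 3.0432    0.3121  0.5013  1.7245
#> a2     0.9313 2.5377    0.3253  0.2937  1.5688
#> ...
```

One replicate is noisy, but the pattern is already the headline result:
the weighted estimates scatter around the generating values
`(0.5, 0.5, 0.5)`, while the unweighted time-dependent Cox — which adjusts
for the confounder directly — lands near `(1.1, 0.9, 1.5)`, far above the
truth, because the current confounder is affected by past treatment.
Averaging over replicates makes this precise:

```r
run <- run_replicates(cfg, n_reps = 200)   # ~70 s; weighted w/ and w/o interaction + unweighted
run$variants$weighted_interaction$metrics      # |bias| ~ 0.05, coverage ~ 95%
run$variants$unweighted_interaction$metrics    # |bias| ~ 0.6-0.9
grid_report(list("1B" = run))                  # tidy table, one row per variant x parameter
```

A command-line pipeline wraps the same stages:

```sh
Rscript inst/cli/jointmsm.R simulate   --scenario 1B --n-subjects 1000 --seed 7 --out-dir out
Rscript inst/cli/jointmsm.R weights    --panel out/panel.csv --out-dir out
Rscript inst/cli/jointmsm.R fit        --panel out/panel_weighted.csv --variant weighted_interaction --out-dir out
Rscript inst/cli/jointmsm.R replicates --scenario 1B --n-reps 50 --seed 7 --out-dir out
```

Exit codes: 0 success, 2 validation error, 3 estimation failure. Panels
are flat CSVs with header `id,start,stop,event,a1,a2,L,L0` (months as the
time unit); every stage writes its fully resolved configuration next to
its outputs.

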