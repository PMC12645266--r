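# effortpain

Simulation and hierarchical Bayesian modelling of a pain-avoidance
prosocial effort task.

## The problem this package addresses

In the task this package models, a participant repeatedly chooses between a
**rest offer** — six electric shocks for no effort — and a **work offer** —
fewer shocks (1–5) in exchange for squeezing a hand dynamometer at 40–80%
of their maximum voluntary contraction. Half the trials decide the
participant's own shocks ("self"), half another person's ("other"). Two
phenomena of interest are *prosocial apathy* (initiating less effort for
others) and *prosocial superficiality* (exerting less force for others);
establishing their **absence** requires effort-discounting choice models
and quantified null evidence, not just non-significant p-values.

The package is for computational researchers who want a tested, end-to-end,
self-contained pipeline for this task family: no external MCMC toolchain,
no download of the original data.

## The models at its core

Offers are valued in shock units (`Shock` coded −5…−1, `Effort` 1…5, rest
offer fixed at −6):

    linear      SV = Shock + κ·Effort
    parabolic   SV = Shock + κ·Effort²
    hyperbolic  SV = Shock · 1/(1 + κ·Effort)

with discount rate κ ≤ 0 and a softmax choice rule
`P(work) = 1/(1 + exp(−β·(SV_work − SV_rest)))`, β > 0. Self/other
parameters use effect coding, `κ_OTHER = κ_SELF + κ_EFFECT`. Crossing three
shapes with shared/separate κ and β gives 12 candidate models, fitted
hierarchically (Normal(0,1) group-location priors, 4 NUTS chains × 1000
warmup + 1000 draws, convergence at R̂ < 1.01), compared by PSIS-LOO
(`LOOIC = −2·elpd_loo`, lower is better) with per-subject best-model
attribution, and validated by posterior predictive checks and parameter
recovery. Behavioural null effects are quantified with default-prior Bayes
factors (JZS paired t-test, Cauchy scale 0.707; correlation BF with a
uniform prior on ρ), reported as BF01 (3–10 moderate, >10 strong null
evidence).

See `vignettes/effortpain-methods.Rmd` for assumptions, parameter defaults
and numerical choices.

## Worked example

```r
library(effortpain)

schedule <- generate_schedule(n_per_recipient = 75, seed = 1)
cfg      <- population_config(n_subjects = 20)   # the documented world
agents   <- sample_population(cfg, seed = 2)
data     <- simulate_dataset(agents, schedule, cfg, seed = 3)

summarize_behavior(data)
#>  recipient          measure  mean      sd
#>       self work_choice_rate 0.635 0.16287
#>       self        mean_rt_s 1.236 0.02299
#>       self   mean_force_auc 0.484 0.00853
#>       self     success_rate 0.924 0.03823
#>      other work_choice_rate 0.642 0.18410
#>      other        mean_rt_s 1.226 0.03316
#>      other   mean_force_auc 0.479 0.00973
#>      other     success_rate 0.926 0.04698

fit <- fit_model(data, model_spec("parabolic_2k1b"),
                 sampler = sampler_config(4, 1000, 1000, seed = 4))
fit
#> <ep_fit> parabolic_2k1b
#>   subjects: 20, trials: 2981, draws: 4000 (4 chains x 1000)
#>   max R-hat: 1.0040 (converged, < 1.01)
#>   post-warmup divergences: 0
#>   group |kappa_self| = 0.220, |kappa_other| = 0.227, beta = 2.29
```

The work-choice rate (~64%) and the group |κ| values are the cohort the
generator was configured to produce; 2981 trials are the 3000 simulated
minus the injected non-responses. Is effort discounted differently for the
other person? The κ difference and the behavioural Bayes factor both say
no for this cohort:

```r
hdi <- compute_hdi(fit$group_draws$kappa_effect, 0.95)
#> group kappa_other - kappa_self: mean -0.007, 95% HDI [-0.022, 0.008]

per <- summarize_behavior(data)$per_subject
s <- per[per$recipient == "self", ];  s <- s[order(s$subject_id), ]
o <- per[per$recipient == "other", ]; o <- o[order(o$subject_id), ]
jzs_paired_bf(s$work_choice_rate, o$work_choice_rate)
#> work-rate self vs other: t(19) = -0.36, BF01 = 4.06 (moderate null)
```

(HDI covering 0 → no credible self/other discounting difference; BF01 ≈ 4
→ moderate evidence *for* the null.) Model comparison against the
shared-κ alternative:

```r
fit1k <- fit_model(data, model_spec("parabolic_1k1b"),
                   sampler = sampler_config(4, 1000, 1000, seed = 5))
compare_models(list(fit, fit1k))
#>            model  looic     se delta_looic se_diff_vs_best
#> 1 parabolic_2k1b 1528.8 55.194       0.000              NA
#> 2 parabolic_1k1b 1584.6 55.120      55.802          15.417
#> best-model shares:
#> parabolic_2k1b parabolic_1k1b
#>           0.45           0.55
```

The two-κ model predicts better at the group level (ΔLOOIC ≈ 56, ~3.6 SE),
while per subject the simpler model wins narrow ties for the many agents
whose κ_EFFECT is near zero — exactly the pattern the attribution is
designed to expose.

Validation (`parameter_recovery()`), posterior predictive checks
(`posterior_predictive()`), and the full orchestrated pipeline
(`run_pipeline()` / the `effortpain` CLI in `inst/cli/`) are documented in
the function reference and the vignette.

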