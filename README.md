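# mecmr

Multi-event capture–mark–recapture (CMR) models of age- and
quality-dependent breeding probability in long-lived iteroparous animals,
with the demographic machinery that turns the fitted rates into
life-history traits. The package is aimed at population ecologists working
with annual coded encounter histories of known-age females — the motivating
system is a multi-decade captive sea-turtle breeding colony — who want to
ask how age and fixed individual heterogeneity shape the decision to breed,
and what that implies for survival, iteroparity and future reproductive
potential.

## What it implements

**The multi-event hidden Markov model.** Eight biological states (juvenile,
subadult, non-breeder and breeder split by a two-class latent *quality*,
freshly dead, dead) emit six coded events (0 = unseen, 1 = J, 2 = SA,
3 = NB, 4 = B, 5 = recovered dead). One annual step is governed by
row-stochastic survival, transition and event matrices; the history
likelihood is a forward-algorithm sum over latent paths, conditioned on
first capture as a juvenile at age 0. Recruitment ties the five entry cells
to one probability ψR, so the juvenile transition row is
(1−3ψR, ψR, 0, 0, ψR, ψR, 0, 0). The parameters of interest are the
age-logistic *arrival* ψB (non-breeder breeds next year) and *departure*
ψNB (breeder skips) per quality class, and age-logistic adult survival φ.
Fitting is multi-start quasi-Newton ML (`fit_mecmr()`), with Wald
covariance, an identifiability diagnostic (`check_identifiability()`), and
quasi-likelihood model selection: QSIC = D/ĉ + K·ln N with a conservative
ΔQSIC > 7 decision rule, plus QAICc (`qsic()`, `qaicc()`, `model_table()`).

**Goodness of fit and overdispersion** (`test_3sr()`, `test_3sm()`,
`test_wbwa()`, `c_hat()`): transience, time-to-re-encounter and
"where-before-where-after" memory components from per-occasion contingency
tables, and ĉ = Σχ²/Σdf (floored at 1) to deflate deviances.

**Derived demography** (`isrp()`, `prob_future_reproduction()`,
`expected_future_events()`, `delta_method()`,
`survival_transition_curve()`): the inter-seasonal reproductive period
ISRP = 1 + ψNB/ψB, the probability of a subsequent reproductive event
P = (1−ψNB)φ + ψNB·ψB·φ²/(1−(1−ψB)φ), geometric expectations, and
survival-versus-transition age curves, all with delta-method uncertainty.

**Leslie-matrix life-history traits** (`build_leslie()`, `growth_rates()`,
`r0_and_generation_time()`, `life_expectancies()`, `gini_index()`,
`reproductive_value()`, `pace_shape()`): A = U + F with maternity
mx = (eggs/2)/ISRP, verified irreducible/ergodic, satisfying the discrete
Euler–Lotka identity Σ λ⁻ˣ lx mx = 1 to machine precision; λ, R0,
generation time, life expectancies, the Gini index of iteroparity,
reproductive value, and pace/shape of aging and fecundity.

**Inter-arrival models** (`build_interval_table()`, `fit_cox()`,
`ph_check()`, `fit_ztp()`): waiting times between breeding seasons,
cluster-robust Cox proportional hazards with Schoenfeld-residual
diagnostics, and a zero-truncated Poisson regression whose predicted
intervals are ≥ 1 year by construction.

**A synthetic cohort generator** (`default_config()`, `simulate_cohort()`,
`simulate_breeding_output()`) whose defaults encode the study conditions
(recruitment 0.02 at age 7 rising to 0.19 at 16; adult survival averaging
0.91 and declining with age; arrival 0.78→0.66 and 0.33→0.19 by quality;
a 2002–2003 hurricane detection block; up to 10 clutches of ~110 eggs), so
every stage has a known-truth recovery surface. `run_pipeline()` chains all
stages with per-stage artifacts and a reproducible manifest.

## Worked example

```r
library(mecmr)
cfg <- default_config(n_individuals = 400, seed = 42)
sim <- simulate_cohort(cfg)
summarize_set(sim$histories)
#> $n_individuals   [1] 400
#> $recaptures_mean [1] 23.0525
#> $recaptures_sd   [1] 7.03979
#> $n_dead_recoveries [1] 148
```

Four hundred females followed from birth, each re-encountered about 23
times. The memory component of the goodness-of-fit test is large — the
latent quality mixture makes the future depend on more than the current
observable state — which is exactly what the overdispersion coefficient is
for:

```r
gof <- gof_tests(sim$histories)
gof[["WBWA"]]
#> WBWA: chi2 = 128.844, df = 69, p = 1.69e-05 (69 tables)
c_hat(gof[c("3.SR", "3.SM", "WBWA")])$c_hat
#> [1] 1.823569
```

Refit the generating design and read off the age curves:

```r
fit <- fit_mecmr(generating_design(cfg), sim$histories,
                 n_starts = 1, start = theta_from_config(cfg))
subset(survival_transition_curve(fit, c(17, 34)), parameter == "arrival")
#>    age quality parameter  estimate         se     lower     upper
#> 3   17     low   arrival 0.3714651 0.01794611 0.3362914 0.4066389
#> 4   34     low   arrival 0.1905005 0.02706778 0.1374486 0.2435523
#> 9   17    high   arrival 0.7741599 0.02620347 0.7228021 0.8255178
#> 10  34    high   arrival 0.6657013 0.05639151 0.5551760 0.7762267
```

High-quality females return to breed far more readily (0.77 at age 17,
0.67 at 34) than low-quality ones (0.37 falling to 0.19) — estimates that
recover the generating values. A high-quality female at age 25 waits about
1.3 years between breeding seasons:

```r
arr <- plogis(coef(fit)["psiB.hi.b0"] + 25 * coef(fit)["psiB.hi.b1"])
dep <- plogis(coef(fit)["psiNB.hi.b0"] + 25 * coef(fit)["psiNB.hi.b1"])
isrp(dep, arr)
#> ISRP = 1.3056
```

Life-history traits from the fitted survival schedule and the simulated
egg records:

```r
breeding <- simulate_breeding_output(sim$truth, cfg,
                                     histories = sim$histories, seed = 43)
sched <- pipeline_schedules(sim, breeding, fit)
L <- build_leslie(sched$phi_by_age, sched$eggs_by_age, sched$isrp, afr = sched$afr)
leslie_traits(L)[c("lambda", "R0", "T_gen", "gini", "shape_surv", "shape_rep")]
#> lambda 2.19   R0 2075   T_gen 9.74   gini 0.42
#> shape_surv 0.11   shape_rep 0.021
```

A growing, protected population (λ ≈ 2.2) with ~2000 female eggs per female
lifetime, moderate iteroparity (Gini 0.42), mild actuarial senescence
(shape_surv > 0) and essentially age-constant reproduction. Finally, the
waiting-time models show the antagonistic age/experience pattern — older
females wait longer, experienced females wait less:

```r
itab <- build_interval_table(breeding, sim$histories)
fit_cox(itab, c("age_at_start", "experience"))
#> Cox proportional hazards fit: 2636 intervals, 2318 events, Nagelkerke R2 = 0.014
#>      covariate estimate robust_se     hr hr_lower hr_upper percent_change        p
#> 1 age_at_start -0.02987  0.003848 0.9706   0.9633   0.9779         -2.943 8.33e-15
#> 2   experience  0.05044  0.005935 1.0517   1.0396   1.0640          5.174 1.91e-17
```

See `vignettes/mecmr-methods.Rmd` for the model, its assumptions, the
design decisions and the numerical choices.

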