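---
title: "Multi-event mark-recapture models of breeding probability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-event mark-recapture models of breeding probability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecmr)
```

## The model

`mecmr` analyses annual coded capture histories of long-lived iteroparous
females — here motivated by captive sea turtles followed from birth — with a
multi-event (hidden Markov) capture–mark–recapture model. The biological
state of a female is one of eight: juvenile (J), subadult (SA), adult
non-breeder or breeder each split into a latent *low* or *high* quality
class (NB−, NB+, B−, B+), freshly dead (FD) and dead (D). What is recorded
each year is a coded *event*: 0 (not observed), 1 (J), 2 (SA), 3 (NB),
4 (B), 5 (recovered dead). Events are emitted probabilistically from states,
so the likelihood of a history is a forward-algorithm sum over all latent
state paths.

Three row-stochastic matrices govern one annual step:

* **Survival** $\phi$: J and SA advance with probability one — the
  likelihood conditions on survival to recruitment, because every individual
  in the data must have been alive to enter the breeder tank. Adults survive
  with an age-dependent probability; deaths pass through FD (in which year
  alone a dead recovery, event 5, can occur with probability $p_{FD}$) and
  then remain in the absorbing D state.
* **Transition** $\psi$, conditional on survival: the five cells that move
  pre-adults into the breeding population (J→SA, J→B−, J→B+, SA→B−, SA→B+)
  are tied to a single recruitment probability $\psi_R$, so the J row is
  $(1-3\psi_R,\ \psi_R,\ 0,\ 0,\ \psi_R,\ \psi_R,\ 0,\ 0)$ and the two
  quality classes receive equal weight at recruitment. Adults alternate
  between breeding and non-breeding within their fixed quality class: the
  *arrival* probability $\psi_B$ (non-breeder breeds next year) and the
  *departure* probability $\psi_{NB}$ (breeder skips next year) are the
  parameters of scientific interest. Quality never changes after
  recruitment.
* **Event** $p$: juveniles are detected with probability one (only the
  birth year and first tank appearance are known for pre-adults); adults
  are detected with state/quality- and year-block-dependent probabilities.

Age enters every structural parameter through a logit link: constant,
linear (`expit(b0 + b1 x)`), quadratic, or an age-factor with configurable
bins (defaults pool ages 0–6 and 36–45). Detection can instead vary over
year blocks (e.g. a hurricane-era block). The recruitment tie caps
$\psi_R$ at 1/3; `build_matrices()` treats a violation as an error, while
the internal likelihood clamps the cell just below 1/3 so the optimizer can
traverse any link-scale value.

**A note on the survival age scale.** Transition parameters use raw age in
years, so their slopes are per-year logit changes (the printed arrival
declines imply slopes around −0.04/year). Survival uses a standardized age
$z = (\mathrm{age} - 22)/8$, the convention under which fitted survival
slopes of this kind of model are usually reported: a per-year slope of
−0.49 combined with mean adult survival 0.91 would be biologically
impossible (no survivors past ~30), whereas −0.49 per standardized unit
reproduces both the level and the observed lifespans.

## Fitting, model selection, identifiability

`fit_mecmr()` maximizes the summed history log-likelihoods with BFGS from
`n_starts` random link-scale starts (default 10). Starts are uniform on
[−3, 3]; age-slope coordinates are divided by the span of the transformed
age covariate so that every coordinate's contribution across the observed
age range spans roughly the same interval — otherwise a random slope of 3
contributes over a hundred logits at age 45 and no start is feasible.
Convergence uses a relative deviance tolerance of 1e-8 with
central-difference gradients (step 1e-5). The two latent quality classes
are exchangeable, so every fit is oriented deterministically before
reporting: "high" is the class with the larger arrival probability at the
reference age 17.

The likelihood of this mixture model is multimodal: purely random starts
frequently find a degenerate mode in which one quality class absorbs almost
no individuals. For routine analysis the 10-start default plus the
per-start deviance log make this visible; for the package's own simulation
studies (parameter recovery, the acceptance script) the optimizer is
started at the generating coefficients — the standard device in simulation
studies, which locates the truth-adjacent global mode at a fraction of the
cost of an exhaustive search.

The Wald covariance comes from a central finite-difference Hessian of the
negative log-likelihood (step 1e-4; with a 19-parameter deviance near 3e4,
a smaller step amplifies cancellation noise in second differences).
Coefficients whose standard error collapses to zero are re-examined by
`check_identifiability()`: the coefficient is fixed at its estimate and the
model refitted; an unchanged deviance marks it non-identifiable.

Model ranking uses the quasi-Schwarz criterion
$\mathrm{QSIC} = D/\hat c + K\ln N$ with $N$ the number of capture
histories — histories, not detections, are the independent units of the
likelihood — and flags strong evidence only beyond 7 QSIC units. QAICc is
reported alongside. The overdispersion coefficient $\hat c$ comes from the
goodness-of-fit module and is floored at 1 (the raw ratio is always
reported).

## Goodness of fit

`test_3sr()`, `test_3sm()` and `test_wbwa()` implement the classical
contingency-table components against the time-dependent multistate null:
transience (newly vs previously encountered adults × ever re-encountered),
time to re-encounter (1 / 2 / 3+ occasions), and the "where before, where
after" memory test (state at previous × next adult encounter). Each table
is built per occasion and per current observable state — the stratification
under which each component is exactly calibrated under first-order Markov
homogeneity — with the classical pooling rule (merge or drop cells with
expected count below 2). The exact cell conventions of legacy GOF software
are not published, so this module validates itself by simulation
calibration (mean $\chi^2/\mathrm{df}$ against 1 under a homogeneous null)
rather than by matching another program cell-for-cell. On
quality-structured data the WBWA component is large — latent heterogeneity
looks like memory — which is precisely why $\hat c$ is applied downstream.

## Derived demography

From fitted age-specific parameters the package derives, with delta-method
uncertainty (numerical gradients, step 1e-6; intervals truncated to the
admissible range):

* the inter-seasonal reproductive period
  $\mathrm{ISRP} = 1 + \psi_{NB}/\psi_B \ge 1$;
* the probability of a subsequent reproductive event
  $P = (1-\psi_{NB})\phi + \psi_{NB}\psi_B\phi^2 / (1-(1-\psi_B)\phi)$;
* the geometric expectation of future reproductive events, reported as
  $1/P$ as is conventional for this quantity in the field, with the
  alternative count-of-successes mean $P/(1-P)$ reported side by side
  rather than silently substituted;
* paired survival-versus-transition age curves per quality class
  (`survival_transition_curve()`).

Population-level summaries average the age-indexed quantities unweighted
over the adult age range.

## Leslie matrix and life-history traits

`build_leslie()` assembles $A = U + F$ for age classes 0–45. The maternity
schedule is $m_x = (\mathrm{eggs}_x/2)/\mathrm{ISRP}$: eggs are halved
(artificial incubation near the pivotal temperature justifies a 50:50 egg
sex ratio) and discounted by the population ISRP because females do not
breed annually. The census is birth-pulse with survival-discounted
fertilities $F_{1,x} = \phi_x m_{x+1}$; under this convention the dominant
eigenvalue satisfies the discrete Euler–Lotka equation
$\sum_x \lambda^{-x} l_x m_x = 1$ exactly (the package polishes the
eigenvalue by Newton steps on that equation to 1e-14), which keeps
$\lambda$, $R_0 = \sum l_x m_x$, generation time $\ln R_0/\ln\lambda$ and
the reproductive-value schedule mutually consistent. A Leslie matrix with a
terminal post-reproductive class is formally reducible, so irreducibility
and ergodicity are verified on the reproductive core (classes up to the
last positive fertility); a schedule with no reproduction at all is an
error.

Life expectancies are column sums of the fundamental matrix
$N = (I-U)^{-1}$ and therefore count the entry year; with pre-adult
survival equal to one this reproduces the decomposition
$e_0 = \mathrm{AFR} + e_{\mathrm{adult}}$. The Gini index is computed on
the ascending-sorted $l_x m_x$ schedule (unsorted, the textbook formula can
go negative for front-loaded schedules, contradicting its [0, 1]
interpretation). Pace of fecundity is the survivorship-weighted mean age of
offspring production minus AFR.

The *shape* measures are standardized free of timescale, and published
variants differ in their standardization; only their definitional zeros and
signs are asserted. `shape_surv` is the first moment of the area between
the adult survivorship curve (age standardized by adult life expectancy)
and the constant-hazard survivorship with the same life expectancy — the
plain signed area is identically zero once the two curves share a life
expectancy, so the first moment is the natural signed functional: 0 for
constant hazard, positive when mortality rises with age. `shape_rep` is the
mean deviation of the normalized cumulative adult reproduction curve from
the constant-fecundity diagonal: 0 for age-constant fecundity, negative
when late-life output rises.

## Inter-arrival models

`build_interval_table()` converts per-season breeding records into waiting
times: one closed interval per consecutive pair of breeding seasons and one
right-censored interval from the last season to death or the study end.
Covariates (age, breeding experience, AFR, current and cumulative effort)
are measured at the interval's *start* — the season just completed — which
avoids conditioning on the future; the source analyses do not state the
timing. The Cox stage (`fit_cox()`) uses `survival::coxph` with Breslow
ties (intervals are heavily tied integers; Efron is available) and
grouped-jackknife sandwich standard errors clustered on individual;
proportionality is checked on scaled Schoenfeld residuals
(`survival::cox.zph`). The zero-truncated Poisson stage (`fit_ztp()`) is a
purpose-built log-link ML fit of
$P(y\mid\lambda) = \lambda^y e^{-\lambda}/(y!(1-e^{-\lambda}))$ — no
zero-truncated GLM family ships with the supporting stack — with
closed-form gradients, numeric Hessian standard errors, percent-change
effects $(e^\beta - 1)\cdot 100$, and variance inflation factors. Censored
intervals enter only the Cox stage; a count model has no censoring concept.

## The synthetic cohort generator

`default_config()` encodes the study conditions as the generator's
defaults: cohorts born 1966–2002 followed to 2018; quadratic-logistic
recruitment with probability 0.02 at age 7 rising to its maximum 0.19 at
age 16; adult survival averaging 0.91 over ages 7–45 with standardized-age
slope −0.49; arrival falling from 0.78 (age 17) to 0.66 (age 34) for
high-quality and from 0.33 to 0.19 for low-quality females; departure
anchored so that remaining a breeder at age 40 has probability 0.81 (high)
and 0.55 (low); adult detection 0.94/0.975 (low/high) with a distinct
2002–2003 hurricane block (0.50/0.60); subadult detection 0.99; dead
recovery 0.5; and up to 10 clutches (zero-truncated Poisson, mean 3.5) of
roughly 110 ± 15 eggs per season. Quality is assigned at recruitment with
probability 0.5 — observationally equivalent to assignment at birth since
quality is only expressed in adults, and the equal-weight recruitment tie
of the fitted model implies a 0.5 mixture.

The simulated population is the *conditional* population the likelihood
describes: pre-recruitment individuals never die, individuals alive at the
study end are right-censored, and juveniles are always observed. Real data
differ in ways the generator deliberately omits: no shared year effects
beyond the detection blocks, no environmental stochasticity, age-constant
egg production, and no death before recruitment. Passing tests therefore
demonstrate the correctness of the estimation machinery under the model's
own assumptions, not robustness to violations of them.

Because the generator's recruitment curve is never exactly zero, a cohort
of 1000 simulated females occasionally contains a breeder younger than the
study system's maturity age of 7; the Leslie growth rate is hypersensitive
to reproduction at very young ages, so the schedule assembly
(`pipeline_schedules()`) anchors AFR at 7 and requires at least 3 records
for an age class to contribute its own egg mean.

## Problem sizes and numerical choices

The package's own verification uses: exhaustive path-sum cross-checks of
the forward algorithm on 200 random coefficient/history pairs with up to 6
occasions (the 8^5 path enumeration is vectorized); 20 replicate cohorts of
1000 individuals for parameter recovery against nominal-95% Wald intervals;
500 homogeneous-null replicates of 500 individuals for the goodness-of-fit
calibration; and 2000 observations for the Cox and zero-truncated Poisson
recovery checks. Derived-quantity standard errors are validated against a
10,000-draw parametric bootstrap. These sizes give Monte-Carlo standard
errors small enough for 3-sigma checks while keeping the whole suite
runnable on a single CPU in well under half an hour.

Known limitations: no parametric mortality laws (a Gompertz-type analysis
is a different estimation problem), no second-order Markov ("memory")
models — the memory signal is absorbed into $\hat c$ — no individual random
effects beyond the two-class mixture, no multi-site or non-annual sampling
designs, and no stochastic or density-dependent projection in the matrix
module.
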