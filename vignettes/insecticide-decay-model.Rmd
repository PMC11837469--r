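---
title: "Modelling insecticide decay and polygenic resistance selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling insecticide decay and polygenic resistance selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmsim)
```

## The model

`irmsim` treats resistance to each insecticide as a classically polygenic
quantitative trait, the polygenic resistance score (PRS). Only the
population mean of each trait evolves; the phenotypic distribution around
it is normal with a fixed standard deviation. This is the central
simplification: selection changes means via the Breeder's equation, and
neither the variance, allele frequencies, nor population size are tracked.

A generation proceeds as follows.

1. **Measurement scale.** The mean PRS $\bar z$ maps to bioassay survival
   through a Hill function $k(\bar z) = \bar z^n / (\bar z^n + K^n)$ with
   half-saturation $K = 900$ and coefficient $n = 1$, chosen because this
   pair reproduces the conventional calibration points (score 0, 47, 100,
   225, 900, 3600 giving 0, 5, 10, 20, 50, 80% survival) exactly or to the
   printed rounding. Bioassay survival converts to field survival of
   exposed mosquitoes as $p = 1 - \omega\,(1 - (\varphi_1 k + \varphi_2))$
   with regression constants $\varphi_1 = 0.48$, $\varphi_2 = 0.15$,
   clamped to $[0,1]$. At $\omega = 1$ this is the plain bioassay-to-field
   regression; at $\omega = 0$ nothing is killed; $\omega > 1$ represents
   above-recommended doses and can drive survival of susceptibles to zero.
2. **Truncation selection.** A fraction $x$ of each sex contacts the
   deployment (males at $m x$). Exactly the top-$p$ of the exposed trait
   distribution survives, so exposed survivors carry a mean excess
   $\sigma\, i(p)$ where $i(p) = \phi(\Phi^{-1}(1-p))/p$ is the mean of
   the standard normal's upper-$p$ tail. The selection differential
   dilutes this excess by the unexposed fraction:
   $S = x p \sigma i(p) / ((1-x) + x p)$. For a mixture the exposed must
   survive both components, so the weight $p$ becomes $p_i p_j$ while the
   per-trait excess stays $\sigma i(p_i)$ — an effective partner shrinks
   trait-$i$ selection (mutual protection), and at $x = 1$ the partner
   becomes irrelevant because there is no unexposed pool to dilute.
3. **Response.** Sex-specific differentials (minus any fitness-cost
   differentials) are averaged and scaled:
   $R = h^2 \cdot \frac{S_f + S_m}{2} \cdot \beta$. Cross-resistance adds
   the Falconer correlated response
   $\alpha \sqrt{h^2_I h^2_J}\, \bar S_{partner}\, \beta$, using equal
   phenotypic standard deviations for the two traits. Sex-averaging
   happens before the correlated term; both use the cost-adjusted
   differentials.
4. **Control.** The degree of control, $x(1 - p)$ with the joint $p$ for
   mixtures, is the fraction of adult females killed that generation. It
   is a single-generation diagnostic only: without population dynamics,
   multi-generation control cannot be interpreted, so strategy outcomes
   never use it.

## Parameters, units and defaults

| Parameter | Symbol | Default | Units / meaning |
|---|---|---|---|
| Half-saturation score | $K$ | 900 | PRS at 50% bioassay survival |
| Hill coefficient | $n$ | 1 | mapping steepness |
| Field regression | $\varphi_1, \varphi_2$ | 0.48, 0.15 | slope, intercept (proportions) |
| Phenotypic SD | $\sigma$ | 20 | PRS units, fixed across generations |
| Heritability | $h^2$ | 0.2 | proportion of variance that is genetic |
| Cross-resistance | $\alpha$ | 0 (±0.3 in sweeps) | genetic correlation |
| Exposure scaling | $\beta$ | 1 | timescale calibration multiplier |
| Female exposure | $x$ | 0.7 | proportion contacting insecticide |
| Male ratio | $m$ | 1 | male exposure $= m x$ |
| Coverage | $C$ | 0.7 | proportion in the treated site |
| Dispersal | $\theta$ | 0.2 | per-generation mixing proportion |
| Fitness costs | $S^\phi$ | 0 | PRS units per sex and trait |
| Deployed efficacy | $\omega_0$ | 1 (0.75, 0.5 for reduced-dose mixtures) | kills all susceptibles at 1 |
| Base decay rate | $\delta_b$ | 0.015 (0.005–0.025 swept) | efficacy per generation |
| Threshold generation | $\tau_b$ | 15 | end of slow-decay stage (~1.5 y) |
| Rapid decay rate | $\delta_r$ | 0.08 | efficacy per generation |
| Withdrawal / return threshold | — | 10% / 8% | bioassay survival |
| Deployment frequency | — | 30 generations | ~3 y between net rounds |
| Horizon | — | 500 generations | 50 y at 10 generations/year |

Decay is **linear** in efficacy per generation (the rates are stated in
efficacy units per generation, which is a linear, not proportional, rate);
no exponential mode is offered. The two-stage profile applies the base
rate through generation $\tau_b$ inclusive and the rapid rate strictly
after, floored at zero; `constant` and `none` modes are available. A
reduced-dose mixture is represented by lowering $\omega_0$ with unchanged
rates. Redeployment resets the decay clock regardless of history.

## The multi-generation simulator

Two demes: the treated site (weight $C$) and untreated refugia. Per
generation: deployment decisions, scheduled redeployment (every 30
generations), efficacy lookup, insecticide selection in the site,
cost-only selection in the refugia, dispersal (each deme moves a fraction
$\theta$ toward the coverage-weighted pooled mean — this conserves the
global mean of each trait exactly), then threshold monitoring. The
sequence arm withdraws a deployed insecticide the generation its monitored
survival reaches 10%, deploying the next available one the following
generation (withdrawn insecticides return below 8%); it terminates when
nothing is deployable. The mixture arm terminates outright when either
component reaches 10%, with no fallback to the surviving component.
Censored runs enter lifespan differences at the 50-year cap.

Where the procedure was genuinely open, the package's conventions are:

* thresholds are monitored on the **treated-deme** mean (decisions are
  made where deployment happens); a `monitor = "global"` option exists;
* withdrawal is checked every generation, with replacement effective the
  next generation, rather than only at scheduled deployment points;
* the sequence deploys insecticide *i* first, including when *i* carries
  pre-existing resistance (scenario 2);
* population bioassay survival is evaluated **at the mean PRS** rather
  than integrated over the trait distribution, matching how score–survival
  pairs are conventionally tabulated; the difference is a smoothing of the
  mapping and does not change orderings.

These conventions shift absolute lifespans by a few generations and can
strengthen or weaken the mixture's advantage; sign-level conclusions in
the test suite are robust to them, but users comparing against other
implementations should check them first.

## Numerical choices

* Field survival is clamped up to a floor of $10^{-10}$ before the
  selection intensity is computed; $i(p)$ grows like the normal quantile,
  so the floored differential at $x < 1$ is numerically zero rather than
  overflowing. The floor is configurable.
* Full exposure over a fully lethal deployment ($x = 1$, joint $p = 0$)
  kills the entire cohort: the differential is undefined and the engine
  raises a degenerate-extinction error. Grid sweeps record such cells with
  control 1 and an `NA` change.
* Negative mean scores are legal state (a susceptibility reserve, e.g.
  produced by negative cross-resistance) and map to zero bioassay
  survival.
* On the deployable efficacy grid (0–1.2) the change in bioassay survival
  at partial exposure is hump-shaped in efficacy only where the grid spans
  the selection peak. For strongly resistant populations (80% bioassay
  survival generally, 50% at exposures ≥ 0.8) even efficacy 1.2 leaves
  exposed survival too high, the peak lies beyond the grid and the change
  rises monotonically across it; extending the efficacy axis to the lethal
  dose recovers an interior maximum for every resistance level. The test
  suite asserts exactly this two-part statement.

## What the Monte-Carlo cohorts do and do not establish

The cohort simulator draws individuals from the *assumed* structure:
independent normal traits, Bernoulli exposure, deterministic top-fraction
survival (by default against the theoretical normal quantile, so the
comparison probes the dilution and averaging algebra rather than quantile
estimation; an empirical-quantile mode exists). Agreement between the
analytic differentials and cohorts of $10^6$ individuals across randomised
parameter settings (within three batch-mean standard errors) verifies that
the closed forms are the correct expectations *of that structure*. It says
nothing about real mosquito populations: non-normal trait distributions,
exposure heterogeneity beyond Bernoulli, probabilistic (non-truncation)
mortality, evolving variance, and density-dependent demography are all
outside the model, so passing tests validate internal consistency, not
field realism. Correlated-trait cohorts are provided only to probe the
cross-resistance approximation (the analytic engine treats the two
truncations as independent given the means, with $\alpha$ entering only
through the correlated response).

## Problem sizes

The shipped analyses use the full single-generation grids (780 monotherapy
and 60,840 mixture cells), three scenario sweeps of 90 strategy
comparisons each (every comparison running both arms to at most 500
generations), and twenty million-individual oracle cohorts; unit tests
exercise the same code on smaller cohorts ($10^3$–$2\times10^5$) chosen to
keep the suite brisk while leaving Monte-Carlo error well below the
three-standard-error bands.

## Known limitations

* No population dynamics, age structure or disease transmission: degree of
  control is a per-generation diagnostic and strategy lifespan the only
  multi-generation outcome.
* Fixed phenotypic variance; selection cannot erode it.
* The probabilistic-selection branch of polygenic models is not
  implemented; only truncation selection is.
* Decay-parameter estimation from field durability data is out of scope;
  rates are inputs.
* Plotting is left to the user (the tidy CSVs are designed for ggplot2);
  no figure replication is attempted.
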