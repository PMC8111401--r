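---
title: "Modelling lisinopril disposition in irradiated and control rats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lisinopril disposition in irradiated and control rats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpk)
```

## The scientific problem

ACE inhibitors such as lisinopril are leading candidates for mitigating
the delayed injuries (lung, kidney, heart) that follow high-dose partial
body irradiation.  Regulatory development requires knowing whether
irradiation itself changes the drug's pharmacokinetics.  `radpk`
implements the complete analysis pipeline for a rat study of this
question: a mechanistic compartmental model of lisinopril disposition,
population (mixed-effects) estimation of radiation-group effects,
model-free exposure (AUC) comparison, and a synthetic-study generator so
that every stage can be validated by simulation even though the original
animal-level measurements are not publicly deposited.

## The structural model

Drug amounts (µmol) are tracked in four compartments: the gut depot
(gavage dosing only), plasma (central, volume $V_2$), a lumped
peripheral compartment representing internal tissues (volume $V_3$),
and cumulative urine.  With $C_\mathrm{plasma} = Y_\mathrm{plasma}/V_2$
the system is

$$
\begin{aligned}
\dot Y_\mathrm{depot} &= -k_a Y_\mathrm{depot},\\
\dot Y_\mathrm{plasma} &= F k_a Y_\mathrm{depot}
  - Cl\, C_\mathrm{plasma} - Q\, C_\mathrm{plasma} + Q\, Y_\mathrm{peri}/V_3,\\
\dot Y_\mathrm{peri} &= Q\, C_\mathrm{plasma} - Q\, Y_\mathrm{peri}/V_3,\\
\dot Y_\mathrm{urine} &= Cl\, C_\mathrm{plasma},
\end{aligned}
$$

with absorption rate $k_a$ (1/h), bioavailability $F$ (the fraction of
an oral dose reaching circulation, applied to the depot-to-plasma
transfer so that a fraction $1-F$ of absorbed drug leaves the system
unobserved), renal clearance $Cl$ (L/h) and inter-compartmental
clearance $Q$ (L/h).  Intravenous dosing places the dose directly in
plasma and bypasses both the depot and $F$.  Units are fixed
throughout: hours, liters, µmol; doses in µg are converted by the molar
mass 405.5 g/mol at the data boundary (`dose_to_umol()`).

Because the system is linear with constant coefficients, `pk_solve()`
evaluates the exact solution: a sum of exponentials in the two
disposition rates $\alpha \ge \beta$ (the roots of
$x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21}$, where
$k_{10}=Cl/V_2$, $k_{12}=Q/V_2$, $k_{21}=Q/V_3$) and the absorption
rate $k_a$.  Rates that coincide to within a relative gap of $10^{-10}$
(confluent cases, or a vanishing terminal rate when $Cl$ or $Q$ is
zero) are routed through a Padé matrix exponential of the full
$4\times4$ system, which is exact for any parameter values; an adaptive
ODE integrator exists in the test suite purely as an oracle.  Two
closed-form consequences used throughout: the terminal half-life is
$\log 2/\beta$ (`terminal_half_life()`), and
$\mathrm{AUC}_{0-\infty} = F D / Cl$ for gavage ($D/Cl$ IV), because in
a linear system every absorbed molecule is ultimately excreted in
urine at rate $Cl\,C_\mathrm{plasma}$ (`auc_infinity()`).

```{r halflives}
ctrl <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
                  V2 = 0.008, V3 = 0.513)
rad <- radiation_effect(ka = 0.883, Cl = 0.943, Q = 0.615, F = 1.326)
c(control = terminal_half_life(ctrl),
  irradiated = terminal_half_life(apply_radiation(ctrl, rad)))
```

## Stochastic model and likelihood

Radiation acts multiplicatively on $k_a$, $Cl$, $Q$ and $F$
(`radiation_effect()`); the volumes carry no group effect.  Animals
share group-typical parameters except for log-normal multiplicative
random effects on the volumes,
$V_{2,i} = V_2 e^{\eta_{i1}},\ V_{3,i} = V_3 e^{\eta_{i2}}$ with
$\eta_i \sim N(0, \mathrm{diag}(\omega_{V2}^2, \omega_{V3}^2))$.
Measurements carry additive Gaussian error with a separate SD per
observed compartment (plasma concentration, µmol/L; cumulative 24-h
urine amount, µmol).  Only plasma and urine enter the likelihood; the
peripheral amount is inferred from the model.  Raw measured values are
divided by their spike-in extraction efficiencies before fitting, and
pre-dose (t = 0) records are retained in the data but excluded from the
likelihood.

The marginal likelihood integrates $\eta_i$ out per animal.
`pk_loglik()` approximates each animal's integral by an exact
vectorized Newton search for the conditional mode followed by a
second-order (Laplace) expansion — `nodes = 1` — or by mode-centred,
curvature-scaled adaptive Gauss–Hermite quadrature for `nodes > 1`.
With both $\omega$ components zero the random effects drop out and the
value is the exact Gaussian residual log-likelihood.

Two numerical choices deserve record:

* **Curvature floor.**  The mode curvature $\det(-H)$ entering the
  Laplace correction is floored at the prior curvature
  $1/(\omega_{V2}\omega_{V3})^2$.  Without the floor the correction
  $-\tfrac12\log\det(-H)$ grows without bound as an animal's
  conditional density approaches a fold ($\det \to 0$), which plants
  spurious cusp optima that attract the outer optimizer — we observed
  square-root-shaped cusps at apparent "optima" before introducing the
  floor.  The floored value respects the bound that an animal's
  marginal can never exceed the supremum of its conditional likelihood.
* **Quadrature default.**  `pk_fit()` uses `nodes = 3` by default.  In
  null-hypothesis simulations (all radiation ratios 1) the pure
  Laplace Wald statistics for the $Q$ and $F$ ratios were markedly
  overdispersed (SD of null z-scores up to $\approx 4$ at the full
  study size) because the approximation error varies with the realized
  data of the sparsely sampled, urine-only animals; three-node
  adaptive quadrature removes the worst of this at about 1.5× the
  computational cost, and reduces exactly to the Laplace value as
  `nodes = 1`.  Residual over-dispersion remains at small study sizes
  (see the limitations below).

Estimation (`pk_fit()`) maximizes this marginal likelihood over
log-transformed positive parameters, a logit-transformed $F$, and
log-ratios for the radiation effects; Wald intervals and tests (of each
log-ratio against 0) are formed on the estimation scale and
back-transformed.  The objective has stiff directions (curvatures
$\sim 10^7$) next to nearly flat variance-component directions, and the
quasi-Newton line search regularly halts early ("false convergence")
or on saddle points.  `pk_fit()` therefore conditions `nlminb` with
per-parameter scales from a pilot curvature probe, and follows it with
an eigendecomposition of an adaptive-step finite-difference Hessian:
genuine negative-curvature directions trigger an escape line search and
a re-run, and at a minimum, damped Newton steps on a broad-scale
(SE-proportional step) gradient polish the solution until the Newton
step is below a tenth of every standard error (flat directions,
eigenvalues below $10^{-6}$ of the stiffest, are excluded from this
criterion and clamped in the reported covariance).  The broad-scale
gradient is deliberate: the per-animal mode approximations imprint a
small-scale wiggle on the marginal likelihood, and only the slope of
the broad quadratic is statistically meaningful.  Up to three
jittered restarts follow if convergence still fails.  Starting values
come from non-compartmental heuristics (`pk_init()`): $V_2$ from
back-extrapolated first IV concentrations, $Cl$ from IV dose/AUC, $k_a$
from the gavage peak time, $F$ from the gavage/IV urinary recovery
ratio, with fixed fallbacks when an arm is missing.

Identifiability hinges on the design: the IV arm anchors $V_2$ and
separates $F$ from $k_a$, and urinary recovery anchors $Cl$ and $F$;
`pk_fit()` warns when either is absent.  The nested one-compartment
model (`model = "one_cpt"`, dropping $Q$, $V_3$, their ratio and
$\omega_{V3}$; 4 parameters fewer) supports the likelihood-ratio
comparison via `anova()`.

## Non-compartmental analysis

For the sparse batch (serial-sacrifice) design — most animals
contribute a single plasma sample — `nca_auc()` estimates the
dose-normalized AUC(0–tlast) by the linear trapezoidal rule on the
arithmetic per-time means (normalization to 300 µg administered,
tlast = 24 h by default).  Uncertainty uses a bootstrap-t: animals are
resampled with replacement within each time-point batch, each
replicate's AUC is studentized by its own delta-method SE
($\sum_j w_j^2 s_j^2 / n_j$ over trapezoid weights $w_j$), and the
resulting t-quantiles calibrate the interval.  Time points observed in
a single animal cannot be studentized; they enter the point estimate
but contribute no variance (with a warning), and when no batch is
studentizable the interval falls back to bootstrap percentiles.  The
radiation/control ratio (`nca_ratio()`) applies the same machinery to
the log-ratio; its p-value is the bootstrap-t tail fraction against a
zero log-ratio.  The resampling unit, window and replicate count are
recorded in the returned objects together with the seed, so intervals
are exactly reproducible.

## The synthetic-study generator

`study_design()` reproduces the original sampling layout exactly: 219
animals in 20 cells of radiation group × route × dose (300/600 µg
gavage, 60 µg IV, plus a small vehicle cell), each animal with 0–4
sparse plasma draws from the scheduled menus (13 gavage times between 0
and 48 h; 5 min, 1.5 h, 24 h IV) and at most one cumulative 24-h urine
collection.  `simulate_study()` draws each animal's volumes, solves the
model exactly, adds the additive noise, multiplies by the extraction
efficiency (so the ETL correction recovers the noisy value), and emits
a dataset that passes `validate_pk_dataset()` unchanged.

The original study reports neither residual nor between-animal
variance estimates, so the generator's defaults are explicitly
synthetic and chosen once: $\omega_{V2}=\omega_{V3}=0.3$, and residual
SDs at 5% of a model-derived reference scale per compartment (the peak
control 300 µg gavage concentration for plasma; the design-weighted
mean model 24-h urine amount for urine).  These produce inter-animal
spread comparable to the roughly 1.6–2.7-fold variation reported
qualitatively for the real data.  Extraction efficiencies default to
0.85 (plasma) and 0.90 (urine) — plausible spike-in recoveries; their
exact values are immaterial because generation and correction invert
each other.  Additive noise may produce negative raw values; they are
retained, consistent with the Gaussian error model.  What passing
simulation-based tests do *not* show: robustness to the features the
generator omits — assay limits of quantification, proportional error
components, body-weight covariates, or model misspecification of the
lumped peripheral compartment.

## Validation summary

The test suite validates each stage against an independent route: the
closed-form solver against adaptive ODE integration on randomized
parameter draws (≤ $10^{-8}$ relative); mass balance, dose linearity
and monotonicity as properties; the Laplace/quadrature engine against
a per-animal mode-centred Gauss–Hermite oracle built on `optim` and
`pk_solve`; parameter recovery on replicate full-design simulations
(median relative errors of a few percent for all six structural
parameters and all four ratios, comfortably within 15%); Wald type-I
calibration under a null generator; likelihood-ratio rejection of the
one-compartment reduction on two-compartment data; and bootstrap-t
interval coverage on batch data with a known estimand.  Problem sizes
in the routine suite are chosen for quick feedback — quarter-scale
designs (≈57 animals) for repeated fitting experiments, the full
219-animal design for the headline recovery — and the acceptance
script re-runs the full-design experiments end to end.

## Known limitations

* The additive (not proportional) error model follows the source
  analysis; with concentrations spanning two decades it weights late
  time points weakly.
* Radiation effects are a single dichotomous covariate; no dose-level,
  body-weight or occasion effects are modelled.
* The Wald tests rely on the quadrature-refined marginal likelihood
  and are only asymptotically calibrated.  With `nodes = 1` (pure
  Laplace) they over-reject badly for the $Q$ and $F$ ratios; with the
  quadrature refinement, null rejection rates in our simulations are
  close to nominal at half the study size and above but still
  inflated (roughly 10–15% at a 5% level) on quarter-size designs,
  where single-observation animals with two latent random effects
  leave the integration error data-dependent.  Interval estimates and
  point recovery are unaffected; small-study hypothesis tests should
  be interpreted cautiously.
* Saturable ACE binding (a candidate mechanism for the long terminal
  phase) is outside the model class: kinetics are strictly linear.
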