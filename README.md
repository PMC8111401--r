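# radpk

Population pharmacokinetics of lisinopril in irradiated and control
rats.

ACE inhibitors are among the most promising mitigators of the delayed
multi-organ injuries caused by high-dose partial-body irradiation, and
regulatory development requires knowing whether irradiation changes
the drug's own pharmacokinetics. `radpk` implements the complete
analysis pipeline for a rat study of that question — and, because the
animal-level measurements behind the published analysis are not
publicly deposited, a synthetic-study generator that reproduces the
study's sparse sampling design so the whole pipeline can be validated
by simulation.

The core is a two-compartment disposition model with an oral (gavage)
depot and a cumulative urine compartment.  Amounts in µmol:

    dY_depot/dt  = -ka * Y_depot
    dY_plasma/dt =  F * ka * Y_depot - Cl * C - Q * C + Q * Y_peri / V3
    dY_peri/dt   =  Q * C - Q * Y_peri / V3
    dY_urine/dt  =  Cl * C,        C = Y_plasma / V2

with absorption rate `ka` (1/h), bioavailability `F`, renal clearance
`Cl` (L/h), inter-compartmental clearance `Q` (L/h) and apparent
volumes `V2`, `V3` (L).  IV dosing bypasses the depot and `F`.  The
system is linear, so the package evaluates its exact closed-form
solution (`pk_solve()`), with derived quantities such as the terminal
half-life `log(2)/beta` and `AUC(0,Inf) = F*D/Cl`.

On top of the structural model:

* **Mixed-effects estimation** (`pk_fit()`): log-normal random effects
  on the volumes per animal, additive compartment-specific residual
  error on plasma concentration and cumulative 24-h urine amount,
  multiplicative radiation-group ratios on `ka`, `Cl`, `Q`, `F`.  The
  marginal likelihood is integrated per animal by a vectorized
  conditional-mode (Laplace) expansion, refined by adaptive
  Gauss–Hermite quadrature; Wald intervals and tests of each ratio
  against 1 come back on the natural scale.  The classic S3 surface is
  provided: `summary()`, `coef()`, `confint()`, `logLik()`,
  `predict()`, `residuals()`, `simulate()`, `plot()`, and `anova()`
  for the likelihood-ratio comparison against the nested
  one-compartment model.
* **Non-compartmental analysis** (`nca_auc()`, `nca_ratio()`):
  dose-normalized trapezoidal AUC(0–24 h) over per-time arithmetic
  means for the sparse batch design, with bootstrap-t confidence
  intervals (animals resampled within time-point batches) and a
  bootstrap-t test of the radiation/control AUC ratio.
* **Synthetic studies** (`study_design()`, `simulate_study()`,
  `recovery_experiment()`): the original 219-animal design — 20 cells
  of radiation group × route × dose with 0–4 sparse plasma draws per
  animal and single 24-h urine collections — with the model's stated
  stochastic structure and extraction-efficiency attenuation.
* **Data handling** (`read_pk_dataset()`, `validate_pk_dataset()`,
  `dose_to_umol()`, `correct_extraction()`): a NONMEM-style CSV layout
  with row-numbered schema diagnostics.

## Worked example

```r
library(radpk)

## typical control-group values and radiation-group ratios
ctrl <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
                  V2 = 0.008, V3 = 0.513)
rad  <- radiation_effect(ka = 0.883, Cl = 0.943, Q = 0.615, F = 1.326)

terminal_half_life(ctrl)
#> [1] 65.28471
terminal_half_life(apply_radiation(ctrl, rad))
#> [1] 83.52688
```

The long terminal half-life (65 h in control animals, 84 h after the
radiation ratios are applied) reflects the slow return of drug bound
in the peripheral compartment; the irradiated value is longer mainly
because the inter-compartmental clearance ratio (0.615) slows that
exchange.

Simulate a study at a quarter of the original size, fit it, and test
the radiation effects:

```r
cfg <- sim_config(theta = ctrl, ratios = rad,
                  design = scale_design(study_design(), 0.25))
d   <- simulate_study(cfg, seed = 42)
fit <- pk_fit(d)
summary(fit)
#> Two-compartment mixed-effects fit: 74 observations, 56 animals
#> log-likelihood 95.138; R2 = 100.0%; convergence code 0
#>
#> Base parameter estimates (control group):
#>  parameter estimate     lwr     upr  units
#>         ka  0.28700 0.25900 0.31800   1/hr
#>          F  0.19100 0.17700 0.20500 scalar
#>         Cl  0.00859 0.00795 0.00928   L/hr
#>          Q  0.01490 0.01260 0.01760   L/hr
#>         V2  0.00756 0.00638 0.00896      L
#>         V3  0.48400 0.36300 0.64500      L
#>
#> Radiation-group parameter ratios (irradiated / control):
#>  parameter estimate   lwr   upr p_value
#>   ratio.ka    0.817 0.743 0.900 3.6e-05
#>   ratio.Cl    0.943 0.873 1.020    0.14
#>    ratio.Q    0.591 0.457 0.765 6.1e-05
#>    ratio.F    1.340 1.200 1.490 9.4e-08
#>
#> Variance components (SDs):
#>      V2      V3  plasma   urine
#> 0.26200 0.00353 0.07590 0.00483
```

Estimates recover the generating values; the `p_value` column tests
each ratio against 1, so here the fit flags the reduced
inter-compartmental clearance and raised bioavailability of the
irradiated group while leaving renal clearance equivocal at this
sample size.
`anova(fit, pk_fit(d, model = "one_cpt"))` gives the likelihood-ratio
test against the one-compartment reduction, and `r_squared(fit)` the
pooled goodness of fit.

Model-free exposure comparison on the same dataset:

```r
nca_ratio(d, tlast = 24, B = 2000, seed = 1)
#> AUC(0-24 h) ratio irradiated/control: 1.611
#>   95% CI [1.431, 1.795]; p = 0.0055 (bootstrap-t, B = 2000)
```

(The 0-24 h data ratio exceeds the model's asymptotic `r_F / r_Cl =
1.41` because the slower peripheral exchange of the irradiated group
also keeps more drug in plasma over the first day.)

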