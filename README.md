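# acetapop

Population pharmacodynamics of acetazolamide-induced bicarbonate
lowering in invasively ventilated COPD patients.

Mechanically ventilated COPD patients often develop metabolic
alkalosis, which depresses respiratory drive and can prolong weaning.
Acetazolamide (a carbonic anhydrase inhibitor) increases renal
bicarbonate elimination and is used to correct it.  `acetapop` is an R
package for the population PK/PD analysis of that response, aimed at
pharmacometricians and intensivists who want to reproduce, stress-test
or extend the dose–response reasoning behind acetazolamide dosing in
this setting.

## The model

Drug amount: one-compartment iv bolus superposition with a half-life
fixed at six hours,

    A(t) = sum_j D_j exp(-k_elim (t - t_j)),   k_elim = ln(2)/0.25 per day.

Serum bicarbonate: an indirect-response (turnover) model in which the
drug stimulates elimination through an Emax function of the body
amount,

    dBicar/dt = kin - kout [1 + Emax A(t)/(A(t) + A50)] Bicar,
    Bicar(0) = Bicar0 = kin/kout,  Emax = 1 (fixed).

Covariate submodel (baseline standardized to SAPS II 50, chloride
100 mmol/L):

    Bicar0 = TV(Bicar0) (SAPSII/50)^-0.112 (Cl/100)^-1.18 (1.092 if steroids)
    kout   = TV(kout) [1 - Furo/(Furo + Fur50)]

with exponential between-subject variability on `Bicar0` and `kout`
and a proportional residual error.  Default parameter values
(`population_parameters()`) are the published estimates:
TV(Bicar0) = 35.5 mmol/L, TV(kout) = 0.395/day, A50 = 117 mg,
Fur50 = 187 mg/day, omega = (0.101, 0.792), sigma = 0.04.

The package provides: trajectory solvers (adaptive ODE, an
integrating-factor oracle, and a fast compiled engine — cross-checked
to < 1e-6 mmol/L), a synthetic study generator emulating the original
68-patient design, exact marginal-likelihood mixed-effects estimation,
NPDE diagnostics with decorrelation, dosing-scenario simulation, and a
small CLI (`inst/cli/acetapop.R`).

## Worked example

Simulate a 68-patient study at the published values, refit it, and run
the diagnostics:

```r
library(acetapop)
theta <- population_parameters()          # published final model
ds <- generate_study(study_design(), theta, seed = 7)
fit <- fit_nlme(ds)                       # ~30 s
print(fit)
```

```
Population model fit (68 subjects, 214 observations)
  log-likelihood -512.23 | AIC 1044.5 | BIC 1078.1 | 10 estimated parameters
              estimate   rse fixed
tv_bicar0      35.9100  (2%)
beta_saps      -0.2268 (17%)
beta_chloride  -1.0010 (21%)
theta_cort      1.0490  (3%)
tv_kout         0.4482 (19%)
fur50          71.5300 (45%)
a50           112.5000 (15%)
omega_bicar0    0.0949 (10%)
omega_kout      0.8378 (13%)
sigma_prop      0.0405  (7%)
  shrinkage: bicar0 0.06, kout 0.16
```

At this (realistic) study size the structural parameters are recovered
well — baseline 35.9 vs 35.5 mmol/L, A50 112 vs 117 mg — while the
covariate exponents carry the large uncertainties typical of a
68-patient design.  Model adequacy via normalized prediction
distribution errors:

```r
np <- compute_npde(ds, fit$estimates, K = 500, seed = 8)
npde_tests(np)
#> NPDE mean 0.005 var 1.037 | p(mean)=0.92 p(var)=0.68 p(norm)=0.55
```

None of the calibration tests reject: mean ~0, variance ~1,
approximately normal, as expected when the model is correct.  Typical-
subject dose–response (change from baseline at 24 h, total daily dose
split twice daily):

```r
dose_response_24h(theta)
#>   daily_dose delta_24h
#> 1          0      0.00
#> 2        250     -4.07
#> 3        500     -5.67
#> 4       1000     -7.10
```

and scenario comparison, e.g. furosemide coprescription blunting the
response over a 5-day course of 500 mg once daily:

```r
simulate_scenarios(theta, list(
  scenario("reference", dose = 500),
  scenario("furosemide 160 mg/day",
           subject_covariates(furosemide_dose = 160), dose = 500)))$summary
#>                   label bicar0 max_decrease t_nadir
#> 1             reference   35.5        11.76    4.54
#> 2 furosemide 160 mg/day   35.5         9.74    4.71
```

`headline_check(theta)` tabulates, per covariate scenario, the smallest
menu dose achieving a > 5 mmol/L decrease.

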