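# svcpois

Semi-varying coefficient conditional Poisson models for daily helpline
call counts.

## What this package is for

Telephone quitlines are a first point of contact for smokers considering
quitting, and their daily call volume responds to televised anti-smoking
campaigns (measured in TARPs — target audience rating points), to strong
day-of-week structure, and to slowly changing conditions (holiday periods,
public-relations events) for which no covariates exist. `svcpois` fits a
first-order autoregressive conditional Poisson model whose mean splits into
a carryover term with a smoothly time-varying coefficient and a parametric
immigration term:

    E(Y_j | F_{j-1}) = Y_{j-1} (alpha_j + X_j' beta) + Z_j' gamma

where `Y_{j-1}` is yesterday's count, `alpha_j = alpha(t_j)` is a smooth
per-capita carryover rate (the nonparametric part, estimated by local-linear
kernel smoothing), `X_j` holds six day-of-week indicators (Sunday is the
reference) modifying the carryover, and `Z_j = [X_j | TARPs_Quit |
TARPs_NRT]` drives the immigration of new callers. Estimation is by profile
backfitting between the kernel smoother and identity-link quasi-Poisson
estimating equations; standard errors come from an
overdispersion-adjusted nonparametric residual bootstrap. The package is
aimed at analysts of media-intervention count series: it also ships
goodness-of-fit diagnostics (Poisson deviance R², Pearson residuals, a
regression-based overdispersion test), a five-model mean-square-error
comparison against simpler references, and a synthetic-data generator with
known ground truth (including a finite-population chain-binomial mode) so
the whole pipeline is testable without access to confidential helpline
records.

## Worked example

```r
library(svcpois)

sim <- simulate_calls(sim_config(seed = 1))   # a synthetic advertising year
fit <- svcm(sim$series, bandwidth = "auto")   # CV-selected bandwidth
fit
```

```
Semi-varying coefficient conditional Poisson model
  360 days (2000-08-06 to 2001-07-31), bandwidth 7 days, epanechnikov kernel
  backfit: 22 iteration(s), converged

Carryover modifiers (beta, relative to Sunday):
    Mon     Tue     Wed     Thu     Fri     Sat
 0.0897 -0.1529 -0.3215 -0.4619 -0.3300 -0.6751

Immigration effects (gamma):
       Mon        Tue        Wed        Thu        Fri        Sat TARPs_Quit
   52.7880    -4.0155    24.4787    21.0724    12.0794     5.0925     0.4501
 TARPs_NRT
    0.2303

Varying coefficient alpha(t): range [0.637, 1.46]
```

The carryover modifiers say how yesterday's volume propagates: after a busy
Monday, Tuesday-to-Saturday carryover is depressed (cohort depletion), most
strongly on Saturday. The immigration effects say what a day contributes on
its own: a Monday brings about 53 fresh calls even after a silent Sunday,
and every TARP of Quit-campaign advertising adds about half a call — about
twice the per-TARP effect of the NRT campaign. The fitted `alpha(t)` curve
rises above 1.4 during the New-Year surge the generator plants inside the
holiday advertising gap.

```r
boot <- boot_svcm(fit, B = 500, seed = 1)     # 5000 for production use
head(wald_table(fit, boot), 3)
```

```
  parameter label    estimate         se         z            p
1  beta_Mon   Mon  0.08965022 0.06781840  1.321916 1.861961e-01
2  beta_Tue   Tue -0.15286767 0.05392394 -2.834876 4.584349e-03
3  beta_Wed   Wed -0.32154749 0.04774387 -6.734843 1.641069e-11
```

```r
svcm_diagnostics(fit)
```

```
Deviance R-squared: 0.956
Pearson residuals: mean 0.01633 , variance 1.005
Overdispersion: phi_hat = 0.001922 , z = 0.02591 , P = 0.4897
MSE: 68.5
```

On this Poisson-noise scenario the dispersion is at its null (real helpline
data are strongly overdispersed, which is what the bootstrap's phi
adjustment is for). `compare_models(sim$series, bandwidth = fit$bandwidth)`
reproduces the expected in-sample ordering: the full model beats the
varying-carryover model without day modifiers, which beats the
constant-carryover model, which beats the TARP-only regression.

A thin command-line wrapper is installed with the package for scripted use
(`simulate`, `fit`, `bootstrap`, `compare` subcommands):

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts", "svcpois.R", package = "svcpois"))')
Rscript "$SCRIPT" fit --preset seasonal-troughs --outdir out --bandwidth auto
```

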