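# tpnmrds

Mark-recapture distance sampling (MRDS) with a **two-piece normal detection
function**, for dual-observer aerial line-transect surveys whose detection
curve peaks *off* the transect line.

## Who this is for

Wildlife biometricians estimating abundance (and, downstream, harvest rates)
of bears or similar species from fixed-wing surveys with a pilot and a
backseat observer. Flat side windows create a blind strip under the aircraft
and a unimodal, asymmetric detection shape, so conventional distance sampling
— which assumes perfect detection on the line and a monotone detection
function — is biased twice over. `tpnmrds` removes both assumptions:

- the **distance model** is a two-piece normal with apex `μ` and a log-linear
  scale that differs left and right of the apex and may depend on covariates,
  fit by conditional maximum likelihood on exact distances:

  `g(x, z) = exp(−(x−μ)² / 2σ(x,z)²)`,
  `ln σ(x,z) = β₀ + βₐ·1[x>μ] + βᵀz + γᵀz·1[x>μ]`;

- the **mark-recapture model** is a conditional multinomial logistic model
  for the capture histories {pilot-only, observer-only, both} of groups seen
  by at least one observer, giving absolute detection at the apex,
  `p•(μ̂, z) = p₁ + p₂ − p₁p₂`;

- under **point independence** the two combine into a per-group detection
  probability `p̂(z) = p•(μ̂, z)·∫ g(u,z)du / (w − w_b)` and a stratified
  Horvitz-Thompson estimate `N̂ₛ = (Aₛ/aₛ) Σ sᵢ/p̂(zᵢ)`, with
  `CV² = CV²(encounter rate) + CV²(model)` (length-weighted among-transect
  "R2" estimator plus a delta method over both coefficient blocks) and
  log-normal confidence intervals.

The package also provides AIC forward selection with χ²/KS/Q-Q goodness of
fit and a detection-probability screen, pooled-versus-stratified model
comparison, harvest-rate estimation honouring biennial hunt averaging, and a
**synthetic survey generator** with known truth so the whole pipeline is
testable by simulation. See the methods vignette
(`vignettes/tpnmrds-methods.Rmd`) for the model details and design choices.

## Worked example

Simulate a survey at the scale of a real two-stratum aerial bear survey
(~360 detected groups, window 22–1000 m), fit both stages, and estimate
abundance and a harvest rate:

```r
library(tpnmrds)

sc  <- sim_scenario()                  # two strata, known truth
sim <- simulate_survey(sc, seed = 7)

tpn <- fit_tpn(sim$detections, covariates = c("bin2sd1000", "tranflat"),
               w_b = 22, w = 1000)
mr  <- fit_mr(sim$detections,
              covariates = c("bed", "observer", "pilot_group", "distance",
                             "pcvr5", "observer_group"))
mcds_gof(tpn)
est <- mrds_abundance(sim$detections, sim$design, tpn, mr)
est
harvest_rate(effective_annual_harvest(c(40, 0), "biennial"), est,
             stratum = "Total")
```

```
Two-piece normal MCDS fit
  n = 374  truncation [ 22 , 1000 ] m
  apex mu = 120.2 m
  logLik = -2430.892  AIC = 4871.78
            Coefficient     SE
ln_mu            4.7889 0.1574
(Intercept)      3.5261 0.3216
igrmew           1.8266 0.3666
bin2sd1000       0.8960 0.1727
tranflat         0.4745 0.1052
Goodness of fit (mcds stage)
  chi-square = 19.411, df = 12, p = 0.079
  Kolmogorov-Smirnov D = 0.0257, p = 0.966
  apex-bin chi-square contribution = 0.017
MRDS abundance estimates (point independence)
  average apex detection: 0.875 (SE 0.025)
 Stratum Estimate    SE     CV Lower 95% CI Upper 95% CI Density/1000km2
      9D    741.0 65.26  8.81%        623.7        880.3           85.68
      10    157.7 17.52 11.11%        127.0        196.0           54.99
   Total    898.7 72.22  8.04%        767.9      1,051.8           78.03
Harvest rate estimate
  annual harvest: 20  abundance: 898.7 (CV 8.04%)
  rate: 2.18%  SE: 0.17%  95% CI: ( 1.87% , 2.54% )
```

Reading the output: the fitted apex (120.2 m, truth 110.5 m) is where
detection peaks; `igrmew` is the log-ratio of the right to left scale
(strong right skew); average apex detection 0.875 means even at the best
distance one-in-eight groups would be missed by both observers — forcing it
to 1 (`mrds_abundance(..., mr = NULL)`) visibly shrinks the estimate, which
is exactly the bias the mark-recapture stage removes. The generating truth
here was 850.4 animals in total; it falls inside the 95% interval
(767.9, 1051.8). The χ² p-value of 0.079 is unremarkable once you know this
reference runs slightly small with estimated parameters (vignette,
"Known limitation").

A config-driven pipeline (`run_fit()`, `run_estimate()`, `run_simulate()`)
and a thin CLI wrapper (`inst/cli/tpnmrds.R`) cover scripted analyses from
CSV detections/transects tables; column names are mapped in the config, so
any reasonable CSV dialect can be consumed.

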