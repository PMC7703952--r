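# riboswitchr

Kinetic modelling, calibration and sensitivity analysis for whole-cell
biosensors built from an RNA **aptamer riboswitch** driving a fluorescent
reporter. The shipped calibrations describe *E. coli* expressing DsRed in
response to the explosive RDX (hexahydro-1,3,5-trinitro-1,3,5-triazine),
but every parameter is an input: the machinery applies to any analyte whose
membrane transport and aptamer binding follow first-order kinetics.

It is aimed at people who design or interpret plate-reader biosensor
assays and want a mechanistic model behind the fluorescence: how long must
a culture be exposed before a given concentration is detectable, what
limits sensitivity, and which rate constants the data can or cannot pin
down.

## The model

Five species evolve by mass action after an analyte aliquot is added at
`t = 0`: extracellular chemical `c_out`, intracellular chemical `c_in`,
bound complex `r*`, free riboswitch `r`, and reporter `p`:

    d[c_out]/dt = k1-·[c_in] - k1+·[c_out]
    d[c_in]/dt  = k1+·[c_out] - k1-·[c_in] - k2+·[c_in][r] + k2-·[r*]
    d[r*]/dt    = k2+·[c_in][r] - k2-·[r*]
    d[r]/dt     = -d[r*]/dt
    d[p]/dt     = k5 + k3·[r*] - k4·[p]

with conserved totals `r + r* = r_tot` and `c_out + c_in + r* = c_tot`.
Under time-scale separation (transport and binding fast relative to
reporter turnover) the reporter admits a closed form whose steady state is
the sigmoid

    p_inf = k5/k4 + k3·r_tot/k4 · c_tot / (K_D·(1+P)/P + c_tot)

where `P = k1+/k1-` is the cytoplasm:media partition ratio and
`K_D = k2-/k2+` the dissociation constant. The sensor's sensitivity at
exposure time `t` is the half-maximal concentration `c50(t)`, which
follows a power law `c50 = (tau/t)^gamma` with `gamma` near 1: ten times
lower detectable concentration costs about ten times the exposure. See the
vignette (`vignettes/riboswitch-kinetics.Rmd`) for the derivations,
assumptions and numerical choices.

## Worked example

Generate a day of synthetic plate-reader data from the shipped analytic
parameter set (control plus a 44 uM exposure, 2% multiplicative noise),
then run the staged calibration and ask design questions of the result:

```r
library(riboswitchr)

pars <- riboswitch_defaults("mathematical")
pars$p0 <- 20   # fresh culture: reporter starts below the basal plateau

ctrl <- rfu_to_concentration(
  gen_timeseries(pars, c_tot = 0, curve = 107.31,
                 noise = noise_model("multiplicative_lognormal", 0.02, seed = 1)),
  107.31)
rdx44 <- rfu_to_concentration(
  gen_timeseries(pars, c_tot = 44, curve = 107.31,
                 noise = noise_model("multiplicative_lognormal", 0.02, seed = 2)),
  107.31)

basal <- fit_basal(ctrl)
basal
#> Riboswitch model fit: basal reporter kinetics
#>   n = 145, RSS = 173.661, R^2 = 0.9973
#>      estimate      lower      upper
#> k4 8.2979e-06 7.5608e-06 9.1070e-06
#> k5 1.3513e-03 1.3041e-03 1.4003e-03
#> p0 1.9769e+01 1.9197e+01 2.0357e+01

expo <- fit_exposure(rdx44,
                     fixed = list(k4 = coef(basal)[["k4"]],
                                  k5 = coef(basal)[["k5"]],
                                  p0 = coef(basal)[["p0"]],
                                  P = pars$P, K_D = pars$K_D, k3 = pars$k3))
expo
#> Riboswitch model fit: exposure kinetics (c_tot = 44 uM)
#>   n = 145, RSS = 426.222, R^2 = 0.9964
#>            estimate      lower      upper
#> k1_minus 4.7870e-08 3.5864e-08 6.3897e-08
#> r_tot    4.2589e+00 3.8551e+00 4.7050e+00
```

The control fit recovers the reporter turnover (`k4`, `k5`) and starting
level; the exposure fit then identifies the efflux rate and riboswitch
abundance. Both R-squared values sit where real assays of this kind land
(above 0.98). Sensitivity analysis on the calibrated parameters:

```r
power_law_fit(sensitivity_curve(expo$params))
#> Power law c50 = (tau/t)^gamma:
#>   tau   = 344.8 h [336, 353.9]
#>   gamma = 1.0347  [1.0273, 1.0421]

c50(expo$params, 24 * 3600)                  # detectable dose after 24 h
#> [1] 16.25                                  # uM
min_exposure_time(expo$params, 10, 4.4)      # hours to +10 uM DsRed at 4.4 uM
#> [1] 31.58
```

`gamma` near 1 is the inverse-proportionality law. `tau` from this one
noisy day of data overshoots the reference value — the same fit on the
reference parameters themselves gives `tau = 219.6 h`, `gamma = 1.022` —
because a 24 h assay constrains the slow efflux rate only weakly; that
uncertainty is visible in the `k1_minus` interval above and propagates to
`tau`.

The full workflow (synthesis, unit conversion, all fit stages, sensitivity,
with logs, a fit report and a reproducibility manifest) is one call:

```r
res <- run_pipeline(list(params = "mathematical", seed = 11))
```

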