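# desvisc

Sigma-profile neural-network modelling of deep eutectic solvent (DES)
viscosity, for solvent-engineering and QSPR work on choline-chloride DESs
and their cosolvent mixtures.

High viscosity is the main obstacle to using choline-chloride DESs as
green solvents, and dilution with water, methanol, isopropanol or DMSO
changes the viscosity by orders of magnitude. `desvisc` predicts
log₁₀ η (η in mPa·s) of a DES or DES + cosolvent mixture from molecular
structure and state:

* **Descriptors.** Each compound's COSMO sigma-profile (31-point,
  ±0.03 e/Å², read from the open two-column text format) is discretized
  by the trapezoidal rule into eight region areas S₁…S₈ — strong/weak
  hydrogen-bond donor, nonpolar and weak/strong acceptor surface — and
  mixtures combine them by the molar-weighted rule
  Sᵢ^mix = Σⱼ xⱼ Sᵢʲ.
* **Model.** A feed-forward network (tanh hidden layers, linear output;
  reference architecture 9-19-16-1) on the nine inputs (S₁…S₈, T in K),
  trained by Levenberg–Marquardt on the Bayesian-regularized objective
  F = β·E_D + α·E_W with α, β re-estimated each iteration from the
  effective number of parameters γ = N_w − 2α·tr(H⁻¹).
* **Validation.** R²/RMSE/AARD on the log scale, ordered-response
  external splitting (every 9th response-sorted record), leave-one-system-out
  Q², Williams-plot applicability domain (leverages against
  h\* = 3(d\*+1)/p, standardized residuals against ±3), and
  partial-derivative (PaD) input contributions.
* **Synthetic data.** A seeded generator producing Gaussian-peak
  sigma-profiles and Vogel–Fulcher–Tammann viscosity surfaces with
  multiplicative noise, used as the ground-truth oracle in the tests.

## Worked example

```r
library(desvisc)

sim <- simulate_viscosity_dataset(n_hbd = 6, seed = 42)   # 432 records
d   <- split_dataset(sim$data, every_kth = 9, train_fraction = 0.8, seed = 42)
fit <- des_ann(data = d, hidden = c(19, 16), max_iter = 150, seed = 42)
fit
#> sigma-profile neural-network viscosity model
#>   architecture: 9-19-16-1 (527 weights)
#>   trainer: Bayesian regularization (LM), 150 iterations (budget reached)
#>   alpha = 3.945, beta = 5062, effective parameters gamma = 87.6
#>   train    n =  346  R2 = 0.99981  RMSE = 0.01770  AARD = 54.941%
#>   test     n =   38  R2 = 0.99970  RMSE = 0.02218  AARD = 15.789%
#>   external n =   48  R2 = 0.99969  RMSE = 0.02310  AARD = 6.233%
```

R² and RMSE are on the log₁₀-viscosity scale. The inflated AARD is a
known artifact of relative deviations on that scale: records near
1 mPa·s have log η ≈ 0 in the denominator (the methods vignette
discusses this), so RMSE/R² are the stable statistics here. Predictions
come back in mPa·s on request and match the simulated measurements:

```r
predict(fit, d[1:2, ], type = "eta")
#> [1] 4587.7618  876.3942
d$eta_mPas[1:2]
#> [1] 4701.7375  869.0931
```

Reliability and input-importance diagnostics:

```r
williams_report(fit)
#> Williams-plot applicability domain
#>   d* = 9, p = 346, h* = 0.08671, |SDR| < 3
#>           inside response_outlier
#>              426                6
#>   coverage: 98.611% of 432 points inside

relative_contributions(fit)
#> PaD relative input contributions (%)
#>   S8    44.57
#>   S7    18.10
#>   S4    11.28
#>   ...
```

`plot(fit)` draws the parity plot, `plot(fit, which = 2)` the Williams
plot; `coef()`, `residuals()`, `fitted()`, `summary()` and `simulate()`
behave as for any fitted R model. Models serialize losslessly to JSON
(`write_des_ann()` / `read_des_ann()`), and published per-neuron weight
tables can be imported with `import_weight_table()`.

A command-line wrapper with `descriptors`, `simulate`, `train`,
`predict`, `evaluate`, `ad` and `contrib` subcommands is installed at
`inst/cli/desvisc.R`:

```sh
Rscript inst/cli/desvisc.R train --dataset data.csv --profiles profiles/ \
    --model model.json --arch 9,19,16,1 --seed 1
```

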