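# sorbfit

Water sorption isotherm modeling and model selection for dried food
products, built around the storage physics of parchment coffee beans
processed by wet and semidry postharvest methods.

## The problem

The equilibrium moisture content `X_e` (kg water / kg dry solid) a food
attains depends on the water activity `a_w` of the surrounding air, the
temperature, and how the product was processed. A calibrated model of
`X_e(a_w, T, ...)` — the *sorption isotherm* — is the basic tool for
choosing packaging and storage conditions. This package fits and compares
the two families used in practice:

- **Twelve conventional isotherm equations**: the theoretical GAB model

  `X_e = X_m C K a_w / [(1 - K a_w)(1 + (C - 1) K a_w)]`

  with Arrhenius temperature laws
  `C = C_0 exp((H_m - H_n)/(R_w T))`, `K = K_0 exp((lambda - H_n)/(R_w T))`,
  plus the empirical Peleg, Smith, Kuhn, DLP, Chung-Pfost, Caurie,
  Iglesias & Chirife, White & Eiring, Polynomial, Oswin and
  Yanniotis & Blahovec equations, each with linear temperature dependence
  of its coefficients, `a_i(T) = a_i1 T_K + a_i2`.
  Two dummy-variable offsets extend every model across the design:
  `+ b_1 D_1 + b_2 D_2` with `D_1 = 1` for the semidry postharvest method
  and `D_2 = 1` for the adsorption branch.

- **Four machine-learning regressors** on the features
  `(a_w, T, D_1, D_2)`: a cost-complexity-pruned regression tree
  (0.1-SE rule), a 100-tree random forest, 4-nearest-neighbors, and
  nu-SVR with a Laplacian kernel and cost `C = 500.5`, solved exactly as
  a quadratic program.

Parameters are estimated by nonlinear least squares (residual mean square
`RMS = sum((y_exp - y_cal)^2)/N`) with genetic-algorithm or
quadratic-rearrangement (GAB) initialization and asymptotic 95%
confidence intervals. Models are compared by a repeated random 75/25
train/validation protocol (default 100 iterations) scored with the mean
relative error `MRE (%)` and adjusted determination coefficient
`R2_adj (%)`, screened for residual validity (Ljung-Box independence,
Brown-Forsythe/Levene homoscedasticity), and ranked by a two-factor ANOVA
with Fisher LSD letter groups.

A synthetic dynamic-dewpoint-isotherm (DDI) generator reproduces the
measurement protocol (desorption scan 0.60 -> 0.10 a_w, adsorption scan
0.60 -> 0.85 a_w, 0.01 steps, 25/35/45 °C, two methods) with a known
ground truth, so the whole pipeline is testable without instrument data.

## Worked example

```r
library(sorbfit)

ds  <- generate_isotherm(seed = 42)          # 462 synthetic DDI records
fit <- fit_global(attr(ds, "truth")$spec, ds, seed = 1)
fit
#> <fit_result> GAB: RMS = 3.694e-06 on 462 records (converged, 8 iter)
#>        X_m         C_0         K_0         H_m         H_n         b_1         b_2
#>  1.0034e-01  2.0619e-09  9.4974e+00  6.3546e+03  2.8729e+03 -1.5885e-02  1.2313e-03
```

The RMS ~ 3.7e-6 is the square of the generator's noise (sd = 0.002
decimal d.b.), i.e. the model explains everything but measurement error.
`confidence_intervals(fit)` brackets the generating truth
(X_m = 0.102, b_1 = -0.016, b_2 = +0.002):

```r
ci <- confidence_intervals(fit)
#>   parameter   estimate        se      lower      upper
#> 1       X_m  1.003e-01 6.312e-04  9.910e-02  1.016e-01
#> 6       b_1 -1.588e-02 1.802e-04 -1.624e-02 -1.553e-02
#> 7       b_2  1.231e-03 3.973e-04  4.505e-04  2.012e-03
```

Model selection over conventional and ML candidates:

```r
res <- run_pipeline(ds, c("GAB", "Oswin", "RF"), n_iterations = 10, seed = 7)
res$ranking
#>   model mean_mre     se_mre letter_mre mean_r2adj letter_r2adj valid rank
#> 1   GAB 1.511876 0.02782652          a   98.91045            c  TRUE    1
#> 2 Oswin 2.269368 0.05071743          b   97.68490            b FALSE    2
#> 3    RF 3.230960 0.13455637          c   95.36223            a FALSE    3
```

The generating family (GAB) wins with its own LSD letter and is the only
model whose full-data residuals pass both screening tests (Ljung-Box
p = 0.25, Levene p = 0.80); the misspecified Oswin fit shows the serial
and heteroscedastic residual patterns the screening is designed to catch
(both p < 0.001). `mean ± SE` summarize the validation metric across
iterations; models sharing a letter are statistically indistinguishable
at 95%.

## Command line

```sh
Rscript inst/cli/sorbfit simulate --seed 7 --out coffee.csv
Rscript inst/cli/sorbfit evaluate --data coffee.csv \
    --models GAB,Oswin,SVM --iterations 100 --seed 1 --out metrics.csv
Rscript inst/cli/sorbfit rank --metrics metrics.csv --out ranking.json
Rscript inst/cli/sorbfit report --data coffee.csv --model GAB --out report/
```

`simulate` also accepts `--scenario crossing --cross-aw 0.75` to generate
a semidry truth whose 25/45 °C isotherms intersect at high water activity
(the "crossing phenomenon" caused by sugar dissolution).

## Documentation

The methods vignette (`vignettes/sorption-modeling.Rmd`) describes the
models, the estimation and ranking procedure, what the synthetic
generator does and does not emulate, and the package's numerical and
design choices.
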