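---
title: "Modeling water sorption isotherms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling water sorption isotherms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorbfit)
```

## The model and its assumptions

A sorption isotherm relates the equilibrium moisture content $X_e$
(decimal dry basis: kg water per kg dry solid) of a hygroscopic product
to the water activity $a_w \in (0,1)$ of the surrounding air at a given
temperature. Macroporous foods such as parchment coffee typically show a
type-II sigmoid curve. `sorbfit` treats $X_e$ as

$$X_e = f_\theta(a_w, T) + b_1 D_1 + b_2 D_2 + \varepsilon,$$

where $f_\theta$ is one of twelve conventional closed forms, $D_1$
indicates the semidry postharvest method (reference: wet), $D_2$ the
adsorption branch (reference: desorption), and $\varepsilon$ is
measurement error. The additive dummy terms are a deliberate modeling
simplification: both sorption branches and both process variants share
one parametric curve family, and hysteresis and process effects are
constant vertical offsets ($b_2 > 0$ means adsorption sits above
desorption; $b_1 < 0$ means the semidry mucilage coating restricts
hygroscopicity). There is no separate hysteresis-loop model.

Temperature enters in Kelvin everywhere. For GAB, the energy constant
and multilayer factor follow Arrhenius laws,
$C = C_0 e^{(H_m - H_n)/R_w T}$ and $K = K_0 e^{(\lambda - H_n)/R_w T}$,
with the water-specific gas constant $R_w = 0.4615$ kJ kg$^{-1}$
K$^{-1}$ (the sorption heats $H_m$, $H_n$, $\lambda$ are per kilogram of
water, not per mole) and $\lambda = 2406$ kJ kg$^{-1}$, the latent heat
of vaporization near the 35 °C design midpoint. Both constants are
configurable in `model_spec()`. For the empirical equations every
coefficient gets a linear law $a_i(T) = a_{i1} T_K + a_{i2}$. A reduced
DLP variant (`dlp_reduced`) drops the intercept of the $a_2$ line,
mirroring a published parameterization whose intercept entry is absent;
both behaviors are selectable because the omission could be
typographical.

Moisture is decimal dry basis *internally, always*. Printed parameter
tables in this literature mix "% d.b." conventions whose magnitudes are
only mutually consistent when $X_e$ is a decimal fraction of roughly
0.05–0.35; carrying one unit internally removes a 100$\times$ ambiguity
once, at the I/O boundary (`read_dataset(..., xe_unit = "percent")`).

## Estimation

All fits minimize the residual mean square
$\mathrm{RMS} = \sum_i (y_i - \hat y_i)^2 / N$ with an in-package
Levenberg–Marquardt optimizer (central-difference Jacobians, Marquardt
diagonal scaling, only improving steps accepted, step/objective
tolerance $10^{-10}$, at most 2000 iterations). Arrhenius
pre-exponentials are optimized on the log scale; every other parameter
is raw. Domain violations (e.g. $K a_w \ge 1$, a nonpositive
White & Eiring denominator) raise errors during evaluation and act as
rejection barriers during optimization — values are never clamped.

Starting values come from the field's two standard devices:

- **GAB**: the quadratic rearrangement
  $a_w / X_e = \beta_0 + \beta_1 a_w + \beta_2 a_w^2$ is fit by ordinary
  least squares and inverted algebraically ($K$ from
  $K^2 + (\beta_1/\beta_0) K + \beta_2/\beta_0 = 0$, then $C$, then
  $X_m$). Both admissible roots are checked and the one with lower RMS
  kept; the degenerate $C = 2$ case (vanishing linear term) inverts
  cleanly.
- **Empirical models**: a real-coded genetic algorithm (population 60,
  150 generations, tournament selection, blend crossover, Gaussian
  mutation, elitism, mandatory seed) searches generous per-model bounds.

`fit_global()` estimates the temperature-parameterized coefficients and
$b_1, b_2$ over the full design. The default strategy is a single
*joint* RMS minimization — it is well defined, whereas staged
procedures are narrative. The staged alternative
(`strategy = "sequential"`) is retained for fidelity: per-temperature
fits, Arrhenius/linear linkage by log-linear or linear regression
against $T_K$, then a dummy-only refit. Two staging details are the
package's own: per-temperature fits use the *wet-method records of both
branches* (so coefficients never extrapolate beyond the fitted $a_w$
range; the small $b_2$ offset is absorbed later), and each temperature
is warm-started from the previous one, keeping the coefficient paths in
one basin so that the linkage regression is smooth in $T$.

Confidence intervals are the standard asymptotic nonlinear-regression
ones: $\hat\sigma^2 = \mathrm{SSE}/(N - M)$ with the Jacobian at the
optimum, Student-$t$ quantiles, symmetric about the estimates.
Column-equilibrated normal equations keep the computation stable despite
the extreme scale spread of Arrhenius parameters; a rank-deficient
Jacobian raises a non-identifiability error rather than returning
garbage intervals. Monte-Carlo calibration (the acceptance suite) shows
94–98% empirical coverage for $X_m$, $b_1$, $b_2$ at the default design.

## Machine-learning regressors

All four regressors consume the fixed feature encoding
$(a_w, T, D_1, D_2)$. For the distance/kernel methods (kNN, SVM), $a_w$
and $T$ are standardized and the indicators left 0/1 (disable with
`scale = FALSE` in `ml_config()`; whether the original study scaled is
unknown). Trees are scale-invariant and consume raw features.

- **Regression tree**: CART grown with variance-reduction splits
  (minsplit 20, minbucket 7), weakest-link cost-complexity pruning, and
  10-fold cross-validated subtree selection using the one-SE-style rule
  with multiplier 0.1 — the semantics of a post-pruning standard error
  of 0.1.
- **Random forest**: 100 bagged unpruned trees with per-node feature
  subsampling. The default `mtry = max(floor(p/2), 1) = 2` deviates from
  the common regression rule $p/3$, which degenerates to a single
  feature here and produced near-random trees (validation MRE 6.2%
  versus 3.6% for the single tree); at `mtry = 2` the forest dominates
  the tree (2.9%), restoring the ensemble behavior the protocol expects.
- **kNN**: 4 nearest neighbors by Euclidean distance on the scaled
  features. The neighborhood is defined by the $k$ smallest *distinct*
  distances with all ties included, which makes predictions invariant to
  duplicating the training set.
- **nu-SVR**: Laplacian kernel $k(x,z) = e^{-\sigma \|x - z\|}$, cost
  $C = 500.5$, $\nu = 0.5$, kernel width $\sigma$ set by the inverse
  median pairwise distance ($\nu$ and $\sigma$ are artifact choices; the
  study states neither). The dual problem — minimize
  $\tfrac12 (\alpha - \alpha^*)^\top K (\alpha - \alpha^*) - y^\top
  (\alpha - \alpha^*)$ subject to $\sum (\alpha - \alpha^*) = 0$,
  $\sum (\alpha + \alpha^*) \le C \nu n$, $0 \le \alpha, \alpha^* \le C$
  — is solved exactly with `quadprog` (a tiny ridge on the kernel makes
  it strictly convex); the bias and tube half-width come from the KKT
  conditions of the free support vectors.

## Evaluation protocol and ranking

`make_splits()` partitions the records into 75% training / 25%
validation, 100 times by default. Partitions are stratified by the
(method, branch, temperature) cell — with plain uniform sampling a
training set could lose an entire dummy level and make $b_1$ or $b_2$
unidentifiable; unstratified sampling remains available.

Each model is scored on both subsets with
$\mathrm{MRE} = \frac{100}{N} \sum |y - \hat y| / y$ and the adjusted
determination coefficient
$R^2_{adj} = 100 - \frac{N-1}{N-M} (100 - R^2)$. $R^2$ uses the standard
total sum of squares about the observed mean; a published variant that
puts $\sum (\bar y - \hat y)^2$ in the denominator is reproducible with
`denominator = "as_printed"` (neither form is claimed as authorial
intent). For the ML regressors, $M$ is taken as the number of features
plus one (their effective parameter count is not well defined; the
choice only shifts $R^2_{adj}$ by a fraction of a point at $N > 100$).

Residual screening fits each model once on the full dataset and tests
the residuals — ordered by the fixed convention (method, branch,
temperature, ascending $a_w$), since independence tests need an ordering
— with Ljung–Box (lags $\min(10, N/5)$) and Brown–Forsythe/Levene
grouped by $a_w$ terciles (temperature grouping available). Models
failing either test at $\alpha = 0.05$ are still ranked but flagged
invalid, matching the protocol of testing all models while reporting
validity.

Ranking uses a fixed-effects two-factor ANOVA (model and iteration as
factors, the iteration factor treated as fixed) per metric, followed by
unprotected Fisher LSD comparisons
$\mathrm{LSD} = t_{0.975, df_e} \sqrt{2 \mathrm{MSE} / n}$ on the model
factor. Because all pairwise comparisons share one threshold,
non-significance is an interval property of the sorted means, and the
compact letter display assigns one letter per maximal indistinguishable
run; the letters provably agree with the brute-force pairwise verdicts
(tested). The ANOVA's own residuals are checked with Shapiro–Wilk, a
per-model Ljung–Box (Bonferroni-combined — the *pooled* residual
sequence of a two-way layout is constrained by the iteration factor and
inflates the Q statistic, to the point of a 48% false-alarm rate with
two models), and a regression of squared residuals on the model factor
and the iteration *index* (the iteration factor would fit the squares
perfectly in the two-model case).

## The synthetic generator: what it does and does not establish

`generate_isotherm()` emulates the dynamic-dewpoint protocol: a
desorption scan 0.60 → 0.10 $a_w$ and an adsorption scan 0.60 → 0.85, in
0.01 steps, at 25/35/45 °C for wet and semidry methods — 462 records per
replicate. The default ground truth is the Arrhenius-GAB model with
dummy offsets at magnitudes representative of a global fit to parchment
coffee ($X_m = 0.102$, $C_0 = 1.4\times10^{-8}$, $K_0 = 10.5$,
$H_m = 6099$, $H_n = 2895$ kJ kg$^{-1}$, $b_1 = -0.016$,
$b_2 = +0.002$). Noise is additive Gaussian with sd 0.002 decimal d.b. —
the instrument's scatter is not published, so this is a stand-in chosen
small relative to signal and comparable to triplicate error bars; it is
exposed in `noise_model()`. Records at $a_w = 0.60$ appear once per
branch (the raw protocol); merging branches is a view, not a mutation.

`make_crossing_scenario()` builds a semidry truth whose 25/45 °C curves
intersect near a requested $a_w > 0.6$, emulating the high-$a_w$
temperature crossing attributed to sugar dissolution in the mucilage
layer. One construction detail matters: at fixed $C$ the GAB value is
strictly increasing in $K a_w$, so raising $K$ with temperature alone
*cannot* produce a crossing — the scenario therefore lets $C$ fall with
temperature (depressing the low-$a_w$ curve) while solving for the $K$
rise that pins the intersection, then converts both anchors to exact
Arrhenius parameters. The achieved crossing is verified numerically at
construction and refused if it misses by more than 0.05.

What a green test on synthetic data does **not** establish: recovery of
any published parameter values for real coffee (that requires the
deposited measured dataset, out of scope here), realism of the noise
magnitude or its independence structure, instrument drift, or
between-replicate biological variability — the generator draws iid
noise around a smooth truth.

## Numerical choices and degenerate inputs

- Seeds are mandatory for every stochastic stage (GA, splits, ML
  training, noise); identical seeds give byte-identical artifacts.
- Grid construction works in exact step counts with endpoint inclusion;
  a step exceeding the scan range is an invalid-protocol error.
- Zero observed moisture makes MRE undefined and errors; constant
  residual vectors are degenerate inputs for Ljung–Box; Levene requires
  two groups of two.
- A dataset missing a dummy level fails fast with the level named, both
  in fitting and in ranking (unbalanced model × iteration tables are
  schema errors).
- Models failing to converge in more than 20% of split iterations are
  reported as unstable rather than aborting the pipeline.

## Known limitations

No weighted or robust loss, no Bayesian estimation, no isosteric-heat
derivation, no instrument physics. The nu-SVR QP is dense
($2n \times 2n$): fine for DDI-sized data (hundreds of records), not for
datasets orders of magnitude larger. The compact letter display relies
on the common-threshold structure of unprotected LSD; it would need a
general insert–absorb algorithm under unequal per-model variances.
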