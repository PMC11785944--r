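# Synthetic dynamic-dewpoint-isotherm (DDI) datasets with known ground
# truth. The generator emulates the measurement protocol of a vapor
# sorption analyzer: a desorption scan 0.60 -> 0.10 a_w and an adsorption
# scan 0.60 -> 0.85 a_w on a 0.01 step, at 25/35/45 C, for two postharvest
# methods, with additive Gaussian instrument noise.

#' Water-activity grid of a DDI scan
#'
#' @param branch `"desorption"` (0.60 down to 0.10) or `"adsorption"`
#'   (0.60 up to 0.85).
#' @param step grid spacing in water activity units (default 0.01).
#' @return numeric vector of water activities in protocol (scan) order,
#'   endpoints included.
#' @export
ddi_grid <- function(branch = c("desorption", "adsorption"), step = 0.01) {
  branch <- match.arg(branch)
  if (!is_scalar_number(step) || step <= 0)
    stop_sorb("step must be a positive number", "sorbfit_invalid_protocol")
  lims <- if (branch == "desorption") c(0.60, 0.10) else c(0.60, 0.85)
  span <- abs(diff(lims))
  if (step > span + 1e-12)
    stop_sorb(sprintf("step %.3g exceeds the %s range %.2f-%.2f",
                      step, branch, lims[1], lims[2]),
              "sorbfit_invalid_protocol")
  dir <- sign(lims[2] - lims[1])
  k <- floor(span / step + 1e-9)
  g <- lims[1] + dir * step * (0:k)
  g <- round(g, 10)
  if (abs(g[length(g)] - lims[2]) > 1e-9) g <- c(g, lims[2])
  g
}

#' Measurement-noise description for the synthetic generator
#'
#' @param kind `"gaussian-additive"` (sd in decimal d.b.),
#'   `"gaussian-proportional"` (sd as a fraction of the true value), or
#'   `"none"`.
#' @param sd noise scale (>= 0). Default 0.002 decimal d.b., a stand-in
#'   for triplicate DDI scatter.
#' @return a `noise_model` object.
#' @export
noise_model <- function(kind = c("gaussian-additive", "none",
                                 "gaussian-proportional"),
                        sd = 0.002) {
  kind <- match.arg(kind)
  if (!is_scalar_number(sd) || sd < 0)
    stop_sorb("noise sd must be >= 0", "sorbfit_invalid_noise")
  structure(list(kind = kind, sd = sd), class = "noise_model")
}

#' Default synthetic ground truth
#'
#' A GAB model with Arrhenius temperature dependence and dummy offsets,
#' using parameter magnitudes representative of a global fit to parchment
#' coffee DDI data (moisture in decimal dry basis).
#'
#' @return list with elements `spec` ([model_spec()]) and `params`.
#' @export
default_truth <- function() {
  list(
    spec = model_spec("GAB", temp_mode = "arrhenius", uses_dummies = TRUE),
    params = c(X_m = 0.102, C_0 = 1.4e-8, K_0 = 10.5,
               H_m = 6099, H_n = 2895, b_1 = -0.016, b_2 = 0.002)
  )
}

canonical_order <- function(df, methods = c("wet", "semidry"),
                            branches = c("desorption", "adsorption")) {
  df[order(match(df$method, methods), match(df$branch, branches),
           df$temperature_c, df$aw, df$replicate), , drop = FALSE]
}

#' Generate a synthetic DDI sorption dataset
#'
#' One record per water-activity grid point x temperature x method x
#' branch x replicate; `xe` is the truth-model evaluation (including dummy
#' offsets) plus noise. Regeneration with the same seed is bit-identical.
#'
#' @param truth_spec,truth_params ground-truth model ([model_spec()] and
#'   named parameter vector); default [default_truth()].
#' @param temperatures design temperatures, Celsius.
#' @param methods postharvest methods, subset of `c("wet", "semidry")`.
#' @param branches subset of `c("desorption", "adsorption")`.
#' @param replicates number of replicate scans per design cell.
#' @param step water-activity grid step.
#' @param noise a [noise_model()].
#' @param seed integer seed (mandatory when noise kind is not `"none"`).
#' @return an `isotherm_dataset`: a data.frame with columns
#'   `aw, temperature_c, method, branch, replicate, xe` in canonical order
#'   (method, branch, temperature, ascending aw), carrying attributes
#'   `truth`, `seed`, `provenance`.
#' @export
generate_isotherm <- function(truth_spec = NULL, truth_params = NULL,
                              temperatures = c(25, 35, 45),
                              methods = c("wet", "semidry"),
                              branches = c("desorption", "adsorption"),
                              replicates = 1, step = 0.01,
                              noise = noise_model(), seed = 1L) {
  if (is.null(truth_spec)) {
    tr <- default_truth()
    truth_spec <- tr$spec
    truth_params <- tr$params
  }
  stopifnot(inherits(truth_spec, "model_spec"), inherits(noise, "noise_model"))
  if (!length(temperatures) || !length(methods) || !length(branches) ||
      replicates < 1)
    stop_sorb("design must be nonempty", "sorbfit_invalid_design")
  methods <- match.arg(methods, c("wet", "semidry"), several.ok = TRUE)
  branches <- match.arg(branches, c("desorption", "adsorption"),
                        several.ok = TRUE)
  cells <- expand.grid(method = methods, branch = branches,
                       temperature_c = temperatures,
                       replicate = seq_len(replicates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    g <- ddi_grid(cells$branch[i], step)
    data.frame(aw = g, temperature_c = cells$temperature_c[i],
               method = cells$method[i], branch = cells$branch[i],
               replicate = cells$replicate[i], stringsAsFactors = FALSE)
  }))
  recs <- canonical_order(recs, methods, branches)
  rownames(recs) <- NULL
  xe_true <- tryCatch(
    evaluate_model(truth_spec, truth_params, recs$aw, recs$temperature_c,
                   d1 = as.numeric(recs$method == "semidry"),
                   d2 = as.numeric(recs$branch == "adsorption")),
    error = function(e) stop_sorb(
      paste0("invalid truth configuration: ", conditionMessage(e)),
      "sorbfit_invalid_truth"))
  if (any(!is.finite(xe_true)) || any(xe_true < 0))
    stop_sorb("invalid truth configuration: model evaluation yields negative or non-finite xe",
              "sorbfit_invalid_truth")
  recs$xe <- withr::with_seed(as.integer(seed), {
    switch(noise$kind,
      none = xe_true,
      `gaussian-additive` = xe_true + rnorm(length(xe_true), 0, noise$sd),
      `gaussian-proportional` = xe_true * (1 + rnorm(length(xe_true), 0, noise$sd)))
  })
  structure(recs,
            truth = list(spec = truth_spec, params = truth_params,
                         noise = noise),
            seed = as.integer(seed), provenance = "synthetic",
            class = c("isotherm_dataset", "data.frame"))
}

#' Construct a temperature-crossing ground truth
#'
#' Builds a semidry-method GAB truth whose 25 C and 45 C adsorption curves
#' intersect near a requested water activity (the high-`a_w` "crossing
#' phenomenon" attributed to sugar dissolution). The crossing location is
#' verified numerically at construction.
#'
#' @param cross_aw requested crossing water activity, in (0.6, 0.85).
#' @param X_m,C25,C45,K25 anchor values of the GAB coefficients at the two
#'   extreme temperatures; `K45` is solved so the curves intersect at
#'   `cross_aw`.
#' @return list with `spec`, `params` (Arrhenius GAB with dummies) and
#'   `cross_aw_achieved`, the numerically located crossing.
#' @export
make_crossing_scenario <- function(cross_aw, X_m = 0.102, C25 = 60,
                                   C45 = 25, K25 = 0.70) {
  if (!is_scalar_number(cross_aw) || cross_aw <= 0.6 || cross_aw >= 0.85)
    stop_sorb("cross_aw must lie in (0.6, 0.85), the adsorption range",
              "sorbfit_invalid_argument")
  fixed <- model_spec("GAB", temp_mode = "fixed")
  xe25 <- function(aw) evaluate_model(fixed, c(X_m = X_m, C = C25, K = K25), aw)
  f <- function(K45) {
    evaluate_model(fixed, c(X_m = X_m, C = C45, K = K45), cross_aw) -
      xe25(cross_aw)
  }
  hi <- 1 / 0.85 - 1e-3
  if (f(K25) >= 0 || f(hi) <= 0)
    stop_sorb("could not bracket a crossing for the requested anchors",
              "sorbfit_invalid_argument")
  K45 <- stats::uniroot(f, c(K25, hi), tol = 1e-12)$root
  ar <- linearize_arrhenius(temperatures_c = c(25, 45), C = c(C25, C45),
                            K = c(K25, K45))
  params <- c(X_m = X_m, ar, b_1 = -0.016, b_2 = 0.002)
  spec <- model_spec("GAB", temp_mode = "arrhenius", uses_dummies = TRUE)
  # verify: locate the sign change of the 45C - 25C difference on the grid
  g <- ddi_grid("adsorption", 0.01)
  d <- evaluate_model(spec, params, g, 45, d1 = 1, d2 = 1) -
       evaluate_model(spec, params, g, 25, d1 = 1, d2 = 1)
  sc <- which(diff(sign(d)) != 0)
  if (!length(sc))
    stop_sorb("constructed scenario shows no crossing on the adsorption grid",
              "sorbfit_invalid_argument")
  achieved <- (g[sc[1]] + g[sc[1] + 1]) / 2
  if (abs(achieved - cross_aw) > 0.05)
    stop_sorb(sprintf("crossing found at %.3f, more than 0.05 from requested %.3f",
                      achieved, cross_aw), "sorbfit_invalid_argument")
  list(spec = spec, params = params, cross_aw_achieved = achieved)
}

#' @export
print.isotherm_dataset <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("<isotherm_dataset> %d records (%s)%s\n", nrow(x),
              attr(x, "provenance") %||% "measured",
              if (!is.null(tr)) sprintf(", truth: %s", tr$spec$name) else ""))
  NextMethod()
}

# indicator encodings used throughout (D1 = semidry, D2 = adsorption)
dummies <- function(df) {
  list(d1 = as.numeric(df$method == "semidry"),
       d2 = as.numeric(df$branch == "adsorption"))
}
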