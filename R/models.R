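# Registry of the twelve conventional water sorption isotherm equations,
# with optional temperature parameterization (Arrhenius for GAB, linear in
# absolute temperature for the empirical coefficients) and additive
# dummy-variable covariates for postharvest method (d1 = semidry) and
# sorption branch (d2 = adsorption).

KELVIN0 <- 273.15

# defaults: latent heat of water vaporization near the design midpoint
# (35 C), kJ/kg, and the water-specific gas constant, kJ/(kg K)
DEFAULT_LAMBDA <- 2406
DEFAULT_RW <- 0.4615

#' Names of the supported conventional sorption models
#' @return character vector of the twelve model names.
#' @export
sorption_models <- function() {
  c("GAB", "Peleg", "Smith", "Kuhn", "DLP", "ChungPfost", "Caurie",
    "IglesiasChirife", "WhiteEiring", "Polynomial", "Oswin",
    "YanniotisBlahovec")
}

# base (fixed-temperature) parameter names per model
model_base_params <- function(name) {
  switch(name,
    GAB = c("X_m", "C", "K"),
    Peleg = c("a_0", "a_1", "a_2", "a_3"),
    Smith = c("a_1", "a_2"),
    Kuhn = c("a_1", "a_2"),
    DLP = c("a_0", "a_1", "a_2", "a_3"),
    ChungPfost = c("a_1", "a_2"),
    Caurie = c("a_1", "a_2"),
    IglesiasChirife = c("a_1", "a_2"),
    WhiteEiring = c("a_1", "a_2"),
    Polynomial = c("a_0", "a_1", "a_2", "a_3"),
    Oswin = c("a_1", "a_2"),
    YanniotisBlahovec = c("a_0", "a_1", "a_2", "a_3"),
    stop_sorb(sprintf("unknown model '%s'; valid models: %s", name,
                      paste(sorption_models(), collapse = ", ")),
              "sorbfit_unknown_model")
  )
}

#' Construct a sorption model specification
#'
#' @param name one of [sorption_models()].
#' @param temp_mode `"fixed"` (raw coefficients at a single temperature),
#'   `"linear"` (empirical coefficients `a_i = a_i1 * T_K + a_i2`, Kelvin
#'   slope), or `"arrhenius"` (GAB only: `C` and `K` follow Arrhenius laws
#'   in `C_0, K_0, H_m, H_n` with fixed `lambda`, `R_w`).
#' @param uses_dummies append additive offsets `b_1 * d1 + b_2 * d2` for
#'   the semidry-method and adsorption-branch indicators.
#' @param lambda latent heat of water vaporization, kJ/kg (Arrhenius mode).
#' @param R_w water-specific gas constant, kJ/(kg K) (Arrhenius mode).
#' @param dlp_reduced DLP only: drop the intercept of the `a_2(T)` line
#'   (slope-only temperature dependence) in linear mode.
#' @return an object of class `model_spec` with fields `name`,
#'   `temp_mode`, `uses_dummies`, `param_names`, `n_params`, `constants`.
#' @export
model_spec <- function(name,
                       temp_mode = c("fixed", "linear", "arrhenius"),
                       uses_dummies = FALSE,
                       lambda = DEFAULT_LAMBDA, R_w = DEFAULT_RW,
                       dlp_reduced = FALSE) {
  temp_mode <- match.arg(temp_mode)
  base <- model_base_params(name)
  if (temp_mode == "arrhenius" && name != "GAB")
    stop_sorb("Arrhenius temperature mode is defined for the GAB model only",
              "sorbfit_invalid_spec")
  if (temp_mode == "linear" && name == "GAB")
    stop_sorb("GAB uses temp_mode 'arrhenius' (or 'fixed'), not 'linear'",
              "sorbfit_invalid_spec")
  pn <- switch(temp_mode,
    fixed = base,
    arrhenius = c("X_m", "C_0", "K_0", "H_m", "H_n"),
    linear = as.vector(t(outer(base, c(".1", ".2"), paste0))))
  if (name == "DLP" && dlp_reduced && temp_mode == "linear")
    pn <- setdiff(pn, "a_2.2")
  if (uses_dummies) pn <- c(pn, "b_1", "b_2")
  structure(list(
    name = name, temp_mode = temp_mode, uses_dummies = uses_dummies,
    param_names = pn, n_params = length(pn),
    dlp_reduced = dlp_reduced,
    constants = list(lambda = lambda, R_w = R_w)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (temp_mode=%s%s)\n  parameters: %s\n",
              x$name, x$temp_mode,
              if (x$uses_dummies) ", dummies" else "",
              paste(x$param_names, collapse = ", ")))
  invisible(x)
}

#' GAB energy constant as a function of temperature (Arrhenius law)
#'
#' `C(T) = C_0 exp((H_m - H_n) / (R_w T_K))`.
#'
#' @param C_0 pre-exponential factor (dimensionless, > 0).
#' @param H_m,H_n monolayer and multilayer sorption heats, kJ/kg.
#' @param R_w water-specific gas constant, kJ/(kg K).
#' @param temperature_c temperature in Celsius.
#' @return C, dimensionless.
#' @export
gab_c_of_T <- function(C_0, H_m, H_n, R_w, temperature_c) {
  if (any(C_0 <= 0)) stop_sorb("C_0 must be positive", "sorbfit_invalid_params")
  C_0 * exp((H_m - H_n) / (R_w * (temperature_c + KELVIN0)))
}

#' GAB multilayer factor as a function of temperature (Arrhenius law)
#'
#' `K(T) = K_0 exp((lambda - H_n) / (R_w T_K))`.
#'
#' @param K_0 pre-exponential factor (dimensionless, > 0).
#' @param lambda latent heat of water vaporization, kJ/kg.
#' @param H_n multilayer sorption heat, kJ/kg.
#' @param R_w water-specific gas constant, kJ/(kg K).
#' @param temperature_c temperature in Celsius.
#' @return K, dimensionless.
#' @export
gab_k_of_T <- function(K_0, lambda, H_n, R_w, temperature_c) {
  if (any(K_0 <= 0)) stop_sorb("K_0 must be positive", "sorbfit_invalid_params")
  K_0 * exp((lambda - H_n) / (R_w * (temperature_c + KELVIN0)))
}

#' Linear temperature dependence of an empirical coefficient
#'
#' `a_i(T) = a_i1 * T_K + a_i2` with the temperature in Kelvin.
#'
#' @param a_i1 slope, 1/K.
#' @param a_i2 intercept, units of the coefficient.
#' @param temperature_c temperature in Celsius.
#' @return the coefficient value at that temperature.
#' @export
linear_param <- function(a_i1, a_i2, temperature_c) {
  a_i1 * (temperature_c + KELVIN0) + a_i2
}

# resolve base coefficients at given temperatures; returns a list of
# vectors (one per base coefficient), each recycled to length(n)
resolve_coeffs <- function(spec, params, temperature_c) {
  base <- model_base_params(spec$name)
  switch(spec$temp_mode,
    fixed = lapply(setNames(base, base), function(p) rep(params[[p]], length.out = max(1, length(temperature_c)))),
    linear = lapply(setNames(base, base), function(p) {
      sl <- params[[paste0(p, ".1")]]
      ic <- if (paste0(p, ".2") %in% names(params)) params[[paste0(p, ".2")]] else 0
      linear_param(sl, ic, temperature_c)
    }),
    arrhenius = {
      if (is.null(temperature_c))
        stop_sorb("temperature required for Arrhenius-mode GAB", "sorbfit_invalid_params")
      list(
        X_m = rep(params[["X_m"]], length.out = length(temperature_c)),
        C = gab_c_of_T(params[["C_0"]], params[["H_m"]], params[["H_n"]],
                       spec$constants$R_w, temperature_c),
        K = gab_k_of_T(params[["K_0"]], spec$constants$lambda, params[["H_n"]],
                       spec$constants$R_w, temperature_c)
      )
    })
}

# closed-form model equations on resolved coefficients; domain violations
# raise a sorbfit_domain_error (never silently clamped)
eval_base <- function(name, cf, aw) {
  dom <- function(ok, what) {
    if (!all(ok)) stop_sorb(sprintf("%s model evaluation-domain error: %s",
                                    name, what), "sorbfit_domain_error")
  }
  switch(name,
    GAB = {
      kaw <- cf$K * aw
      dom(cf$C > 0, "C must be positive")
      dom(kaw > 0 & kaw < 1, "K*aw must lie in (0, 1)")
      den2 <- 1 + (cf$C - 1) * kaw
      dom(den2 > 0, "1 + (C-1)*K*aw must be positive")
      cf$X_m * cf$C * kaw / ((1 - kaw) * den2)
    },
    Peleg = cf$a_0 * aw^cf$a_1 + cf$a_2 * aw^cf$a_3,
    Smith = cf$a_1 - cf$a_2 * log(1 - aw),
    Kuhn = cf$a_1 / log(aw) + cf$a_2,
    DLP = {
      x <- log(-log(aw))
      cf$a_0 + cf$a_1 * x + cf$a_2 * x^2 + cf$a_3 * x^3
    },
    ChungPfost = cf$a_1 - cf$a_2 * log(-log(aw)),
    Caurie = exp(cf$a_1 + cf$a_2 * aw),
    IglesiasChirife = cf$a_1 + cf$a_2 * (aw / (1 - aw)),
    WhiteEiring = {
      den <- cf$a_1 + cf$a_2 * aw
      dom(den > 0, "a_1 + a_2*aw must be positive")
      1 / den
    },
    Polynomial = cf$a_0 + cf$a_1 * aw + cf$a_2 * aw^2 + cf$a_3 * aw^3,
    Oswin = cf$a_1 * (aw / (1 - aw))^cf$a_2,
    YanniotisBlahovec = {
      d1 <- cf$a_0 + cf$a_1 * aw
      d2 <- cf$a_2 + cf$a_3 * aw
      dom(d1 != 0 & d2 != 0, "denominators must be nonzero")
      aw / d1 + aw / d2
    })
}

#' Evaluate a sorption model
#'
#' Computes the equilibrium moisture content `X_e` (decimal dry basis)
#' predicted by a conventional isotherm model, including the additive
#' dummy-variable offsets `b_1 d1 + b_2 d2` when the specification carries
#' them. Vectorized over `aw`, `temperature_c`, `d1`, `d2`.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector (or list) holding `spec$param_names`.
#' @param aw water activity, in the open interval (0, 1).
#' @param temperature_c temperature in Celsius (required unless
#'   `temp_mode = "fixed"`).
#' @param d1 indicator: 1 = semidry postharvest method, 0 = wet.
#' @param d2 indicator: 1 = adsorption branch, 0 = desorption.
#' @return predicted `X_e`, decimal dry basis.
#' @export
evaluate_model <- function(spec, params, aw, temperature_c = NULL,
                           d1 = 0, d2 = 0) {
  stopifnot(inherits(spec, "model_spec"))
  params <- as.list(params)
  missing <- setdiff(spec$param_names, names(params))
  if (length(missing))
    stop_sorb(sprintf("missing parameters: %s", paste(missing, collapse = ", ")),
              "sorbfit_invalid_params")
  if (any(!is.finite(aw)) || any(aw <= 0) || any(aw >= 1))
    stop_sorb("aw must lie strictly in (0, 1)", "sorbfit_domain_error")
  n <- max(length(aw), length(temperature_c), length(d1), length(d2))
  aw <- rep(aw, length.out = n)
  d1 <- rep(d1, length.out = n)
  d2 <- rep(d2, length.out = n)
  tc <- if (is.null(temperature_c)) NULL else rep(temperature_c, length.out = n)
  if (spec$temp_mode != "fixed" && is.null(tc))
    stop_sorb("temperature_c required for temperature-parameterized models",
              "sorbfit_invalid_params")
  cf <- resolve_coeffs(spec, params, tc)
  xe <- eval_base(spec$name, cf, aw)
  if (spec$uses_dummies)
    xe <- xe + params[["b_1"]] * d1 + params[["b_2"]] * d2
  if (any(!is.finite(xe)))
    stop_sorb(sprintf("%s evaluation produced non-finite X_e", spec$name),
              "sorbfit_domain_error")
  xe
}

# default parameter bounds for GA initialization, on the fixed-temperature
# parameterization (generous; configurable by callers)
default_bounds <- function(spec) {
  wide <- function(p, lo, hi) list(lower = setNames(lo, p), upper = setNames(hi, p))
  base <- model_base_params(spec$name)
  b <- switch(spec$name,
    GAB = list(lower = c(X_m = 1e-3, C = 0.1, K = 0.01),
               upper = c(X_m = 1, C = 1000, K = 0.999)),
    WhiteEiring = wide(base, rep(-100, length(base)), rep(100, length(base))),
    YanniotisBlahovec = wide(base, rep(-50, length(base)), rep(50, length(base))),
    Peleg = list(lower = c(a_0 = 0, a_1 = 0.01, a_2 = 0, a_3 = 0.01),
                 upper = c(a_0 = 2, a_1 = 20, a_2 = 2, a_3 = 20)),
    wide(base, rep(-5, length(base)), rep(5, length(base))))
  if (spec$uses_dummies) {
    b$lower <- c(b$lower, b_1 = -0.2, b_2 = -0.2)
    b$upper <- c(b$upper, b_1 = 0.2, b_2 = 0.2)
  }
  b
}
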