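# Nonlinear least-squares estimation of sorption-model parameters by
# minimizing the residual mean square RMS = sum((y_exp - y_cal)^2) / N,
# with genetic-algorithm or quadratic-rearrangement initialization, an
# in-package Levenberg-Marquardt optimizer, asymptotic 95% confidence
# intervals, and the staged (per-temperature -> Arrhenius/linear linkage
# -> dummy refit) global strategy.

#' Residual mean square
#' @param y_exp,y_cal observed and predicted values.
#' @return `sum((y_exp - y_cal)^2) / N`.
#' @export
rms <- function(y_exp, y_cal) {
  stopifnot(length(y_exp) == length(y_cal))
  mean((y_exp - y_cal)^2)
}

# --- parameter transforms for optimizer conditioning ---------------------
# Arrhenius GAB pre-exponentials are strictly positive and span many
# decades; they are optimized on the log scale. Everything else is raw.
param_transform <- function(spec) {
  logged <- if (spec$temp_mode == "arrhenius") c("C_0", "K_0") else character(0)
  list(
    to = function(p) { p[logged] <- log(p[logged]); p },
    from = function(p) { p[logged] <- exp(p[logged]); p }
  )
}

# residual function factory: returns f(params) = xe - model(params), in
# canonical record order; domain violations yield NA residuals
residual_fun <- function(spec, data, free = spec$param_names,
                         fixed = NULL) {
  data <- canonical_order(data)
  dm <- dummies(data)
  function(theta) {
    p <- c(setNames(as.numeric(theta), free), fixed)
    r <- tryCatch(
      data$xe - evaluate_model(spec, p, data$aw, data$temperature_c,
                               dm$d1, dm$d2),
      sorbfit_domain_error = function(e) rep(NA_real_, nrow(data)),
      sorbfit_invalid_params = function(e) rep(NA_real_, nrow(data)))
    r
  }
}

num_jacobian <- function(f, theta, r0 = NULL) {
  p <- length(theta)
  if (is.null(r0)) r0 <- f(theta)
  J <- matrix(NA_real_, length(r0), p)
  for (j in seq_len(p)) {
    h <- 6e-6 * max(abs(theta[j]), 1e-6)
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    rp <- f(tp); rm <- f(tm)
    if (all(is.finite(rp)) && all(is.finite(rm))) {
      J[, j] <- (rp - rm) / (2 * h)
    } else if (all(is.finite(rp))) {
      J[, j] <- (rp - r0) / h
    } else if (all(is.finite(rm))) {
      J[, j] <- (r0 - rm) / h
    } else {
      stop_sorb("Jacobian evaluation failed: parameter perturbations leave the evaluation domain",
                "sorbfit_fit_error")
    }
  }
  J
}

# Levenberg-Marquardt with Marquardt diagonal scaling; only improving
# steps are accepted, so the descent property holds by construction.
lm_minimize <- function(rfun, theta0, tol = 1e-10, max_iter = 2000) {
  r <- rfun(theta0)
  if (any(!is.finite(r)))
    stop_sorb("initial parameters violate the model evaluation domain",
              "sorbfit_fit_error")
  theta <- theta0
  sse <- sum(r^2)
  damp <- 1e-3
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J <- num_jacobian(rfun, theta, r)
    g <- -crossprod(J, r)           # -(1/2) gradient of SSE
    A <- crossprod(J)
    dscale <- pmax(diag(A), 1e-12)
    accepted <- FALSE
    for (inner in 1:60) {
      H <- A + damp * diag(dscale, nrow = length(theta))
      delta <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        rc <- rfun(cand)
        if (all(is.finite(rc)) && sum(rc^2) < sse) {
          step_rel <- max(abs(delta) / pmax(abs(theta), 1))
          improve <- sse - sum(rc^2)
          theta <- cand; r <- rc; sse <- sum(rc^2)
          damp <- max(damp / 3, 1e-12)
          accepted <- TRUE
          if (improve <= tol * (sse + tol) || step_rel < tol) converged <- TRUE
          break
        }
      }
      damp <- damp * 5
      if (damp > 1e14) break
    }
    if (!accepted) { converged <- TRUE; break }  # no improving step exists
    if (converged) break
  }
  list(theta = theta, sse = sse, iterations = it, converged = converged)
}

#' GAB starting values from the quadratic rearrangement
#'
#' Rearranges the GAB equation into
#' `aw/xe = 1/(X_m C K) + (C-2)/(X_m C) aw + K(1-C)/(X_m C) aw^2`,
#' fits the quadratic by ordinary least squares and inverts algebraically
#' for `(X_m, C, K)`.
#'
#' @param data a data.frame with columns `aw` and `xe` (one temperature),
#'   or pass `aw` and `xe` vectors directly.
#' @param aw,xe optional explicit vectors overriding `data`.
#' @return named vector `c(X_m, C, K)`.
#' @export
init_gab_quadratic <- function(data = NULL, aw = data$aw, xe = data$xe) {
  if (length(unique(aw)) < 3)
    stop_sorb("initialization requires at least 3 distinct aw values",
              "sorbfit_init_error")
  if (any(xe <= 0))
    stop_sorb("all xe must be positive", "sorbfit_init_error")
  b <- coef(lm(I(aw / xe) ~ aw + I(aw^2)))
  if (any(!is.finite(b)) || abs(b[1]) < .Machine$double.eps)
    stop_sorb("quadratic rearrangement is degenerate", "sorbfit_init_error")
  r1 <- b[[2]] / b[[1]]             # (C-2) K
  r2 <- b[[3]] / b[[1]]             # K^2 (1-C)
  disc <- r1^2 - 4 * r2
  if (disc < 0)
    stop_sorb("complex roots in the GAB quadratic inversion",
              "sorbfit_init_error")
  Ks <- (-r1 + c(1, -1) * sqrt(disc)) / 2
  cand <- list()
  for (K in Ks) {
    if (!is.finite(K) || K <= 0) next
    C <- r1 / K + 2
    if (C <= 0) next
    X_m <- 1 / (b[[1]] * C * K)
    if (X_m <= 0) next
    cand[[length(cand) + 1]] <- c(X_m = X_m, C = C, K = K)
  }
  if (!length(cand))
    stop_sorb("no admissible (X_m, C, K) root", "sorbfit_init_error")
  if (length(cand) > 1) {
    spec <- model_spec("GAB", temp_mode = "fixed")
    sse <- vapply(cand, function(p) {
      pr <- tryCatch(evaluate_model(spec, p, aw), error = function(e) NULL)
      if (is.null(pr)) Inf else sum((xe - pr)^2)
    }, numeric(1))
    cand <- cand[which.min(sse)]
  }
  cand[[1]]
}

#' Genetic-algorithm configuration
#' @param pop_size population size (>= 2).
#' @param generations number of generations.
#' @param seed integer seed (mandatory: GA runs are reproducible).
#' @param p_mutate per-gene mutation probability.
#' @param elite number of elite individuals copied unchanged.
#' @return a `ga_config` object.
#' @export
ga_config <- function(pop_size = 60, generations = 150, seed,
                      p_mutate = 0.15, elite = 2) {
  stopifnot(pop_size >= 2, generations >= 1)
  if (missing(seed)) stop_sorb("ga_config requires a seed", "sorbfit_invalid_config")
  structure(list(pop_size = pop_size, generations = generations,
                 seed = as.integer(seed), p_mutate = p_mutate,
                 elite = elite), class = "ga_config")
}

#' Genetic-algorithm initialization of model parameters
#'
#' Real-coded GA (tournament selection, blend crossover, Gaussian
#' mutation, elitism) minimizing the RMS; returns the elite individual.
#' Deterministic given the config seed.
#'
#' @param spec a [model_spec()].
#' @param data sorption records (`aw`, `temperature_c`, `method`,
#'   `branch`, `xe`).
#' @param bounds list with named numeric vectors `lower`, `upper` covering
#'   every free parameter; default [default_bounds()] (fixed-T mode).
#' @param config a [ga_config()].
#' @return named parameter vector (the best individual found).
#' @export
ga_initialize <- function(spec, data, bounds = default_bounds(spec), config) {
  stopifnot(inherits(config, "ga_config"))
  pn <- spec$param_names
  lo <- bounds$lower[pn]; hi <- bounds$upper[pn]
  if (any(is.na(lo)) || any(is.na(hi)) || any(!is.finite(c(lo, hi))))
    stop_sorb("finite bounds required for every free parameter",
              "sorbfit_bounds_error")
  if (any(hi < lo)) stop_sorb("upper bounds below lower bounds",
                              "sorbfit_bounds_error")
  rfun <- residual_fun(spec, data)
  fitness <- function(theta) {
    r <- rfun(theta)
    if (any(!is.finite(r))) Inf else mean(r^2)
  }
  p <- length(pn); rng <- hi - lo
  withr::with_seed(config$seed, {
    pop <- t(replicate(config$pop_size, lo + runif(p) * rng))
    if (p == 1) pop <- matrix(pop, ncol = 1)
    fit <- apply(pop, 1, fitness)
    if (all(!is.finite(fit)))
      stop_sorb("entire initial population infeasible: check bounds",
                "sorbfit_bounds_error")
    for (gen in seq_len(config$generations)) {
      ord <- order(fit)
      nkeep <- min(config$elite, config$pop_size)
      newpop <- pop[ord[seq_len(nkeep)], , drop = FALSE]
      while (nrow(newpop) < config$pop_size) {
        pick <- function() {
          ij <- sample.int(config$pop_size, 2)
          ij[which.min(fit[ij])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        u <- runif(p, -0.25, 1.25)
        child <- u * p1 + (1 - u) * p2
        mut <- runif(p) < config$p_mutate
        child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.1 * rng[mut])
        child <- pmin(pmax(child, lo), hi)
        newpop <- rbind(newpop, child)
      }
      pop <- newpop
      fit <- apply(pop, 1, fitness)
    }
    best <- pop[which.min(fit), ]
    setNames(as.numeric(best), pn)
  })
}

#' Fit a sorption model by nonlinear ordinary least squares
#'
#' Minimizes the residual mean square with a Levenberg-Marquardt local
#' search from `init`. Residuals are stored in the canonical record order
#' (method, branch, temperature, ascending aw).
#'
#' @param spec a [model_spec()].
#' @param data sorption records.
#' @param init named starting parameter vector covering
#'   `spec$param_names`; must be inside the evaluation domain.
#' @param tol step/objective relative tolerance.
#' @param max_iter maximum outer iterations.
#' @return a `fit_result`: list with `spec`, `params`, `rms`, `n_obs`,
#'   `converged`, `residuals`, `iterations`, `data`.
#' @export
fit_ols <- function(spec, data, init, tol = 1e-10, max_iter = 2000) {
  if (!nrow(data)) stop_sorb("empty dataset", "sorbfit_fit_error")
  init <- unlist(init)[spec$param_names]
  if (any(is.na(init)))
    stop_sorb("init must name every free parameter", "sorbfit_fit_error")
  data <- canonical_order(as.data.frame(data))
  tr <- param_transform(spec)
  rfun_orig <- residual_fun(spec, data)
  r0 <- rfun_orig(init)
  if (any(!is.finite(r0)))
    stop_sorb("init lies outside the model evaluation domain",
              "sorbfit_fit_error")
  rfun <- function(th) rfun_orig(tr$from(setNames(th, spec$param_names)))
  opt <- lm_minimize(rfun, tr$to(init), tol = tol, max_iter = max_iter)
  params <- tr$from(setNames(opt$theta, spec$param_names))
  res <- rfun_orig(params)
  structure(list(
    spec = spec, params = params, rms = opt$sse / nrow(data),
    n_obs = nrow(data), converged = opt$converged,
    residuals = res, iterations = opt$iterations, data = data,
    strategy = "local"
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: RMS = %.4g on %d records (%s, %d iter)\n",
              x$spec$name, x$rms, x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(signif(x$params, 5))
  invisible(x)
}

#' Linearized Arrhenius estimation of the GAB temperature parameters
#'
#' Ordinary least squares of `ln C` and `ln K` on `1/T_K`:
#' the `ln C` line gives `ln C_0` (intercept) and `(H_m - H_n)/R_w`
#' (slope); the `ln K` line gives `ln K_0` and `(lambda - H_n)/R_w`.
#'
#' @param temperatures_c at least two distinct temperatures, Celsius.
#' @param C,K per-temperature GAB estimates (positive).
#' @param lambda latent heat of water vaporization, kJ/kg.
#' @param R_w water-specific gas constant, kJ/(kg K).
#' @return named vector `c(C_0, K_0, H_m, H_n)`.
#' @export
linearize_arrhenius <- function(temperatures_c, C, K,
                                lambda = DEFAULT_LAMBDA, R_w = DEFAULT_RW) {
  if (length(unique(temperatures_c)) < 2)
    stop_sorb("need at least two distinct temperatures", "sorbfit_fit_error")
  if (any(C <= 0) || any(K <= 0))
    stop_sorb("C and K must be positive for log-linearization",
              "sorbfit_fit_error")
  invT <- 1 / (temperatures_c + KELVIN0)
  fc <- coef(lm(log(C) ~ invT))
  fk <- coef(lm(log(K) ~ invT))
  H_n <- lambda - fk[[2]] * R_w
  H_m <- H_n + fc[[2]] * R_w
  c(C_0 = exp(fc[[1]]), K_0 = exp(fk[[1]]), H_m = H_m, H_n = H_n)
}

#' Asymptotic confidence intervals for a converged fit
#'
#' Standard nonlinear-regression intervals: residual variance
#' `SSE/(N - M)` combined with the Jacobian at the optimum, Student-t
#' quantile, symmetric about the estimates.
#'
#' @param fit a `fit_result` from [fit_ols()] or [fit_global()].
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `parameter, estimate, se, lower, upper`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged)
    stop_sorb("confidence intervals require a converged fit",
              "sorbfit_fit_error")
  pn <- fit$spec$param_names
  rfun <- residual_fun(fit$spec, fit$data)
  J <- -num_jacobian(function(th) rfun(setNames(th, pn)),
                     fit$params, fit$residuals)
  qrJ <- qr(scale(J, center = FALSE))
  if (qrJ$rank < length(pn))
    stop_sorb("rank-deficient Jacobian: parameters not identifiable",
              "sorbfit_nonidentifiable")
  N <- fit$n_obs; M <- length(pn)
  if (N <= M) stop_sorb("more parameters than observations",
                        "sorbfit_fit_error")
  s <- sqrt(colSums(J^2))
  Js <- sweep(J, 2, s, "/")
  A <- crossprod(Js)
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
    stop_sorb("rank-deficient Jacobian: parameters not identifiable",
              "sorbfit_nonidentifiable"))
  sigma2 <- sum(fit$residuals^2) / (N - M)
  se <- sqrt(sigma2 * diag(Ainv)) / s
  tq <- qt(1 - (1 - level) / 2, df = N - M)
  data.frame(parameter = pn, estimate = as.numeric(fit$params),
             se = se, lower = as.numeric(fit$params) - tq * se,
             upper = as.numeric(fit$params) + tq * se,
             row.names = NULL)
}

# staged initialization mirroring the narrative procedure: fit each
# temperature on the reference cell (wet / desorption), link coefficients
# across temperature, then estimate the dummy offsets
sequential_init <- function(spec, data, seed = 1L, ga = NULL) {
  # reference = wet method, both branches: covers the full aw range so the
  # per-temperature coefficients do not extrapolate (the small b_2 branch
  # offset is absorbed by the later dummy-only refit)
  ref_method <- if (any(data$method == "wet")) "wet" else data$method[1]
  ref <- data[data$method == ref_method, , drop = FALSE]
  if (!nrow(ref)) ref <- data
  temps <- sort(unique(ref$temperature_c))
  fx <- model_spec(spec$name, temp_mode = "fixed")
  # warm-start each temperature from the previous one so the per-T
  # coefficient paths stay in one basin and the linkage is smooth in T
  perT <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    sub <- ref[ref$temperature_c == temps[i], , drop = FALSE]
    init0 <- if (spec$name == "GAB") {
      init_gab_quadratic(sub)
    } else if (i > 1) {
      perT[[i - 1]]
    } else {
      cfg <- ga %||% ga_config(pop_size = 40, generations = 60,
                               seed = child_seed(seed, paste0("ga", temps[i])))
      ga_initialize(fx, sub, default_bounds(fx), cfg)
    }
    perT[[i]] <- fit_ols(fx, sub, init0)$params
  }
  mat <- do.call(rbind, perT)
  TK <- temps + KELVIN0
  if (spec$temp_mode == "arrhenius") {
    ar <- linearize_arrhenius(temps, C = mat[, "C"], K = mat[, "K"])
    p <- c(X_m = mean(mat[, "X_m"]), ar)
  } else if (spec$temp_mode == "linear") {
    p <- numeric(0)
    for (cn in colnames(mat)) {
      if (paste0(cn, ".2") %in% spec$param_names) {
        co <- coef(lm(mat[, cn] ~ TK))
        p[paste0(cn, ".1")] <- co[[2]]; p[paste0(cn, ".2")] <- co[[1]]
      } else {                                  # slope-only (reduced DLP)
        co <- coef(lm(mat[, cn] ~ TK - 1))
        p[paste0(cn, ".1")] <- co[[1]]
      }
    }
  } else {
    p <- colMeans(mat)
  }
  if (spec$uses_dummies) {
    rf <- residual_fun(spec, data, free = c("b_1", "b_2"), fixed = p)
    bfit <- lm_minimize(rf, c(b_1 = 0, b_2 = 0))
    p <- c(p, setNames(bfit$theta, c("b_1", "b_2")))
  }
  p[spec$param_names]
}

#' Global fit across temperatures, methods and branches
#'
#' Fits the temperature-parameterized model plus the dummy offsets
#' `b_1` (semidry) and `b_2` (adsorption) by RMS minimization. Strategy
#' `"joint"` (default) optimizes all free parameters together from a
#' staged starting point; `"sequential"` stops after the staged procedure
#' (per-temperature fits, Arrhenius/linear linkage, dummy-only refit).
#'
#' @param spec a temperature-parameterized [model_spec()] (typically with
#'   `uses_dummies = TRUE`).
#' @param data sorption records spanning every dummy level used.
#' @param strategy `"joint"` or `"sequential"`.
#' @param init optional named starting vector (skips staged
#'   initialization).
#' @param seed seed for GA-based stages.
#' @param ga optional [ga_config()] override for staged GA stages.
#' @param tol,max_iter passed to [fit_ols()].
#' @return a `fit_result` (with `strategy` recorded).
#' @export
fit_global <- function(spec, data, strategy = c("joint", "sequential"),
                       init = NULL, seed = 1L, ga = NULL,
                       tol = 1e-10, max_iter = 2000) {
  strategy <- match.arg(strategy)
  data <- as.data.frame(data)
  if (spec$uses_dummies) {
    if (!any(data$method == "semidry") || !any(data$method == "wet"))
      stop_sorb(paste0("b_1 unidentifiable: postharvest level '",
                       if (any(data$method == "wet")) "semidry" else "wet",
                       "' absent from the data"), "sorbfit_nonidentifiable")
    if (!any(data$branch == "adsorption") || !any(data$branch == "desorption"))
      stop_sorb(paste0("b_2 unidentifiable: branch level '",
                       if (any(data$branch == "desorption")) "adsorption" else "desorption",
                       "' absent from the data"), "sorbfit_nonidentifiable")
  }
  start <- if (!is.null(init)) unlist(init)[spec$param_names] else
    sequential_init(spec, data, seed = seed, ga = ga)
  if (strategy == "sequential" && is.null(init)) {
    data_c <- canonical_order(data)
    rfun <- residual_fun(spec, data_c)
    res <- rfun(start)
    out <- structure(list(
      spec = spec, params = start, rms = mean(res^2), n_obs = nrow(data_c),
      converged = all(is.finite(res)), residuals = res, iterations = 0L,
      data = data_c, strategy = "sequential"), class = "fit_result")
    return(out)
  }
  fit <- fit_ols(spec, data, start, tol = tol, max_iter = max_iter)
  fit$strategy <- strategy
  fit
}
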