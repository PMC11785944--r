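# Initialization strategies, the least-squares engine, Arrhenius
# linearization, confidence intervals, and the global (dummy-augmented)
# fit.

test_that("init_gab_quadratic inverts noise-free GAB data exactly", {
  g <- ddi_grid("desorption")
  spec <- model_spec("GAB", temp_mode = "fixed")
  truth <- c(X_m = 0.102, C = 15, K = 0.75)
  est <- init_gab_quadratic(aw = g, xe = evaluate_model(spec, truth, g))
  expect_equal(est, truth, tolerance = 1e-6)
  # C = 2 kills the linear coefficient of the rearrangement; still inverts
  t2 <- c(X_m = 0.1, C = 2, K = 0.7)
  est2 <- init_gab_quadratic(aw = g, xe = evaluate_model(spec, t2, g))
  expect_equal(est2, t2, tolerance = 1e-6)
  expect_error(init_gab_quadratic(aw = c(0.2, 0.4), xe = c(0.08, 0.1)),
               class = "sorbfit_init_error")
  expect_error(init_gab_quadratic(aw = c(0.2, 0.4, 0.6), xe = c(0.08, -0.1, 0.2)),
               class = "sorbfit_init_error")
})

test_that("the genetic algorithm honors its contracts", {
  d <- smoke_dataset("Oswin")
  spec <- model_spec("Oswin", temp_mode = "fixed")
  # degenerate search space collapses to that point
  pt <- list(lower = c(a_1 = 0.12, a_2 = 0.35), upper = c(a_1 = 0.12, a_2 = 0.35))
  expect_equal(ga_initialize(spec, d, pt, ga_config(pop_size = 10,
                                                    generations = 3, seed = 1)),
               c(a_1 = 0.12, a_2 = 0.35))
  # determinism
  cfg <- ga_config(pop_size = 20, generations = 10, seed = 7)
  expect_identical(ga_initialize(spec, d, config = cfg),
                   ga_initialize(spec, d, config = cfg))
  # all-infeasible population: GAB bounds forcing K*aw >= 1
  gab <- model_spec("GAB", temp_mode = "fixed")
  dg <- smoke_dataset("GAB", branch = "adsorption")
  badb <- list(lower = c(X_m = 0.1, C = 5, K = 2), upper = c(X_m = 0.2, C = 10, K = 3))
  expect_error(ga_initialize(gab, dg, badb, cfg), class = "sorbfit_bounds_error")
  expect_error(ga_config(pop_size = 10, generations = 5),
               class = "sorbfit_invalid_config")
  # GA followed by local least squares nails noise-free Oswin
  start <- ga_initialize(spec, d, config = ga_config(seed = 3))
  expect_lt(fit_ols(spec, d, start)$rms, 1e-8)
})

test_that("fit_ols sits still at a zero-residual fixed point and rejects bad inits", {
  d <- smoke_dataset("GAB")
  spec <- model_spec("GAB", temp_mode = "fixed")
  truth <- smoke_truth("GAB")
  fit <- fit_ols(spec, d, truth)
  expect_lt(fit$rms, 1e-12)
  expect_equal(fit$params, truth, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_error(fit_ols(spec, d, c(X_m = 0.1, C = 10, K = 2)),
               class = "sorbfit_fit_error")
  expect_error(fit_ols(spec, d[0, ], truth), class = "sorbfit_fit_error")
})

test_that("fitted RMS matches the noise variance on correctly specified data", {
  sdn <- 0.002
  d <- generate_isotherm(noise = noise_model(sd = sdn), seed = 31)
  tr <- attr(d, "truth")
  fit <- fit_global(tr$spec, d, seed = 1)
  # mean squared residual ~ sd^2 within 3 standard errors of the chi^2 mean
  se <- sdn^2 * sqrt(2 / fit$n_obs)
  expect_lt(abs(fit$rms - sdn^2), 3 * se + sdn^2 * 7 / fit$n_obs)
})

test_that("descent: returned RMS never exceeds the RMS at the init", {
  set.seed(404)
  for (name in c("Oswin", "Smith", "Caurie", "GAB")) {
    spec <- model_spec(name, temp_mode = "fixed")
    truth <- smoke_truth(name)
    d <- smoke_dataset(name)
    d$xe <- d$xe + rnorm(nrow(d), 0, 0.003)
    init <- truth * runif(length(truth), 0.8, 1.2)
    pred0 <- evaluate_model(spec, init, d$aw)
    fit <- fit_ols(spec, d, init)
    expect_lte(fit$rms, rms(d$xe, pred0) + 1e-15)
  }
})

test_that("linearize_arrhenius inverts exactly and round-trips", {
  tt <- c(25, 35, 45)
  truth <- c(C_0 = 1.4e-8, K_0 = 10.5, H_m = 6099, H_n = 2895)
  Cv <- gab_c_of_T(truth["C_0"], truth["H_m"], truth["H_n"], 0.4615, tt)
  Kv <- gab_k_of_T(truth["K_0"], 2406, truth["H_n"], 0.4615, tt)
  est <- linearize_arrhenius(tt, Cv, Kv)
  expect_equal(est, truth, tolerance = 1e-9)
  # round trip: re-evaluating at the three temperatures reproduces inputs
  expect_equal(gab_c_of_T(est[["C_0"]], est[["H_m"]], est[["H_n"]], 0.4615, tt),
               as.numeric(Cv), tolerance = 1e-9)
  expect_equal(gab_k_of_T(est[["K_0"]], 2406, est[["H_n"]], 0.4615, tt),
               as.numeric(Kv), tolerance = 1e-9)
  # H_m = H_n truth gives a flat ln C line
  Cc <- gab_c_of_T(3, 500, 500, 0.4615, tt)
  est2 <- linearize_arrhenius(tt, Cc, Kv)
  expect_equal(est2[["H_m"]], est2[["H_n"]], tolerance = 1e-9)
  expect_error(linearize_arrhenius(25, 3, 0.7), class = "sorbfit_fit_error")
  expect_error(linearize_arrhenius(tt, c(-1, 2, 3), Kv),
               class = "sorbfit_fit_error")
})

test_that("confidence intervals shrink to zero width on noise-free fits", {
  d <- smoke_dataset("Oswin")
  spec <- model_spec("Oswin", temp_mode = "fixed")
  fit <- fit_ols(spec, d, smoke_truth("Oswin") * 1.05)
  ci <- confidence_intervals(fit)
  expect_lt(max(ci$upper - ci$lower), 1e-6)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
})

test_that("collinear parameterizations are reported as non-identifiable", {
  # a single aw value makes Smith's two coefficients collinear
  spec <- model_spec("Smith", temp_mode = "fixed")
  d <- data.frame(aw = rep(0.4, 12), temperature_c = 25, method = "wet",
                  branch = "desorption", replicate = 1:12,
                  xe = 0.1 + rnorm(12, 0, 1e-4))
  fit <- fit_ols(spec, d, c(a_1 = 0.05, a_2 = 0.1))
  expect_error(confidence_intervals(fit), class = "sorbfit_nonidentifiable")
})

test_that("fit_ols beats a brute-force lattice on Oswin", {
  set.seed(405)
  d <- smoke_dataset("Oswin")
  d$xe <- d$xe + rnorm(nrow(d), 0, 0.002)
  spec <- model_spec("Oswin", temp_mode = "fixed")
  a1g <- seq(0.05, 0.30, length.out = 200)
  a2g <- seq(0.05, 0.80, length.out = 200)
  q <- d$aw / (1 - d$aw)
  best <- Inf
  for (a2 in a2g) {
    qa <- q^a2
    sse <- vapply(a1g, function(a1) sum((d$xe - a1 * qa)^2), numeric(1))
    best <- min(best, min(sse))
  }
  fit <- fit_ols(spec, d, c(a_1 = 0.1, a_2 = 0.4))
  expect_lte(fit$rms * nrow(d), best + 1e-12)
})

test_that("all twelve models recover their own noise-free data", {
  for (name in sorption_models()) {
    spec <- model_spec(name, temp_mode = "fixed")
    truth <- smoke_truth(name)
    d <- smoke_dataset(name)
    init <- truth * 1.1 + ifelse(truth == 0, 0.01, 0)
    fit <- fit_ols(spec, d, init)
    expect_lt(fit$rms, 1e-10)
    expect_lt(max(abs(fit$params - truth) / pmax(1, abs(truth))), 1e-4)
  }
})

test_that("fit_global needs both levels of each dummy factor", {
  d <- generate_isotherm(seed = 5)
  spec <- attr(d, "truth")$spec
  wetdes <- d[d$method == "wet" & d$branch == "desorption", ]
  expect_error(fit_global(spec, wetdes), class = "sorbfit_nonidentifiable")
  expect_error(fit_global(spec, d[d$branch == "desorption", ]),
               class = "sorbfit_nonidentifiable",
               regexp = "adsorption")
})

test_that("fit_global recovers the dummy offsets from noisy data", {
  d <- generate_isotherm(seed = 17)
  tr <- attr(d, "truth")
  fit <- fit_global(tr$spec, d, seed = 2)
  ci <- confidence_intervals(fit)
  for (p in c("b_1", "b_2")) {
    i <- match(p, ci$parameter)
    expect_lt(abs(ci$estimate[i] - tr$params[[p]]),
              0.25 * abs(tr$params[[p]]) + 1e-3)
    expect_true(ci$lower[i] <= tr$params[[p]] &&
                  tr$params[[p]] <= ci$upper[i])
  }
  # zero-offset truths are recovered as statistically zero
  tr0 <- tr; tr0$params[c("b_1", "b_2")] <- 0
  d0 <- generate_isotherm(tr0$spec, tr0$params, seed = 18)
  ci0 <- confidence_intervals(fit_global(tr0$spec, d0, seed = 2))
  for (p in c("b_1", "b_2")) {
    i <- match(p, ci0$parameter)
    expect_true(ci0$lower[i] <= 0 && 0 <= ci0$upper[i])
  }
})

test_that("sequential strategy agrees with joint on a well-specified truth", {
  d <- generate_isotherm(seed = 23)
  spec <- attr(d, "truth")$spec
  sq <- fit_global(spec, d, strategy = "sequential", seed = 3)
  jt <- fit_global(spec, d, strategy = "joint", seed = 3)
  expect_identical(sq$strategy, "sequential")
  expect_lte(jt$rms, sq$rms + 1e-15)    # joint refines the staged solution
  expect_lt(sq$rms, 4 * jt$rms)         # but the staged fit is already close
})
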