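# Split protocol, metric formulas, residual diagnostics, ANOVA/LSD
# ranking, and the end-to-end pipeline.

test_that("make_splits honors sizes, determinism, and stratification", {
  p <- make_splits(100, n_iterations = 5, train_fraction = 0.75, seed = 1,
                   stratify = FALSE)
  expect_true(all(lengths(p$train) == 75))
  expect_true(all(lengths(p$validation) == 25))
  for (i in 1:5)
    expect_setequal(c(p$train[[i]], p$validation[[i]]), 1:100)
  expect_identical(make_splits(100, 5, 0.75, seed = 1, stratify = FALSE), p)
  expect_false(identical(make_splits(100, 5, 0.75, seed = 2,
                                     stratify = FALSE), p))
  # stratified plans keep every design cell in every training set
  d <- generate_isotherm(seed = 3)
  ps <- make_splits(d, 10, 0.75, seed = 4)
  cells <- interaction(d$method, d$branch, d$temperature_c, drop = TRUE)
  for (tr in ps$train)
    expect_setequal(levels(cells), as.character(unique(cells[tr])))
  expect_error(make_splits(4), class = "sorbfit_invalid_config")
  expect_error(make_splits(100, train_fraction = 1),
               class = "sorbfit_invalid_config")
})

test_that("every record reaches validation within 100 iterations", {
  d <- generate_isotherm(seed = 3)
  p <- make_splits(d, 100, 0.75, seed = 5)
  seen <- sort(unique(unlist(p$validation)))
  expect_identical(seen, seq_len(nrow(d)))
})

test_that("MRE reproduces hand-computed values and its invariances", {
  expect_equal(mre(c(0.1, 0.2), c(0.11, 0.18)), 10.0)
  expect_equal(mre(1:5, 1:5), 0)
  y <- runif(20, 0.05, 0.3); yc <- y * runif(20, 0.9, 1.1)
  expect_equal(mre(3.7 * y, 3.7 * yc), mre(y, yc), tolerance = 1e-12)
  expect_error(mre(c(0, 1), c(1, 1)), class = "sorbfit_domain_error")
})

test_that("R2 and adjusted R2 reproduce hand-computed values", {
  r <- r2_adj(c(1, 2, 3), c(1, 2, 4), M = 1)
  expect_equal(r$r2, 50)
  r2m <- r2_adj(c(1, 2, 3), c(1, 2, 4), M = 2)
  expect_equal(r2m$r2_adj, 0)         # 100 - 2*(100 - 50)
  perf <- r2_adj(1:10 / 10, 1:10 / 10, M = 3)
  expect_equal(perf$r2, 100)
  expect_equal(perf$r2_adj, 100)
  # the printed-formula denominator differs from the standard one
  std <- r2_adj(c(1, 2, 3), c(1.1, 2, 2.7), M = 1)
  ap <- r2_adj(c(1, 2, 3), c(1.1, 2, 2.7), M = 1, denominator = "as_printed")
  expect_false(isTRUE(all.equal(std$r2, ap$r2)))
  expect_error(r2_adj(1:3, 1:3, M = 3), class = "sorbfit_invalid_config")
  expect_error(r2_adj(rep(1, 5), rep(1, 5), M = 1),
               class = "sorbfit_domain_error")
})

test_that("adjusted R2 never exceeds R2 when M > 1", {
  set.seed(406)
  for (i in 1:20) {
    y <- runif(30, 0.05, 0.3)
    yp <- y + rnorm(30, 0, 0.01)
    r <- r2_adj(y, yp, M = sample(2:6, 1))
    expect_lte(r$r2_adj, r$r2)
  }
})

test_that("Ljung-Box has power against AR(1) and errors on constants", {
  set.seed(407)
  p_ar <- replicate(20, {
    e <- as.numeric(arima.sim(list(ar = 0.9), 200))
    ljung_box(e)
  })
  expect_true(all(p_ar < 0.001))
  expect_error(ljung_box(rep(0, 50)), class = "sorbfit_degenerate_input")
  expect_error(ljung_box(rnorm(10), lags = 10),
               class = "sorbfit_invalid_config")
})

test_that("Levene detects a 9:1 variance ratio and enforces preconditions", {
  set.seed(408)
  p <- replicate(20, {
    x <- c(rnorm(100, 0, 1), rnorm(100, 0, 3))
    levene_test(x, rep(c("a", "b"), each = 100))
  })
  expect_true(all(p < 0.01))
  expect_error(levene_test(rnorm(10), rep("a", 10)),
               class = "sorbfit_invalid_config")
  expect_error(levene_test(rnorm(51), rep(c("a", "b"), c(1, 50))),
               class = "sorbfit_invalid_config")
})

test_that("residual_diagnostics summarizes both tests with verdicts", {
  set.seed(409)
  aw <- runif(120, 0.1, 0.85)
  rd <- residual_diagnostics(rnorm(120, 0, 0.002), aw)
  expect_true(rd$ljung_box_p >= 0 && rd$ljung_box_p <= 1)
  expect_true(rd$levene_p >= 0 && rd$levene_p <= 1)
  expect_identical(rd$random_ok, rd$ljung_box_p > 0.05)
})

make_metric_table <- function(means, sds, n_it = 100, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(means), function(m) {
    v <- rnorm(n_it, means[[m]], sds[[m]])
    data.frame(model = m, iteration = seq_len(n_it), subset = "validation",
               mre = v, r2 = 100 - v, r2adj = 100 - v,
               n = 100, m = 5, stringsAsFactors = FALSE)
  }))
}

test_that("anova_lsd separates offset models and merges identical ones", {
  # identical metric vectors share a letter and show no model effect
  tab <- make_metric_table(c(A = 3, B = 3), c(A = 0.2, B = 0.2), seed = 2)
  tab$mre[tab$model == "B"] <- tab$mre[tab$model == "A"]
  rk <- suppressWarnings(anova_lsd(tab))   # perfect fit warns in anova.lm
  expect_identical(rk$letter_mre[1], rk$letter_mre[2])
  expect_lt(attr(rk, "anova_mre")["model", "Sum Sq"], 1e-18)
  # a 5-point offset at sd 0.2 is far beyond the LSD
  tab2 <- make_metric_table(c(A = 3, B = 8), c(A = 0.2, B = 0.2), seed = 3)
  rk2 <- anova_lsd(tab2)
  expect_false(rk2$letter_mre[1] == rk2$letter_mre[2])
  expect_identical(rk2$model[1], "A")
  expect_error(anova_lsd(tab2[tab2$model == "A", ]),
               class = "sorbfit_invalid_config")
  expect_error(anova_lsd(rbind(tab2, tab2[1, ])),
               class = "sorbfit_schema_error")
})

test_that("letters agree with brute-force pairwise LSD verdicts", {
  set.seed(410)
  for (rep in 1:10) {
    k <- sample(3:7, 1)
    mns <- setNames(runif(k, 2, 5), LETTERS[1:k])
    sds <- setNames(runif(k, 0.1, 0.8), LETTERS[1:k])
    tab <- make_metric_table(as.list(mns), as.list(sds), n_it = 30,
                             seed = 500 + rep)
    rk <- anova_lsd(tab)
    lsd <- attr(rk, "lsd_mre")
    means <- setNames(rk$mean_mre, rk$model)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      mi <- rk$model[i]; mj <- rk$model[j]
      sig <- unname(abs(means[mi] - means[mj]) > lsd)
      share <- any(strsplit(rk$letter_mre[i], "")[[1]] %in%
                     strsplit(rk$letter_mre[j], "")[[1]])
      expect_identical(!sig, share,
                       label = sprintf("pair %s-%s rep %d", mi, mj, rep))
    }
  }
})

test_that("ranking is invariant to shuffling the metric rows", {
  tab <- make_metric_table(c(A = 3, B = 3.1, C = 5),
                           c(A = 0.3, B = 0.3, C = 0.3), seed = 6)
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "class", "row.names")]
    rownames(x) <- NULL
    x
  }
  rk1 <- anova_lsd(tab)
  set.seed(7)
  rk2 <- anova_lsd(tab[sample(nrow(tab)), ])
  expect_equal(strip(rk1), strip(rk2))
  expect_equal(attr(rk1, "lsd_mre"), attr(rk2, "lsd_mre"))
})

test_that("reported means and SEs reproduce the raw metric table", {
  tab <- make_metric_table(c(A = 3, B = 4), c(A = 0.4, B = 0.2), seed = 8)
  rk <- anova_lsd(tab)
  for (m in c("A", "B")) {
    v <- tab$mre[tab$model == m]
    expect_equal(rk$mean_mre[rk$model == m], mean(v))
    expect_equal(rk$se_mre[rk$model == m], sd(v) / sqrt(length(v)))
  }
})

test_that("ANOVA residual checks pass under the null and flag variance trends", {
  # any single 5%-level check can fail by chance; require >= 8/10 seeds clean
  ok <- vapply(1:10, function(s) {
    tab <- make_metric_table(c(A = 3, B = 4), c(A = 0.3, B = 0.3),
                             seed = 100 + s)
    rc <- anova_residual_checks(anova_lsd(tab))
    rc$normal_ok && rc$random_ok && rc$homoscedastic_ok
  }, logical(1))
  expect_gte(sum(ok), 8)
  # inject variance growing with iteration
  tab2 <- make_metric_table(c(A = 3, B = 4), c(A = 0.3, B = 0.3), seed = 9)
  set.seed(10)
  tab2$mre <- tab2$mre + rnorm(nrow(tab2), 0, 0.02 * tab2$iteration)
  rc2 <- anova_residual_checks(anova_lsd(tab2))
  expect_lt(rc2$mlr_p, 0.05)
})

test_that("train/validation gap of the true model vanishes as noise does", {
  base <- generate_isotherm(noise = noise_model("none"), seed = 21)
  tr <- attr(base, "truth")
  set.seed(11)
  z <- rnorm(nrow(base))
  plan <- make_splits(base, 5, 0.75, seed = 22)
  gap <- vapply(c(0.004, 0.002, 0.001, 0), function(sdn) {
    d <- base
    d$xe <- base$xe + sdn * z
    gaps <- vapply(1:5, function(i) {
      trn <- d[plan$train[[i]], ]; val <- d[plan$validation[[i]], ]
      f <- fit_global(tr$spec, trn, init = tr$params)
      dmv <- sorbfit:::dummies(val); dmt <- sorbfit:::dummies(trn)
      pv <- evaluate_model(f$spec, f$params, val$aw, val$temperature_c,
                           dmv$d1, dmv$d2)
      pt <- evaluate_model(f$spec, f$params, trn$aw, trn$temperature_c,
                           dmt$d1, dmt$d2)
      abs(mre(val$xe, pv) - mre(trn$xe, pt))
    }, numeric(1))
    mean(gaps)
  }, numeric(1))
  expect_lt(gap[4], 1e-6)
  expect_true(all(diff(gap) <= 1e-9))   # monotone toward zero
})

test_that("run_pipeline produces a balanced table and ranks every model", {
  d <- generate_isotherm(seed = 25)
  res <- run_pipeline(d, c("GAB", "KNN"), n_iterations = 5, seed = 26)
  expect_setequal(unique(res$metrics$model), c("GAB", "KNN"))
  expect_equal(nrow(res$metrics), 2 * 5 * 2)  # model x iteration x subset
  expect_s3_class(res$ranking, "ranking_table")
  expect_setequal(res$ranking$model, c("GAB", "KNN"))
  expect_true(all(c("GAB", "KNN") %in% names(res$diagnostics)))
  expect_length(res$unstable, 0)
  # correctly specified model shows no overfit gap (within 2 SE)
  mv <- res$metrics[res$metrics$model == "GAB", ]
  gap <- abs(mean(mv$mre[mv$subset == "validation"]) -
               mean(mv$mre[mv$subset == "train"]))
  sev <- sd(mv$mre[mv$subset == "validation"]) / sqrt(5)
  expect_lt(gap, max(2 * sev, 0.2))
})
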