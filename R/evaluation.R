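# Repeated random train/validation protocol, goodness-of-fit metrics,
# residual-validity screening (Ljung-Box, Brown-Forsythe/Levene), and the
# two-factor ANOVA + Fisher LSD ranking of models.

#' Repeated random train/validation partitions
#'
#' @param data sorption records (or an integer count of records).
#' @param n_iterations number of random partitions (default 100).
#' @param train_fraction fraction assigned to training (default 0.75).
#' @param seed master seed; the whole plan is reproducible from it.
#' @param stratify stratify sampling by the (method, branch, temperature)
#'   cell so every factor level appears in every training set (default
#'   TRUE; plain uniform sampling when FALSE or when `data` is a count).
#' @return a `split_plan`: list with `train` and `validation` index lists,
#'   plus the settings.
#' @export
make_splits <- function(data, n_iterations = 100, train_fraction = 0.75,
                        seed = 1L, stratify = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_sorb("train_fraction must lie in (0, 1)", "sorbfit_invalid_config")
  n <- if (is.numeric(data) && length(data) == 1) as.integer(data) else nrow(data)
  if (n < 8) stop_sorb("dataset too small to partition", "sorbfit_invalid_config")
  cells <- if (stratify && is.data.frame(data)) {
    interaction(data$method, data$branch, data$temperature_c, drop = TRUE)
  } else factor(rep(1, n))
  if (round(train_fraction * n) >= n || round(train_fraction * n) < 1)
    stop_sorb("train_fraction yields an empty subset", "sorbfit_invalid_config")
  plan <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_iterations), function(i) {
      tr <- unlist(lapply(split(seq_len(n), cells), function(idx) {
        ntr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
        sample(idx, ntr)
      }), use.names = FALSE)
      sort(tr)
    })
  })
  structure(list(train = plan,
                 validation = lapply(plan, function(tr) setdiff(seq_len(n), tr)),
                 n = n, n_iterations = n_iterations,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = stratify && is.data.frame(data)),
            class = "split_plan")
}

#' Mean relative error, percent
#'
#' `MRE = (100/N) * sum(|y_exp - y_cal| / y_exp)`.
#'
#' @param y_exp observed values (all nonzero).
#' @param y_cal predicted values.
#' @return MRE in percent.
#' @export
mre <- function(y_exp, y_cal) {
  stopifnot(length(y_exp) == length(y_cal))
  if (any(y_exp == 0))
    stop_sorb("MRE undefined: zero observed value", "sorbfit_domain_error")
  100 / length(y_exp) * sum(abs(y_exp - y_cal) / abs(y_exp))
}

#' Coefficient of determination and its adjusted form, percent
#'
#' `R2 = 100 (1 - SSE/SST)` with SST about the observed mean
#' (`denominator = "standard"`), and
#' `R2_adj = 100 - ((N-1)/(N-M)) (100 - R2)`. The `"as_printed"`
#' denominator variant uses `sum((mean(y_exp) - y_pred)^2)` instead of the
#' total sum of squares.
#'
#' @param y_exp observed values (non-constant).
#' @param y_pred predicted values.
#' @param M number of model parameters.
#' @param denominator `"standard"` or `"as_printed"`.
#' @return list with `r2` and `r2_adj`, both in percent.
#' @export
r2_adj <- function(y_exp, y_pred, M,
                   denominator = c("standard", "as_printed")) {
  denominator <- match.arg(denominator)
  N <- length(y_exp)
  stopifnot(length(y_pred) == N)
  if (N <= M)
    stop_sorb("N must exceed the number of parameters M",
              "sorbfit_invalid_config")
  if (sd(y_exp) == 0)
    stop_sorb("R2 undefined for constant observations", "sorbfit_domain_error")
  sse <- sum((y_exp - y_pred)^2)
  sst <- switch(denominator,
                standard = sum((y_exp - mean(y_exp))^2),
                as_printed = sum((mean(y_exp) - y_pred)^2))
  r2 <- 100 * (1 - sse / sst)
  list(r2 = r2, r2_adj = 100 - (N - 1) / (N - M) * (100 - r2))
}

#' Ljung-Box test of residual independence
#'
#' @param residuals residual vector, ordered by the canonical convention
#'   (method, branch, temperature, ascending aw).
#' @param lags number of autocorrelation lags; default
#'   `min(10, floor(N/5))`.
#' @return p-value of the Q statistic against chi-square(`lags`).
#' @export
ljung_box <- function(residuals, lags = NULL) {
  N <- length(residuals)
  if (sd(residuals) == 0)
    stop_sorb("degenerate input: constant residual vector",
              "sorbfit_degenerate_input")
  lags <- lags %||% max(1L, min(10L, floor(N / 5)))
  if (N <= lags) stop_sorb("need N > lags", "sorbfit_invalid_config")
  Box.test(residuals, lag = lags, type = "Ljung-Box")$p.value
}

# aw terciles used as the default Levene grouping
aw_terciles <- function(aw) {
  qs <- quantile(aw, c(1 / 3, 2 / 3))
  cut(aw, breaks = c(-Inf, qs, Inf), labels = c("low", "mid", "high"))
}

#' Levene (Brown-Forsythe) test of residual homoscedasticity
#'
#' One-way ANOVA of the absolute deviations from the group medians.
#'
#' @param residuals residual vector.
#' @param groups factor of group labels (>= 2 groups, each with >= 2
#'   residuals); typically `aw_terciles(aw)`.
#' @return p-value of the F statistic.
#' @export
levene_test <- function(residuals, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2)
    stop_sorb("Levene test needs at least two groups", "sorbfit_invalid_config")
  if (any(table(groups) < 2))
    stop_sorb("every group needs at least two residuals",
              "sorbfit_invalid_config")
  med <- tapply(residuals, groups, median)
  ad <- abs(residuals - med[groups])
  a <- anova(lm(ad ~ groups))
  a[["Pr(>F)"]][1]
}

#' Residual-validity screening of a fitted model
#'
#' Applies Ljung-Box (independence) and Brown-Forsythe/Levene
#' (homoscedasticity, grouped by aw terciles by default) to the residuals
#' of a model fitted on the full training data, with verdicts at the
#' given alpha.
#'
#' @param residuals canonical-order residual vector.
#' @param aw matching water activities (for the default grouping).
#' @param groups optional explicit grouping factor.
#' @param alpha significance level (default 0.05).
#' @param lags Ljung-Box lag count override.
#' @return list with `ljung_box_p`, `levene_p`, `random_ok`,
#'   `homoscedastic_ok`.
#' @export
residual_diagnostics <- function(residuals, aw, groups = NULL,
                                 alpha = 0.05, lags = NULL) {
  g <- groups %||% aw_terciles(aw)
  lb <- ljung_box(residuals, lags)
  lv <- levene_test(residuals, g)
  list(ljung_box_p = lb, levene_p = lv,
       random_ok = lb > alpha, homoscedastic_ok = lv > alpha)
}

# compact letter display for LSD comparisons with a common threshold:
# non-significance is an interval property of the sorted means, so maximal
# runs of mutually indistinguishable models each get one letter
cld_letters <- function(means, lsd) {
  ord <- order(means)
  m <- means[ord]
  k <- length(m)
  ends <- vapply(seq_len(k), function(i) max(which(m - m[i] <= lsd + 1e-12)),
                 integer(1))
  ivals <- unique(data.frame(start = seq_len(k), end = ends))
  keep <- vapply(seq_len(nrow(ivals)), function(i) {
    !any(ivals$start <= ivals$start[i] & ivals$end >= ivals$end[i] &
           (ivals$start != ivals$start[i] | ivals$end != ivals$end[i]))
  }, logical(1))
  ivals <- ivals[keep, , drop = FALSE]
  ivals <- ivals[order(ivals$start), , drop = FALSE]
  letts <- vapply(seq_len(k), function(i) {
    paste(letters[which(ivals$start <= i & ivals$end >= i)], collapse = "")
  }, character(1))
  out <- character(k)
  out[ord] <- letts
  out
}

#' Two-factor ANOVA with Fisher LSD letter groups
#'
#' For each metric, fits a fixed-effects two-way ANOVA with model and
#' iteration as factors, computes the Fisher least significant difference
#' `t(1 - alpha/2, df_e) * sqrt(2 MSE / n)` on the model factor, and
#' assigns compact letters (models sharing a letter are statistically
#' indistinguishable). Models are ranked by ascending mean validation MRE.
#'
#' @param metrics data.frame with columns `model`, `iteration`, `subset`,
#'   `mre`, `r2adj` (validation rows are used).
#' @param alpha significance level (default 0.05).
#' @param validity optional named logical vector of residual-validity
#'   flags per model.
#' @return a `ranking_table` data.frame: per model the mean, standard
#'   error and letter group of validation MRE and R2_adj, the overall
#'   rank, and the validity flag; ANOVA tables and LSD values are carried
#'   as attributes.
#' @export
anova_lsd <- function(metrics, alpha = 0.05, validity = NULL) {
  v <- metrics[metrics$subset == "validation", , drop = FALSE]
  if (length(unique(v$model)) < 2)
    stop_sorb("ranking requires at least two models", "sorbfit_invalid_config")
  tab <- table(v$model, v$iteration)
  if (any(tab != 1))
    stop_sorb("unbalanced model x iteration design", "sorbfit_schema_error")
  v$model <- factor(v$model)
  v$iteration <- factor(v$iteration)
  n_it <- nlevels(v$iteration)
  per_metric <- function(col) {
    fml <- stats::as.formula(paste(col, "~ model + iteration"))
    fit <- lm(fml, data = v)
    an <- anova(fit)
    mse <- an["Residuals", "Mean Sq"]
    dfe <- an["Residuals", "Df"]
    lsd <- qt(1 - alpha / 2, dfe) * sqrt(2 * mse / n_it)
    means <- tapply(v[[col]], v$model, mean)
    ses <- tapply(v[[col]], v$model, function(x) sd(x) / sqrt(length(x)))
    list(anova = an, lsd = lsd, means = means, ses = ses,
         letters = setNames(cld_letters(as.numeric(means), lsd), names(means)),
         fit = fit)
  }
  m_mre <- per_metric("mre")
  m_r2 <- per_metric("r2adj")
  models <- names(m_mre$means)
  out <- data.frame(
    model = models,
    mean_mre = as.numeric(m_mre$means), se_mre = as.numeric(m_mre$ses),
    letter_mre = as.character(m_mre$letters),
    mean_r2adj = as.numeric(m_r2$means), se_r2adj = as.numeric(m_r2$ses),
    letter_r2adj = as.character(m_r2$letters),
    valid = if (is.null(validity)) NA else as.logical(validity[models]),
    stringsAsFactors = FALSE)
  out <- out[order(out$mean_mre), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("ranking_table", "data.frame"),
            anova_mre = m_mre$anova, anova_r2adj = m_r2$anova,
            lsd_mre = m_mre$lsd, lsd_r2adj = m_r2$lsd, alpha = alpha,
            lm_mre = m_mre$fit, lm_r2adj = m_r2$fit)
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("<ranking_table> %d models (alpha = %.2f, LSD_MRE = %.3g)\n",
              nrow(x), attr(x, "alpha"), attr(x, "lsd_mre")))
  NextMethod()
}

#' Residual checks of the ranking ANOVA
#'
#' Shapiro-Wilk normality, Ljung-Box independence, and a multiple linear
#' regression of the squared residuals on the factors
#' (heteroscedasticity screen), all at the given alpha.
#'
#' @param ranking a `ranking_table` from [anova_lsd()], or a fitted `lm`.
#' @param metric which ANOVA to check, `"mre"` or `"r2adj"`.
#' @param alpha significance level.
#' @return list of p-values and verdicts.
#' @export
anova_residual_checks <- function(ranking, metric = c("mre", "r2adj"),
                                  alpha = 0.05) {
  metric <- match.arg(metric)
  fit <- if (inherits(ranking, "lm")) ranking else
    attr(ranking, paste0("lm_", metric))
  if (is.null(fit)) stop_sorb("no fitted ANOVA found", "sorbfit_invalid_config")
  res <- stats::residuals(fit)
  if (length(res) < 3)
    stop_sorb("Shapiro-Wilk needs at least 3 residuals",
              "sorbfit_degenerate_input")
  sw <- shapiro.test(if (length(res) > 5000) sample(res, 5000) else res)
  # independence is tested per model block (each block, ordered by
  # iteration, is iid under the null; the pooled sequence is not, because
  # the iteration-factor constraints couple the blocks and inflate the Q
  # statistic), then Bonferroni-combined
  blocks <- split(data.frame(r = res,
                             it = as.numeric(as.character(fit$model$iteration))),
                  fit$model$model)
  lb_each <- vapply(blocks, function(b) ljung_box(b$r[order(b$it)]),
                    numeric(1))
  lb <- min(1, length(lb_each) * min(lb_each))
  # squared residuals regressed on the model factor and the iteration
  # index (not the iteration factor: with two models the paired residuals
  # are +-e, so the factor would explain the squares perfectly)
  mdat <- data.frame(r2 = res^2, model = fit$model$model,
                     it = as.numeric(as.character(fit$model$iteration)))
  mlr <- lm(r2 ~ model + it, data = mdat)
  fstat <- summary(mlr)$fstatistic
  mlr_p <- if (is.null(fstat)) NA_real_ else
    pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(shapiro_p = sw$p.value, ljung_box_p = lb, mlr_p = mlr_p,
       normal_ok = sw$p.value > alpha, random_ok = lb > alpha,
       homoscedastic_ok = is.na(mlr_p) || mlr_p > alpha)
}

# fit or train one model (conventional or ML) on a training subset;
# returns list(predict = function(df), M = n free params, converged)
fit_any_model <- function(model, train, seed, full_fit = NULL,
                          ml_cfg = ml_config(), strategy = "joint") {
  if (model %in% names(ml_trainers())) {
    cfg <- ml_cfg; cfg$seed <- seed
    reg <- ml_trainers()[[model]](train, cfg)
    list(predict = function(df) predict(reg, df), M = 5L, converged = TRUE,
         object = reg)
  } else {
    spec <- conventional_spec(model)
    ft <- tryCatch(
      fit_global(spec, train, strategy = strategy,
                 init = if (!is.null(full_fit)) full_fit$params else NULL,
                 seed = seed),
      error = function(e) NULL)
    if (is.null(ft))
      return(list(predict = NULL, M = spec$n_params, converged = FALSE))
    list(predict = function(df) {
      dm <- dummies(df)
      evaluate_model(spec, ft$params, df$aw, df$temperature_c, dm$d1, dm$d2)
    }, M = spec$n_params, converged = ft$converged, object = ft)
  }
}

# default global specification for a conventional model name
conventional_spec <- function(name) {
  if (name == "GAB") model_spec("GAB", "arrhenius", uses_dummies = TRUE)
  else model_spec(name, "linear", uses_dummies = TRUE)
}

#' Run the full modeling and selection pipeline
#'
#' For each split iteration and model: fit/train on the training fraction,
#' score both subsets with MRE and adjusted R2; screen the full-data
#' residuals of every model with Ljung-Box and Levene; rank by two-factor
#' ANOVA with Fisher LSD letters. Models failing residual screening are
#' still ranked but flagged; models failing to converge in more than 20%
#' of iterations are flagged unstable.
#'
#' @param data an `isotherm_dataset` (or compatible data.frame).
#' @param models character vector of conventional model names and/or
#'   `"RT"`, `"RF"`, `"KNN"`, `"SVM"`.
#' @param n_iterations number of random partitions.
#' @param train_fraction training fraction.
#' @param seed master seed.
#' @param ml_cfg an [ml_config()].
#' @param strategy conventional fitting strategy, `"joint"` or
#'   `"sequential"`.
#' @param alpha significance level for diagnostics and LSD.
#' @return list with `ranking` (a `ranking_table`), `metrics` (the raw
#'   per-iteration table), `diagnostics`, `full_fits`, `unstable`, `plan`.
#' @export
run_pipeline <- function(data, models, n_iterations = 100,
                         train_fraction = 0.75, seed = 1L,
                         ml_cfg = ml_config(), strategy = "joint",
                         alpha = 0.05) {
  data <- canonical_order(as.data.frame(data))
  plan <- make_splits(data, n_iterations, train_fraction,
                      seed = child_seed(seed, "splits"))
  # duplicated model names are allowed (they get distinct labels)
  labels <- make.unique(models)
  models <- setNames(models, labels)
  # full-data reference fits: residual screening + warm starts
  full_fits <- lapply(setNames(labels, labels), function(lb)
    fit_any_model(models[[lb]], data,
                  seed = child_seed(seed, paste0("full", lb)),
                  ml_cfg = ml_cfg, strategy = strategy))
  diagnostics <- lapply(full_fits, function(ff) {
    if (is.null(ff$predict)) return(NULL)
    res <- data$xe - ff$predict(data)
    tryCatch(residual_diagnostics(res, data$aw, alpha = alpha),
             error = function(e) NULL)
  })
  validity <- vapply(diagnostics, function(d)
    !is.null(d) && d$random_ok && d$homoscedastic_ok, logical(1))
  rows <- list()
  fails <- setNames(numeric(length(labels)), labels)
  for (it in seq_len(n_iterations)) {
    tr <- data[plan$train[[it]], , drop = FALSE]
    va <- data[plan$validation[[it]], , drop = FALSE]
    for (lb in labels) {
      fm <- fit_any_model(models[[lb]], tr,
                          seed = child_seed(seed, paste0(lb, it)),
                          full_fit = full_fits[[lb]]$object,
                          ml_cfg = ml_cfg, strategy = strategy)
      if (!fm$converged || is.null(fm$predict)) fails[lb] <- fails[lb] + 1
      if (is.null(fm$predict)) next
      for (ss in c("train", "validation")) {
        d <- if (ss == "train") tr else va
        pr <- fm$predict(d)
        r2 <- r2_adj(d$xe, pr, fm$M)
        rows[[length(rows) + 1]] <- data.frame(
          model = lb, iteration = it, subset = ss,
          mre = mre(d$xe, pr), r2 = r2$r2, r2adj = r2$r2_adj,
          n = nrow(d), m = fm$M, stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  ranking <- anova_lsd(metrics, alpha = alpha, validity = validity)
  list(ranking = ranking, metrics = metrics, diagnostics = diagnostics,
       full_fits = full_fits, unstable = names(fails)[fails > 0.2 * n_iterations],
       plan = plan)
}
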