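# The four machine-learning regressors predicting X_e from
# (a_w, temperature, postharvest method, sorption branch), with the
# study hyperparameters: regression tree with post-pruning SE multiplier
# 0.1, random forest with 100 trees, 4-nearest-neighbors, and nu-SVR with
# a Laplacian kernel and cost C = 500.5 (solved exactly as a QP).

#' Machine-learning configuration
#'
#' @param rt_se post-pruning standard-error multiplier for the regression
#'   tree (default 0.1).
#' @param rf_trees number of trees in the random forest (default 100).
#' @param rf_mtry features tried per split (default `max(floor(p/2), 1)`;
#'   the common regression rule `p/3` degenerates to a single feature on
#'   this four-feature encoding and yields near-random trees).
#' @param knn_k number of nearest neighbors (default 4).
#' @param svm_C nu-SVR cost (default 500.5).
#' @param svm_nu nu parameter, fraction of support vectors (default 0.5).
#' @param svm_sigma Laplacian kernel width, or `"heuristic"` for the
#'   inverse median pairwise distance.
#' @param scale standardize `aw` and temperature for the distance/kernel
#'   methods (kNN, SVM); indicators stay 0/1, trees are unscaled.
#' @param seed integer seed for the stochastic learners.
#' @return an `ml_config` object.
#' @export
ml_config <- function(rt_se = 0.1, rf_trees = 100, rf_mtry = NULL,
                      knn_k = 4, svm_C = 500.5, svm_nu = 0.5,
                      svm_sigma = "heuristic", scale = TRUE, seed = 1L) {
  structure(list(rt_se = rt_se, rf_trees = rf_trees, rf_mtry = rf_mtry,
                 knn_k = knn_k, svm_C = svm_C, svm_nu = svm_nu,
                 svm_sigma = svm_sigma, scale = scale,
                 seed = as.integer(seed)), class = "ml_config")
}

# fixed feature encoding: columns aw, temperature_c, d1 (semidry),
# d2 (adsorption); same order at train and predict time
encode_features <- function(df) {
  req <- c("aw", "temperature_c", "method", "branch")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_sorb(sprintf("missing feature columns: %s", paste(miss, collapse = ", ")),
              "sorbfit_schema_error")
  bad <- setdiff(unique(df$method), c("wet", "semidry"))
  if (length(bad))
    stop_sorb(sprintf("unknown method level(s): %s", paste(bad, collapse = ", ")),
              "sorbfit_schema_error")
  badb <- setdiff(unique(df$branch), c("desorption", "adsorption"))
  if (length(badb))
    stop_sorb(sprintf("unknown branch level(s): %s", paste(badb, collapse = ", ")),
              "sorbfit_schema_error")
  dm <- dummies(df)
  cbind(aw = df$aw, temperature_c = df$temperature_c, d1 = dm$d1, d2 = dm$d2)
}

# learn / apply standardization of the continuous columns only
scale_fit <- function(X) {
  mu <- c(mean(X[, 1]), mean(X[, 2]), 0, 0)
  sdev <- c(sd(X[, 1]), sd(X[, 2]), 1, 1)
  sdev[sdev < 1e-12] <- 1
  list(mu = mu, sd = sdev)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Train a regression tree
#'
#' CART grown with variance-reduction splits and pruned by
#' cross-validated cost-complexity selection with the scaled
#' one-standard-error rule (`rt_se`, default 0.1).
#'
#' @param data sorption records (training set).
#' @param config an [ml_config()].
#' @return a `sorb_rt` regressor.
#' @export
train_rt <- function(data, config = ml_config()) {
  X <- encode_features(data); y <- data$xe
  if (!length(y)) stop_sorb("empty training set", "sorbfit_invalid_config")
  withr::with_seed(child_seed(config$seed, "rt"), {
    full <- grow_tree(X, y, minsplit = 20, minbucket = 7)
    alphas <- cc_alphas(full)
    alpha <- select_alpha_cv(X, y, alphas, minsplit = 20, minbucket = 7,
                             se_mult = config$rt_se)
    tree <- prune_tree(full, alpha)
    structure(list(tree = tree, alpha = alpha, config = config),
              class = "sorb_rt")
  })
}

#' @export
predict.sorb_rt <- function(object, newdata, ...) {
  predict_tree(object$tree, encode_features(newdata))
}

#' Train a random forest
#'
#' Bagged unpruned CART trees with per-node feature subsampling
#' (`rf_mtry`, default `max(floor(p/2), 1)`), averaged predictions.
#'
#' @param data sorption records (training set).
#' @param config an [ml_config()].
#' @return a `sorb_rf` regressor.
#' @export
train_rf <- function(data, config = ml_config()) {
  X <- encode_features(data); y <- data$xe
  if (!length(y)) stop_sorb("empty training set", "sorbfit_invalid_config")
  mtry <- config$rf_mtry %||% max(floor(ncol(X) / 2), 1)
  withr::with_seed(child_seed(config$seed, "rf"), {
    trees <- lapply(seq_len(config$rf_trees), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      grow_tree(X[idx, , drop = FALSE], y[idx],
                minsplit = 10, minbucket = 5, mtry = mtry)
    })
    structure(list(trees = trees, config = config), class = "sorb_rf")
  })
}

#' @export
predict.sorb_rf <- function(object, newdata, ...) {
  Xn <- encode_features(newdata)
  preds <- vapply(object$trees, function(tr) predict_tree(tr, Xn),
                  numeric(nrow(Xn)))
  if (nrow(Xn) == 1) mean(preds) else rowMeans(preds)
}

#' Train a k-nearest-neighbors regressor
#'
#' Instance-based: stores the (scaled) training set. Prediction averages
#' the targets of every training point whose distance is among the `k`
#' smallest distinct distances, so exact duplicates share a rank.
#'
#' @param data sorption records (training set).
#' @param config an [ml_config()].
#' @return a `sorb_knn` regressor.
#' @export
train_knn <- function(data, config = ml_config()) {
  X <- encode_features(data); y <- data$xe
  if (config$knn_k > length(unique(apply(X, 1, paste, collapse = "\r"))))
    stop_sorb("k exceeds the number of distinct training points",
              "sorbfit_invalid_config")
  sc <- if (config$scale) scale_fit(X) else NULL
  Xs <- if (is.null(sc)) X else scale_apply(X, sc)
  structure(list(X = Xs, y = y, sc = sc, config = config),
            class = "sorb_knn")
}

#' @export
predict.sorb_knn <- function(object, newdata, ...) {
  Xn <- encode_features(newdata)
  if (!is.null(object$sc)) Xn <- scale_apply(Xn, object$sc)
  k <- object$config$knn_k
  # full sorted neighbor distances via FNN, then expand distance ties
  nb <- FNN::knnx.dist(object$X, Xn, k = nrow(object$X))
  tX <- t(object$X)
  vapply(seq_len(nrow(Xn)), function(i) {
    dist_k <- unique(round(nb[i, ], 12))[min(k, length(unique(round(nb[i, ], 12))))]
    dd <- sqrt(colSums((tX - Xn[i, ])^2))
    mean(object$y[dd <= dist_k + 1e-12])
  }, numeric(1))
}

laplace_kernel <- function(X1, X2, sigma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-sigma * sqrt(pmax(d2, 0)))
}

#' Train a nu-support-vector regressor (Laplacian kernel)
#'
#' Solves the nu-SVR dual exactly as a quadratic program
#' (`quadprog::solve.QP`): minimize
#' `1/2 (a - a*)' K (a - a*) - y' (a - a*)` subject to
#' `sum(a - a*) = 0`, `sum(a + a*) <= C nu n`, `0 <= a, a* <= C`,
#' with `K(x, z) = exp(-sigma ||x - z||)`. The bias and tube width are
#' recovered from the Karush-Kuhn-Tucker conditions.
#'
#' @param data sorption records (training set).
#' @param config an [ml_config()].
#' @return a `sorb_svm` regressor.
#' @export
train_svm <- function(data, config = ml_config()) {
  X <- encode_features(data); y <- data$xe
  n <- length(y)
  if (!n) stop_sorb("empty training set", "sorbfit_invalid_config")
  sc <- if (config$scale) scale_fit(X) else NULL
  Xs <- if (is.null(sc)) X else scale_apply(X, sc)
  sigma <- config$svm_sigma
  if (identical(sigma, "heuristic")) {
    ss <- if (n > 200) Xs[seq(1, n, length.out = 200), , drop = FALSE] else Xs
    md <- median(stats::dist(ss))
    sigma <- if (md > 1e-12) 1 / md else 1
  }
  K <- laplace_kernel(Xs, Xs, sigma)
  C <- config$svm_C; nu <- config$svm_nu
  D <- rbind(cbind(K, -K), cbind(-K, K))
  diag(D) <- diag(D) + 1e-8 * mean(diag(K))
  dvec <- c(y, -y)
  # columns: [eq sum(a - a*) = 0] [-sum(a + a*) >= -C nu n] [z >= 0] [-z >= -C]
  Amat <- cbind(c(rep(1, n), rep(-1, n)), rep(-1, 2 * n),
                diag(2 * n), -diag(2 * n))
  bvec <- c(0, -C * nu * n, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, dvec, Amat, bvec, meq = 1)
  z <- sol$solution
  a <- z[1:n]; astar <- z[(n + 1):(2 * n)]
  beta <- a - astar
  fx <- as.numeric(K %*% beta)
  r <- y - fx
  tol <- 1e-6 * C
  free_a <- which(a > tol & a < C - tol)
  free_as <- which(astar > tol & astar < C - tol)
  if (length(free_a) && length(free_as)) {
    b <- (mean(r[free_a]) + mean(r[free_as])) / 2
    eps <- max((mean(r[free_a]) - mean(r[free_as])) / 2, 0)
  } else {
    b <- median(r); eps <- 0
  }
  structure(list(X = Xs, beta = beta, b = b, eps = eps, sigma = sigma,
                 sc = sc, config = config), class = "sorb_svm")
}

#' @export
predict.sorb_svm <- function(object, newdata, ...) {
  Xn <- encode_features(newdata)
  if (!is.null(object$sc)) Xn <- scale_apply(Xn, object$sc)
  as.numeric(laplace_kernel(Xn, object$X, object$sigma) %*% object$beta) +
    object$b
}

# uniform trainer dispatch used by the evaluation pipeline
ml_trainers <- function() {
  list(RT = train_rt, RF = train_rf, KNN = train_knn, SVM = train_svm)
}
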