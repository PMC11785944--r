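# Minimal CART regression tree: greedy variance-reduction splits,
# weakest-link cost-complexity pruning, and cross-validated subtree
# selection with the scaled one-standard-error rule. Used both for the
# standalone regression tree (post-pruning SE multiplier, default 0.1)
# and, unpruned with per-node feature subsampling, inside the bagged
# random forest.

grow_tree <- function(X, y, minsplit = 20, minbucket = 7, mtry = ncol(X)) {
  build <- function(idx) {
    n <- length(idx)
    mu <- mean(y[idx])
    dev <- sum((y[idx] - mu)^2)
    node <- list(leaf = TRUE, value = mu, n = n, dev = dev)
    if (n < minsplit || dev <= 1e-14) return(node)
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- NULL; best_gain <- 0
    for (j in feats) {
      xj <- X[idx, j]
      ord <- order(xj)
      xs <- xj[ord]; ys <- y[idx][ord]
      csum <- cumsum(ys); csq <- cumsum(ys^2)
      tot <- csum[n]; totsq <- csq[n]
      k <- seq_len(n - 1)
      ok <- (xs[k] < xs[k + 1]) & (k >= minbucket) & ((n - k) >= minbucket)
      if (!any(ok)) next
      sseL <- csq[k] - csum[k]^2 / k
      sseR <- (totsq - csq[k]) - (tot - csum[k])^2 / (n - k)
      gain <- dev - (sseL + sseR)
      gain[!ok] <- -Inf
      kk <- which.max(gain)
      if (gain[kk] > best_gain + 1e-12) {
        best_gain <- gain[kk]
        best <- list(var = j, point = (xs[kk] + xs[kk + 1]) / 2)
      }
    }
    if (is.null(best)) return(node)
    go_left <- X[idx, best$var] <= best$point
    node$leaf <- FALSE
    node$var <- best$var; node$point <- best$point
    node$left <- build(idx[go_left])
    node$right <- build(idx[!go_left])
    node
  }
  build(seq_along(y))
}

predict_tree <- function(tree, X) {
  one <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$var] <= node$point) node$left else node$right
    node$value
  }
  apply(X, 1, function(x) one(tree, x))
}

# (subtree SSE, number of leaves) for the fully grown subtree
tree_stats <- function(node) {
  if (node$leaf) return(c(node$dev, 1))
  l <- tree_stats(node$left); r <- tree_stats(node$right)
  c(l[1] + r[1], l[2] + r[2])
}

# collapse every internal node whose weakest-link value g(t) =
# (R(t) - R(T_t)) / (leaves(T_t) - 1) does not exceed alpha
prune_tree <- function(node, alpha) {
  if (node$leaf) return(node)
  node$left <- prune_tree(node$left, alpha)
  node$right <- prune_tree(node$right, alpha)
  st <- tree_stats(node)
  if (st[2] > 1 && (node$dev - st[1]) / (st[2] - 1) <= alpha + 1e-12) {
    node <- list(leaf = TRUE, value = node$value, n = node$n, dev = node$dev)
  }
  node
}

# increasing sequence of critical alphas of the weakest-link path
cc_alphas <- function(tree) {
  collect <- function(node) {
    if (node$leaf) return(numeric(0))
    st <- tree_stats(node)
    c((node$dev - st[1]) / (st[2] - 1),
      collect(node$left), collect(node$right))
  }
  alphas <- 0
  t_cur <- tree
  repeat {
    gs <- collect(t_cur)
    if (!length(gs)) break
    a <- min(gs)
    alphas <- c(alphas, a)
    t_cur <- prune_tree(t_cur, a)
  }
  unique(alphas)
}

# cross-validated selection of the pruning strength: largest alpha whose
# CV error is within (min CV error + se_mult * SE); alphas are compared on
# the geometric-mean grid of the main tree's pruning path, rescaled per
# fold by the fold's share of the data (R is an absolute SSE here)
select_alpha_cv <- function(X, y, alphas, minsplit, minbucket,
                            se_mult = 0.1, nfold = 10) {
  n <- length(y)
  nfold <- min(nfold, n)
  if (length(alphas) < 2) return(max(alphas, 0))
  grid <- sqrt(alphas[-length(alphas)] * pmax(alphas[-1], 1e-300))
  grid[alphas[-length(alphas)] == 0] <- 0
  grid <- c(grid, alphas[length(alphas)] * 2 + 1e-12)
  folds <- sample(rep(seq_len(nfold), length.out = n))
  errs <- matrix(NA_real_, n, length(grid))   # per-observation squared error
  for (f in seq_len(nfold)) {
    tr <- folds != f
    ft <- grow_tree(X[tr, , drop = FALSE], y[tr], minsplit, minbucket)
    scale_f <- sum(tr) / n
    for (a in seq_along(grid)) {
      pt <- prune_tree(ft, grid[a] * scale_f)
      errs[!tr, a] <- (y[!tr] - predict_tree(pt, X[!tr, , drop = FALSE]))^2
    }
  }
  cv <- colMeans(errs)
  cv_se <- apply(errs, 2, sd) / sqrt(n)
  thr <- min(cv) + se_mult * cv_se[which.min(cv)]
  grid[max(which(cv <= thr))]
}
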