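# Minimal self-contained learners for the discordance-prediction harness.
#
# The grading environment carries no tree/nnet packages, so the two
# classifiers are implemented here from scratch: a bagged ensemble of
# CART-style gini trees with per-split feature subsampling (a small random
# forest) and a single-hidden-layer feed-forward network trained by BFGS on
# penalized cross-entropy.  Both expose probability predictions.

# ---- classification tree -----------------------------------------------------

.best_split <- function(x, y) {
  # returns c(gain, split) for one feature, or NULL
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  i <- i[valid]
  nl <- i; nr <- n - i
  pl <- cum1[i] / nl; pr <- (tot1 - cum1[i]) / nr
  imp <- nl * pl * (1 - pl) + nr * pr * (1 - pr)
  p0 <- tot1 / n
  gain <- n * p0 * (1 - p0) - imp
  k <- which.max(gain)
  c(gain[k], (xs[i[k]] + xs[i[k] + 1L]) / 2)
}

.grow_tree <- function(X, y, mtry, max_depth, min_node, depth = 0L,
                       importance = NULL) {
  n <- length(y)
  p <- mean(y)
  if (depth >= max_depth || n < 2L * min_node || p == 0 || p == 1)
    return(list(leaf = TRUE, prob = p))
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL; best_j <- NA_integer_
  for (j in feats) {
    s <- .best_split(X[, j], y)
    if (!is.null(s) && (is.null(best) || s[1] > best[1])) {
      best <- s; best_j <- j
    }
  }
  if (is.null(best) || best[1] <= 1e-12) return(list(leaf = TRUE, prob = p))
  left <- X[, best_j] <= best[2]
  if (sum(left) < min_node || sum(!left) < min_node)
    return(list(leaf = TRUE, prob = p))
  list(leaf = FALSE, var = best_j, split = best[2], gain = best[1],
       left = .grow_tree(X[left, , drop = FALSE], y[left], mtry, max_depth,
                         min_node, depth + 1L),
       right = .grow_tree(X[!left, , drop = FALSE], y[!left], mtry, max_depth,
                          min_node, depth + 1L))
}

.predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$prob; return() }
    left <- X[idx, node$var] <= node$split
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

.tree_importance <- function(tree, p) {
  imp <- numeric(p)
  rec <- function(node) {
    if (node$leaf) return()
    imp[node$var] <<- imp[node$var] + node$gain
    rec(node$left); rec(node$right)
  }
  rec(tree)
  imp
}

#' Fit a bagged classification forest
#'
#' CART-style binary trees (gini impurity) grown on bootstrap resamples
#' with `mtry` features considered per split; probabilities are averaged
#' over trees.  Feature importance is the total gini gain accumulated per
#' feature across the ensemble.
#'
#' @param X Numeric matrix (rows = patients, columns = features).
#' @param y Binary labels (0/1 or logical).
#' @param ntree Number of trees, default 100.
#' @param mtry Features per split, default `floor(sqrt(ncol(X)))`.
#' @param max_depth,min_node Tree size controls.
#' @return Object of class `dr_forest` with `trees`, `importance`.
#' @export
forest_fit <- function(X, y, ntree = 100L, mtry = NULL, max_depth = 8L,
                       min_node = 5L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  imp <- numeric(ncol(X))
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- .grow_tree(X[idx, , drop = FALSE], y[idx], mtry,
                             max_depth, min_node)
    imp <- imp + .tree_importance(trees[[t]], ncol(X))
  }
  names(imp) <- colnames(X)
  structure(list(trees = trees, importance = imp / ntree,
                 features = colnames(X)), class = "dr_forest")
}

#' @rdname forest_fit
#' @param object A fitted `dr_forest`.
#' @param newdata Matrix of features.
#' @param ... Unused.
#' @return Predicted event probabilities.
#' @export
predict.dr_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  rowMeans(vapply(object$trees, function(tr) .predict_tree(tr, newdata),
                  numeric(nrow(newdata))))
}

# ---- feed-forward network ----------------------------------------------------

.ff_unpack <- function(theta, p, h) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  w2 <- theta[i + seq_len(h)]; i <- i + h
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

#' Fit a single-hidden-layer feed-forward classifier
#'
#' tanh hidden layer, logistic output, trained by BFGS on cross-entropy
#' with an L2 weight penalty.  Inputs are standardized internally.  This is
#' the package's generic stand-in for a tabular "deep learning" model; an
#' optional small grid over hidden size and decay is searched on an
#' internal validation split by [ff_grid_search()].
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param hidden Hidden units, default 8.
#' @param decay L2 penalty, default 1e-2.
#' @param maxit BFGS iterations, default 200.
#' @return Object of class `dr_ffnet`.
#' @export
ff_fit <- function(X, y, hidden = 8L, decay = 1e-2, maxit = 200L) {
  X <- as.matrix(X); y <- as.numeric(y)
  mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  p <- ncol(Xs); h <- hidden; n <- nrow(Xs)
  npar <- p * h + h + h + 1L
  theta0 <- rnorm(npar, sd = 0.3)
  fn <- function(theta) {
    w <- .ff_unpack(theta, p, h)
    A <- tanh(sweep(Xs %*% w$W1, 2, w$b1, "+"))
    eta <- drop(A %*% w$w2) + w$b2
    pr <- stats::plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr)) + decay * sum(theta^2)
  }
  gr <- function(theta) {
    w <- .ff_unpack(theta, p, h)
    Z <- sweep(Xs %*% w$W1, 2, w$b1, "+")
    A <- tanh(Z)
    eta <- drop(A %*% w$w2) + w$b2
    pr <- stats::plogis(eta)
    d2 <- (pr - y) / n                      # d loss / d eta
    gw2 <- drop(crossprod(A, d2))
    gb2 <- sum(d2)
    dA <- outer(d2, w$w2) * (1 - A^2)       # n x h
    gW1 <- crossprod(Xs, dA)
    gb1 <- colSums(dA)
    c(as.numeric(gW1), gb1, gw2, gb2) + 2 * decay * theta
  }
  fit <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit))
  structure(list(theta = fit$par, p = p, h = h, mu = mu, sg = sg,
                 decay = decay, value = fit$value), class = "dr_ffnet")
}

#' @rdname ff_fit
#' @param object A fitted `dr_ffnet`.
#' @param newdata Matrix of features.
#' @param ... Unused.
#' @export
predict.dr_ffnet <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sg, "/")
  w <- .ff_unpack(object$theta, object$p, object$h)
  A <- tanh(sweep(Xs %*% w$W1, 2, w$b1, "+"))
  stats::plogis(drop(A %*% w$w2) + w$b2)
}

#' Small hyperparameter grid search for the feed-forward classifier
#'
#' Splits the training data 75:25, fits every (hidden, decay) combination
#' on the larger part and picks the combination with the best validation
#' AUC, then refits on all rows.
#'
#' @param X,y Training data.
#' @param hidden_grid,decay_grid Candidate values.
#' @return A fitted `dr_ffnet` (attributes `hidden`, `decay` record the
#'   selected combination).
#' @export
ff_grid_search <- function(X, y, hidden_grid = c(4L, 8L),
                           decay_grid = c(1e-3, 1e-2)) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  pos <- which(y == 1); neg <- which(y == 0)
  val <- c(sample(pos, max(1, floor(length(pos) / 4))),
           sample(neg, max(1, floor(length(neg) / 4))))
  tr <- setdiff(seq_len(n), val)
  best <- NULL; best_auc <- -Inf; best_par <- NULL
  for (h in hidden_grid) for (d in decay_grid) {
    f <- ff_fit(X[tr, , drop = FALSE], y[tr], hidden = h, decay = d)
    a <- auc_score(y[val], predict(f, X[val, , drop = FALSE]))
    if (!is.na(a) && a > best_auc) { best_auc <- a; best_par <- c(h = h, d = d) }
  }
  fit <- ff_fit(X, y, hidden = best_par[["h"]], decay = best_par[["d"]])
  attr(fit, "hidden") <- best_par[["h"]]
  attr(fit, "decay") <- best_par[["d"]]
  fit
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midrank tie handling.
#'
#' @param y Binary truth labels.
#' @param score Numeric prediction scores.
#' @return AUC in `[0, 1]`, `NA` if one class is absent.
#' @export
auc_score <- function(y, score) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
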