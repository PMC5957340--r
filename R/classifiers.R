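# Minimal binary classifiers used by evaluate_classifier(). Each fitter
# returns an object whose predict_cls() yields class labels for a numeric
# feature matrix. Features are standardized with training-set statistics
# inside the fitters, so callers pass raw feature tables.

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mu = mu, sg = sg)
}
standardize_apply <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$sg, "/")

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

# Soft-margin RBF-kernel SVM, dual form solved with quadprog:
# maximize sum(alpha) - 1/2 alpha' (K * yy') alpha, 0 <= alpha <= C,
# sum(alpha * y) = 0. gamma defaults to 1 / n_features, C to 1.
fit_svm_rbf <- function(x, y, C = 1, gamma = 1 / ncol(x)) {
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("the SVM implementation is binary only")
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  yy <- ifelse(y == lev[2L], 1, -1)
  n <- nrow(xs)
  K <- rbf_kernel(xs, xs, gamma)
  D <- (K * tcrossprod(yy)) + diag(1e-8, n)
  A <- cbind(yy, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6
  margin <- sv & alpha < C - 1e-6
  f_raw <- as.vector(K %*% (alpha * yy))
  b <- if (any(margin)) mean(yy[margin] - f_raw[margin]) else mean(yy[sv] - f_raw[sv])
  structure(list(x = xs, y = yy, alpha = alpha, b = b, gamma = gamma,
                 st = st, lev = lev), class = "mncse_svm")
}

predict_cls <- function(fit, newx) UseMethod("predict_cls")

#' @export
predict_cls.mncse_svm <- function(fit, newx) {
  K <- rbf_kernel(standardize_apply(newx, fit$st), fit$x, fit$gamma)
  f <- as.vector(K %*% (fit$alpha * fit$y)) + fit$b
  fit$lev[ifelse(f >= 0, 2L, 1L)]
}

# ---- CART + bagging ---------------------------------------------------

# One binary classification tree on (x, y), Gini impurity, axis-aligned
# splits, `mtry` candidate features per node. Returns a nested list.
grow_tree <- function(x, y, mtry, min_node = 2L, depth = 0L, max_depth = 12L) {
  n <- length(y)
  tab <- table(y)
  maj <- names(tab)[which.max(tab)]
  if (n < min_node || length(tab) == 1L || depth >= max_depth)
    return(list(leaf = TRUE, class = maj))
  p <- ncol(x)
  feats <- sample.int(p, min(mtry, p))
  best <- NULL; best_gain <- 0
  gini <- function(cnt) { s <- sum(cnt); if (s == 0) 0 else 1 - sum((cnt / s)^2) }
  parent <- gini(tab)
  for (f in feats) {
    v <- x[, f]
    cuts <- unique(v)
    if (length(cuts) < 2L) next
    cuts <- sort(cuts)
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      g <- parent - (nl * gini(table(y[left])) +
                     (n - nl) * gini(table(y[!left]))) / n
      if (g > best_gain + 1e-12) { best_gain <- g; best <- list(f = f, cut = cut) }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, class = maj))
  left <- x[, best$f] <= best$cut
  list(leaf = FALSE, f = best$f, cut = best$cut,
       left = grow_tree(x[left, , drop = FALSE], y[left], mtry, min_node, depth + 1L, max_depth),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], mtry, min_node, depth + 1L, max_depth))
}

predict_tree <- function(tree, x) {
  apply(x, 1L, function(row) {
    nd <- tree
    while (!nd$leaf) nd <- if (row[nd$f] <= nd$cut) nd$left else nd$right
    nd$class
  })
}

# Random forest: `ntree` bootstrap-sampled trees, majority vote,
# mtry = floor(sqrt(p)) as is conventional for classification forests.
fit_rf <- function(x, y, ntree = 100L, mtry = max(1L, floor(sqrt(ncol(x))))) {
  y <- as.character(y)
  trees <- replicate(ntree, {
    idx <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], y[idx], mtry)
  }, simplify = FALSE)
  structure(list(trees = trees, lev = sort(unique(y))), class = "mncse_rf")
}

#' @export
predict_cls.mncse_rf <- function(fit, newx) {
  votes <- vapply(fit$trees, predict_tree, character(nrow(newx)), x = newx)
  votes <- matrix(votes, nrow = nrow(newx))
  apply(votes, 1L, function(v) {
    tab <- table(factor(v, levels = fit$lev))
    fit$lev[which.max(tab)]
  })
}

# ---- kNN --------------------------------------------------------------

fit_knn3 <- function(x, y, k = 3L) {
  st <- standardize_fit(x)
  structure(list(x = standardize_apply(x, st), y = as.character(y),
                 k = k, st = st), class = "mncse_knn")
}

#' @export
predict_cls.mncse_knn <- function(fit, newx) {
  as.character(FNN::knn(fit$x, standardize_apply(newx, fit$st),
                        cl = fit$y, k = fit$k))
}

fit_classifier <- function(x, y, classifier, ...) {
  switch(classifier,
         svm_rbf = fit_svm_rbf(x, y, ...),
         rf      = fit_rf(x, y, ...),
         knn3    = fit_knn3(x, y, ...),
         stop("unknown classifier: ", classifier))
}
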