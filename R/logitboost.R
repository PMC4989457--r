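# Two-class LogitBoost with simple (one-variable) weighted least-squares
# base learners. Each boosting step adds 0.5 * (a + b * x_j) for the single
# feature j that most reduces the weighted squared error of the working
# response, so the ensemble collapses to a linear score
# F(x) = beta0 + beta' x with p(late | x) = 1 / (1 + exp(-2 F(x))).
# Working responses are clipped at |z| <= 3 and weights floored, the usual
# stabilizations.

LOGITBOOST_ZMAX <- 3

# Run boosting for n_iter steps; optionally evaluate misclassification on a
# test set after every step (used for the cross-validated choice of the
# iteration count). Returns cumulative coefficients and the per-iteration
# test error vector.
logitboost_path <- function(X, y, n_iter, X_test = NULL, y_test = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  beta0 <- 0
  beta <- numeric(p)
  f <- numeric(n)
  prob <- rep(0.5, n)
  f_test <- if (!is.null(X_test)) numeric(nrow(X_test)) else NULL
  test_err <- numeric(n_iter)

  for (m in seq_len(n_iter)) {
    w <- pmax(prob * (1 - prob), 1e-10)
    z <- (y - prob) / w
    z <- pmin(pmax(z, -LOGITBOOST_ZMAX), LOGITBOOST_ZMAX)

    sw <- sum(w)
    xm <- colSums(w * X) / sw
    zm <- sum(w * z) / sw
    sxz <- colSums(w * X * z) - sw * xm * zm
    sxx <- colSums(w * X * X) - sw * xm * xm
    slope <- ifelse(sxx > 1e-12, sxz / sxx, 0)
    gain <- slope * sxz  # reduction in weighted SSE per feature
    j <- which.max(gain)
    b <- slope[j]
    a <- zm - b * xm[j]

    beta0 <- beta0 + 0.5 * a
    beta[j] <- beta[j] + 0.5 * b
    f <- f + 0.5 * (a + b * X[, j])
    prob <- 1 / (1 + exp(-2 * f))

    if (!is.null(f_test)) {
      f_test <- f_test + 0.5 * (a + b * X_test[, j])
      test_err[m] <- mean((f_test > 0) != (y_test == 1))
    }
  }
  list(beta0 = beta0, beta = beta, test_err = test_err)
}

# Choose the LogitBoost iteration count by stratified cv_folds-fold
# cross-validation (summed per-iteration test errors; ties favor fewer
# iterations), then refit on the full data.
fit_simple_logistic <- function(X, y, max_iter = 200L, cv_folds = 5L, seed = 1L,
                                n_iter = NULL) {
  X <- as.matrix(X)
  if (is.null(n_iter)) {
    n_iter <- cv_boost_iterations(X, y, max_iter, cv_folds, seed)
  }
  fit <- logitboost_path(X, y, n_iter)
  structure(list(beta0 = fit$beta0,
                 beta = stats::setNames(fit$beta, colnames(X)),
                 n_iter = n_iter),
            class = "simple_logistic")
}

cv_boost_iterations <- function(X, y, max_iter, cv_folds, seed) {
  if (length(unique(y)) < 2L || max_iter <= 1L) return(max_iter)
  folds <- with_seed(seed, stratified_folds(y, min(cv_folds, min(table(y)))))
  err <- numeric(max_iter)
  for (k in unique(folds)) {
    te <- folds == k
    fit <- logitboost_path(X[!te, , drop = FALSE], y[!te], max_iter,
                           X[te, , drop = FALSE], y[te])
    err <- err + fit$test_err
  }
  which.min(err)  # first minimum = fewest iterations among ties
}

predict_simple_logistic <- function(fit, X) {
  f <- fit$beta0 + as.numeric(as.matrix(X[, names(fit$beta), drop = FALSE]) %*% fit$beta)
  1 / (1 + exp(-2 * f))
}

# Stratified fold assignment: within each class, shuffle and deal fold ids
# round-robin. Returns an integer vector aligned with y.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}
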