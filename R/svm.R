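# Linear soft-margin classifier (squared-hinge primal), deterministic.
#
# Minimises 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (x_i'w + b))^2 by BFGS
# with analytic gradients.  With d of order 16-512 and n of order 10^3 this
# is fast and has no solver randomness, which keeps nested cross-validation
# reproducible.

linsvm_fit <- function(X, y, C) {
  stopifnot(is.matrix(X), all(y %in% c(-1, 1)), length(y) == nrow(X))
  d <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- 1 - y * (X %*% w + b)
    viol <- pmax(m, 0)
    0.5 * sum(w^2) + C * sum(viol^2)
  }
  grd <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- as.vector(1 - y * (X %*% w + b))
    act <- m > 0
    gy <- numeric(length(y)); gy[act] <- -2 * C * m[act] * y[act]
    c(w + as.vector(crossprod(X, gy)), sum(gy))
  }
  fit <- optim(numeric(d + 1L), obj, grd, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L], value = fit$value,
       C = C)
}

linsvm_predict <- function(model, X) sign(as.vector(X %*% model$w + model$b))

# stratified fold assignment, deterministic given the current RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# inner CV over a C grid; returns the selected C (one-standard-error rule:
# smallest C -- strongest regularisation -- within 1 SE of the best mean
# accuracy, matching the intent of regularising strongly)
select_C <- function(X, y, C_grid, k_inner) {
  fold <- stratified_folds(y, k_inner)
  acc <- matrix(NA_real_, k_inner, length(C_grid))
  for (f in seq_len(k_inner)) {
    tr <- fold != f
    for (j in seq_along(C_grid)) {
      m <- linsvm_fit(X[tr, , drop = FALSE], y[tr], C_grid[j])
      acc[f, j] <- mean(linsvm_predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
  }
  mu <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(k_inner)
  best <- which.max(mu)
  ok <- which(mu >= mu[best] - se[best])
  C_grid[min(ok)]   # grid is ascending: smallest C among near-ties
}
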