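# Brute-force dense evaluation of the mixed-model log-likelihood via the
# explicit marginal covariance V = sum_t s2_t Z_t Z_t' + s2 I. Written
# independently of the package's penalized least-squares route so the two
# can be compared; only suitable for small problems.
dense_deviance <- function(y, X, Zt_list, variances, sigma2, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2, n)
  for (i in seq_along(Zt_list)) {
    Z <- t(as.matrix(Zt_list[[i]]))
    V <- V + variances[i] * (Z %*% t(Z))
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ld_V <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (reml) {
    ld_X <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    ld_V + ld_X + quad + (n - p) * log(2 * pi)
  } else {
    ld_V + quad + n * log(2 * pi)
  }
}

# dense maximum-likelihood search over log-SD parameters (grid start +
# quasi-Newton polish), independent of the package optimizer
dense_optimum <- function(y, X, Zt_list, reml = TRUE,
                          grid = c(0.05, 0.2, 0.5, 1)) {
  k <- length(Zt_list)
  obj <- function(ls) {
    dv <- tryCatch(
      dense_deviance(y, X, Zt_list, exp(ls[seq_len(k)])^2, exp(ls[k + 1])^2,
                     reml),
      error = function(e) Inf)
    if (!is.finite(dv)) 1e10 else dv
  }
  best <- NULL
  for (s0 in grid) {
    op <- optim(log(rep(s0, k + 1)), obj, method = "L-BFGS-B",
                lower = -10, upper = 3, control = list(maxit = 500))
    if (is.null(best) || op$value < best$value) best <- op
  }
  list(variances = exp(best$par[seq_len(k)])^2,
       sigma2 = exp(best$par[k + 1])^2, deviance = best$value)
}
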