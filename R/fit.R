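## Profiled REML/ML estimation for the crossed random-intercepts model via
## penalized least squares with a sparse Cholesky factorization.
##
## With V = sum_t sigma_t^2 Z_t Z_t' + sigma^2 I and theta_t = sigma_t/sigma,
## write U = Z Lambda(theta). The penalized problem
##   min_{u,beta} ||y - X beta - U u||^2 + ||u||^2
## yields the profiled criteria (Bates et al.'s penalized least-squares
## route):
##   -2 L_ML(theta)   = log|L|^2 + n (1 + log(2 pi r^2 / n))
##   -2 L_REML(theta) = log|L|^2 + log|Rx|^2 + (n-p)(1 + log(2 pi r^2/(n-p)))
## where LL' = Lambda'Z'Z Lambda + I, Rx'Rx = X'X - Rzx'Rzx, and r^2 is the
## penalized residual sum of squares at the conditional optimum. sigma^2 is
## profiled out analytically; the log-SD parameterization keeps all
## variances positive, with log(theta) <= -12 treated as the boundary.

.sv_log_theta_bound <- -12

## stateful evaluator: precomputes crossproducts and the symbolic Cholesky
## pattern once, then factorizes in place for each theta
make_pls <- function(design) {
  X <- design$X
  y <- design$y
  Ut <- do.call(rbind, design$Zt)
  n <- design$n_obs
  p <- ncol(X)
  block_sizes <- design$block_cols
  k <- length(block_sizes)
  zero_block <- vapply(design$Zt, function(z) all(z@x == 0) || length(z@x) == 0L,
                       TRUE)
  XtX <- as.matrix(crossprod(X))
  Xty <- as.matrix(crossprod(X, y))
  yty <- sum(y^2)
  q <- sum(block_sizes)
  row_block <- rep(seq_len(k), block_sizes)  # block id of each U-row

  ## small designs: plain dense linear algebra (no permutation needed);
  ## avoids per-call S4 dispatch overhead that dominates at this size
  if (q <= 800 && n <= 5000) {
    Ztd <- as.matrix(Ut)
    ZtZ <- tcrossprod(Ztd)
    ZtX <- Ztd %*% X
    Zty <- as.vector(Ztd %*% y)
    eval_theta_dense <- function(theta) {
      Dg <- theta[row_block]
      A <- ZtZ * outer(Dg, Dg)
      diag(A) <- diag(A) + 1
      R <- chol(A)
      cu <- backsolve(R, Dg * Zty, transpose = TRUE)
      RZX <- backsolve(R, Dg * ZtX, transpose = TRUE)
      RXtRX <- XtX - crossprod(RZX)
      Rx <- chol(RXtRX)
      beta <- backsolve(Rx, forwardsolve(t(Rx), Xty - crossprod(RZX, cu)))
      u <- backsolve(R, cu - RZX %*% beta)
      fitted <- as.vector(X %*% beta) + as.vector(crossprod(Ztd, Dg * u))
      prss <- sum((y - fitted)^2) + sum(u^2)
      list(ldL2 = 2 * sum(log(diag(R))), ldRX2 = 2 * sum(log(diag(Rx))),
           prss = prss, beta = as.numeric(beta), RXtRX = RXtRX,
           u = as.numeric(u), fitted = fitted)
    }
    return(list(eval_theta = eval_theta_dense, n = n, p = p, k = k,
                block_sizes = block_sizes, zero_block = zero_block,
                term_names = names(design$Zt), yty = yty))
  }

  symb <- Matrix::Cholesky(Matrix::tcrossprod(Ut), LDL = FALSE, Imult = 1)

  eval_theta <- function(theta) {
    sc <- theta[row_block]
    SUt <- Ut
    SUt@x <- SUt@x * sc[SUt@i + 1L]
    L <- Matrix::update(symb, SUt, mult = 1)
    cu <- Matrix::solve(L, Matrix::solve(L, SUt %*% y, system = "P"),
                        system = "L")
    RZX <- Matrix::solve(L, Matrix::solve(L, SUt %*% X, system = "P"),
                         system = "L")
    RXtRX <- as.matrix(XtX - crossprod(RZX))
    Rx <- chol(RXtRX)
    beta <- backsolve(Rx, forwardsolve(t(Rx), Xty - as.matrix(crossprod(RZX, cu))))
    u <- Matrix::solve(L, Matrix::solve(L, cu - RZX %*% beta, system = "Lt"),
                       system = "Pt")
    fitted <- as.vector(X %*% beta) + as.vector(crossprod(SUt, u))
    prss <- sum((y - fitted)^2) + sum(u@x^2)
    list(ldL2 = 2 * as.numeric(Matrix::determinant(L, sqrt = TRUE)$modulus),
         ldRX2 = 2 * sum(log(diag(Rx))),
         prss = prss, beta = as.numeric(beta), RXtRX = RXtRX,
         u = as.numeric(u), fitted = fitted)
  }

  list(eval_theta = eval_theta, n = n, p = p, k = k,
       block_sizes = block_sizes, zero_block = zero_block,
       term_names = names(design$Zt), yty = yty)
}

## profiled deviance (-2 log lik) as a function of theta; +Inf when the
## factorization degenerates (extreme theta), so searches step back inward
profiled_deviance <- function(pls, theta, reml = TRUE) {
  e <- tryCatch(pls$eval_theta(theta), error = function(err) NULL)
  if (is.null(e)) return(Inf)
  n <- pls$n; p <- pls$p
  if (e$prss <= 0) return(-Inf)
  if (reml)
    e$ldL2 + e$ldRX2 + (n - p) * (1 + log(2 * pi * e$prss / (n - p)))
  else
    e$ldL2 + n * (1 + log(2 * pi * e$prss / n))
}

## deviance on the explicit variance scale (sigma^2 not profiled); used by
## profile-likelihood intervals. `variances` ordered as the random terms,
## `sigma2` is the residual variance.
explicit_deviance <- function(pls, variances, sigma2, reml = TRUE) {
  theta <- sqrt(pmax(variances, 0) / sigma2)
  e <- tryCatch(pls$eval_theta(theta), error = function(err) NULL)
  if (is.null(e)) return(Inf)
  n <- pls$n; p <- pls$p
  df <- if (reml) n - p else n
  base <- e$ldL2 + df * log(2 * pi * sigma2) + e$prss / sigma2
  if (reml) base + e$ldRX2 else base
}

#' Evaluate the mixed-model deviance at given variance components
#'
#' Returns the -2 log-likelihood (ML) or -2 restricted log-likelihood
#' (REML) of the crossed random-intercepts model at user-supplied variance
#' components, without optimizing. Mostly useful for diagnostics and for
#' validating the profiled estimation path.
#'
#' @param design an [build_design()] result.
#' @param variances named or positional numeric vector, one variance per
#'   random term in the design (order of `names(design$Zt)`).
#' @param sigma2 residual variance (> 0).
#' @param criterion `"reml"` or `"ml"`.
#' @return scalar deviance.
#' @export
lmm_deviance <- function(design, variances, sigma2, criterion = c("reml", "ml")) {
  criterion <- match.arg(criterion)
  stopifnot(length(variances) == length(design$Zt), sigma2 > 0)
  pls <- make_pls(design)
  explicit_deviance(pls, as.numeric(variances), sigma2,
                    reml = criterion == "reml")
}

## quasi-Newton optimization of the profiled deviance over log(theta) with
## seeded random restarts; zero blocks (unidentified variances) are pinned
## at the boundary
optimize_theta <- function(pls, reml, restarts = 3L, seed = 1L, start = NULL) {
  k <- pls$k
  free <- which(!pls$zero_block)
  fixed_lt <- rep(.sv_log_theta_bound, k)
  if (!length(free)) {
    return(list(theta = exp(fixed_lt), value = profiled_deviance(pls, exp(fixed_lt), reml),
                converged = TRUE, counts = 0L))
  }
  obj <- function(lt_free) {
    lt <- fixed_lt
    lt[free] <- lt_free
    dv <- profiled_deviance(pls, exp(lt), reml)
    if (!is.finite(dv)) 1e10 else dv   # L-BFGS-B needs finite values
  }
  starts <- list(if (is.null(start)) rep(-0.5, length(free))
                 else pmax(pmin(log(start[free]), 8), .sv_log_theta_bound))
  if (restarts > 0) {
    extra <- with_local_seed(seed, lapply(seq_len(restarts), function(i)
      runif(length(free), min = -3, max = 1)))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = .sv_log_theta_bound, upper = 8,
            control = list(factr = 1e8, maxit = 200)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop_sv("variance-parameter optimization failed from every start")
  lt <- fixed_lt
  lt[free] <- best$par
  list(theta = exp(lt), value = best$value,
       converged = best$convergence == 0, counts = best$counts[1],
       message = best$message %||% "")
}

#' Fit the crossed random-intercepts model
#'
#' Estimates the variance components of the trait/indicator/state/residual
#' decomposition (plus any genotype-variance interaction terms) by
#' maximizing the profiled REML (default) or ML criterion over log-SD
#' parameters with a quasi-Newton optimizer and seeded random restarts.
#' Fixed effects come from generalized least squares at the optimum, with
#' large-sample normal p-values. Variance estimates at the boundary of the
#' parameter space are reported as exact zeros with a `boundary` flag.
#'
#' @param design an [build_design()] result.
#' @param criterion `"reml"` (default; used for variance components) or
#'   `"ml"`.
#' @param restarts number of additional seeded random starts (default 3).
#' @param seed integer seed for the restart draws (restored afterwards).
#' @param start optional numeric vector of starting relative SDs
#'   (`sigma_t/sigma`), one per random term.
#' @param compute_aic if `TRUE` (default) and `criterion = "reml"`, a
#'   warm-started ML fit is run to obtain the ML-based AIC.
#' @return object of class `sv_fit`; see Details.
#' @details The returned object contains `betas` (data frame with
#'   `estimate`, `se`, `z`, `p_value`), `components` (data frame with
#'   `component`, `var`, `sd`, `share`, `boundary`), `loglik` (the
#'   optimized criterion's log-likelihood), `aic`, `converged`, `n_obs`,
#'   `n_individuals`, and bookkeeping needed by [profile_ci()].
#' @export
fit_lmm <- function(design, criterion = c("reml", "ml"), restarts = 3L,
                    seed = 1L, start = NULL, compute_aic = TRUE) {
  criterion <- match.arg(criterion)
  reml <- criterion == "reml"
  stopifnot(inherits(design, "sv_design"))
  n <- design$n_obs; p <- design$p
  npar <- p + length(design$Zt) + 1L
  if (n < npar)
    stop_sv("more parameters (", npar, ") than observations (", n, ")")

  pls <- make_pls(design)

  ## degenerate input: response perfectly fit by X alone
  ols <- qr(design$X)
  if (sum(qr.resid(ols, design$y)^2) < 1e-12 * max(1, pls$yty)) {
    beta <- qr.coef(ols, design$y)
    comp <- data.frame(component = c(pls$term_names, "residual"),
                       var = 0, sd = 0, share = NA_real_, boundary = TRUE,
                       stringsAsFactors = FALSE)
    betas <- data.frame(term = colnames(design$X), estimate = as.numeric(beta),
                        se = NA_real_, z = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
    return(structure(list(betas = betas, components = comp,
                          loglik = NA_real_, deviance = NA_real_,
                          aic = NA_real_, criterion = criterion,
                          converged = TRUE, boundary = TRUE, degenerate = TRUE,
                          n_obs = n, n_individuals = design$n_individuals,
                          n_params = npar, theta = rep(0, length(design$Zt)),
                          sigma2 = 0, design = design, pls = pls,
                          obs_id = design$obs_id),
                     class = "sv_fit"))
  }

  opt <- optimize_theta(pls, reml, restarts = restarts, seed = seed,
                        start = start)
  theta <- opt$theta
  e <- pls$eval_theta(theta)
  df <- if (reml) n - p else n
  sigma2 <- e$prss / df
  boundary <- theta <= exp(.sv_log_theta_bound) * (1 + 1e-8) | pls$zero_block
  vars <- theta^2 * sigma2
  vars[boundary] <- 0

  comp_names <- c(pls$term_names, "residual")
  all_vars <- c(vars, sigma2)
  comp <- data.frame(component = comp_names, var = all_vars,
                     sd = sqrt(all_vars),
                     share = 100 * all_vars / sum(all_vars),
                     boundary = c(boundary, FALSE), stringsAsFactors = FALSE)

  se <- sqrt(sigma2 * diag(solve(e$RXtRX)))
  z <- e$beta / se
  betas <- data.frame(term = colnames(design$X), estimate = e$beta, se = se,
                      z = z, p_value = 2 * pnorm(-abs(z)),
                      stringsAsFactors = FALSE)

  dev <- opt$value
  aic <- NA_real_
  ml_loglik <- NA_real_
  if (!reml) {
    aic <- dev + 2 * npar
    ml_loglik <- -dev / 2
  } else if (compute_aic) {
    mlopt <- optimize_theta(pls, reml = FALSE, restarts = 0L, seed = seed,
                            start = theta)
    aic <- mlopt$value + 2 * npar
    ml_loglik <- -mlopt$value / 2
  }

  structure(list(
    betas = betas, components = comp,
    loglik = -dev / 2, deviance = dev, aic = aic, ml_loglik = ml_loglik,
    criterion = criterion, converged = opt$converged,
    boundary = any(boundary), degenerate = FALSE,
    n_obs = n, n_individuals = design$n_individuals, n_params = npar,
    theta = theta, sigma2 = sigma2, design = design, pls = pls,
    obs_id = design$obs_id, optimizer = opt[c("counts", "message")]
  ), class = "sv_fit")
}

#' @exportS3Method base::print
print.sv_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<sv_fit> %s fit: %d observations, %d individuals\n",
              toupper(x$criterion), x$n_obs, x$n_individuals))
  if (!x$converged) cat("  ** optimizer did not report convergence **\n")
  cat("\nFixed effects:\n")
  b <- x$betas
  b[-1] <- lapply(b[-1], signif, digits)
  print(b, row.names = FALSE)
  cat("\nVariance components:\n")
  cm <- x$components
  cm$var <- signif(cm$var, digits); cm$sd <- signif(cm$sd, digits)
  cm$share <- round_half_away(cm$share, 1)
  print(cm[c("component", "var", "sd", "share")], row.names = FALSE)
  cat(sprintf("\nlogLik (%s): %.3f   AIC (ML): %.3f\n", x$criterion,
              x$loglik, x$aic))
  invisible(x)
}

#' @exportS3Method stats::logLik
logLik.sv_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}
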