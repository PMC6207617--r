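## Post-fit inference: variance shares, profile-likelihood (and parametric
## bootstrap) intervals for variance components, ML-based AIC comparison,
## genotype-moderated variance models, and per-indicator genotype tests.

#' Variance shares (Var%)
#'
#' Each component's percentage of the total of all variance components in
#' the fitted model (including any genotype-variance interaction terms and
#' the residual), rounded half-away-from-zero.
#'
#' @param components an `sv_fit`, the `components` data frame of one, or a
#'   named numeric vector of variances.
#' @param decimals decimal places for the rounded share (default 1).
#' @return data frame with `component`, `var`, `share`.
#' @export
#' @examples
#' variance_shares(c(trait = 0.212, indicator = 0.387,
#'                   state = 0.048, residual = 0.298))
variance_shares <- function(components, decimals = 1) {
  if (inherits(components, "sv_fit")) components <- components$components
  if (is.data.frame(components)) {
    v <- components$var
    nm <- components$component
  } else {
    v <- as.numeric(components)
    nm <- names(components) %||% paste0("component_", seq_along(v))
  }
  if (any(v < 0)) stop_sv("variances must be nonnegative")
  tot <- sum(v)
  if (tot == 0) stop_sv("all components are zero; shares are undefined")
  data.frame(component = nm, var = v,
             share = round_half_away(100 * v / tot, decimals),
             stringsAsFactors = FALSE)
}

## deviance profile for one component with all other variances re-optimized
make_profiler <- function(fit) {
  pls <- fit$pls
  reml <- fit$criterion == "reml"
  k <- pls$k
  vhat <- fit$components$var          # k random terms then residual
  lsd_hat <- log(pmax(sqrt(vhat), 1e-8))
  function(target_idx) {
    free <- setdiff(seq_len(k + 1L), target_idx)
    free <- free[!c(pls$zero_block, FALSE)[free]]
    warm <- lsd_hat[free]
    function(v) {
      full <- vhat
      full[target_idx] <- v
      obj <- function(lsd) {
        full[free] <- exp(lsd)^2
        if (full[k + 1L] <= 0) return(1e10)
        dv <- explicit_deviance(pls, full[seq_len(k)], full[k + 1L], reml)
        if (!is.finite(dv)) 1e10 else dv   # keep L-BFGS-B on finite ground
      }
      op <- optim(warm, obj, method = "L-BFGS-B", lower = -12, upper = 5,
                  control = list(factr = 1e9, maxit = 100))
      warm <<- op$par                 # continuation along the profile
      op$value
    }
  }
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Bounds are the values of the component's variance at which the REML (or
#' ML) deviance, re-profiled over all other variance parameters, rises by
#' the chi-square(1) quantile above its minimum. The lower bound is
#' truncated at 0. A parametric-bootstrap percentile interval is available
#' as an alternative.
#'
#' @param fit an [fit_lmm()] result (converged).
#' @param component component name: one of the fit's random terms or
#'   `"residual"`.
#' @param level confidence level (default 0.95).
#' @param method `"profile"` (default) or `"boot"`.
#' @param nsim bootstrap replicates when `method = "boot"` (default 200).
#' @param seed seed for the bootstrap draws.
#' @param tol root-finding tolerance on the SD scale; defaults to 1/1000 of
#'   the component's scale. Coarser values speed up simulation studies.
#' @return named numeric `c(lower, upper)` on the variance scale.
#' @export
profile_ci <- function(fit, component, level = 0.95,
                       method = c("profile", "boot"), nsim = 200L, seed = 1L,
                       tol = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "sv_fit"))
  if (fit$degenerate) stop_sv("cannot profile a degenerate (zero-variance) fit")
  if (!fit$converged) warning("profiling a fit that did not report convergence",
                              call. = FALSE)
  comp_names <- fit$components$component
  idx <- match(component, comp_names)
  if (is.na(idx)) stop_sv("unknown component '", component, "'; available: ",
                          paste(comp_names, collapse = ", "))
  if (method == "boot") return(boot_ci(fit, idx, level, nsim, seed))

  k <- fit$pls$k
  vhat <- fit$components$var[idx]
  cutoff <- fit$deviance + qchisq(level, df = 1)
  prof <- make_profiler(fit)(idx)
  is_residual <- idx == k + 1L
  ## work on the SD scale for better-conditioned search steps
  s_hat <- sqrt(vhat)
  scale0 <- max(s_hat, sqrt(fit$sigma2) * 0.05, 1e-4)
  tol <- tol %||% (scale0 * 1e-3)
  g <- function(s) prof(s^2) - cutoff

  upper <- NA_real_
  s_hi <- max(s_hat, scale0) * 1.2
  prev <- s_hat
  for (i in 1:60) {
    if (g(s_hi) > 0) { upper <- uniroot(g, c(prev, s_hi), tol = tol)$root^2; break }
    prev <- s_hi; s_hi <- s_hi * 1.35
  }
  if (is.na(upper))
    warning("upper profile bound not bracketed; returning one-sided interval",
            call. = FALSE)

  lower <- 0
  if (s_hat > 0) {
    ## step down multiplicatively until the deviance crosses the cutoff;
    ## for a random term that never crosses, the bound truncates at 0
    s_lo <- s_hat / 1.35
    prev <- s_hat
    crossed <- FALSE
    for (i in 1:60) {
      gv <- g(s_lo)
      if (is.finite(gv) && gv > 0) {
        lower <- uniroot(g, c(s_lo, prev), tol = tol)$root^2
        crossed <- TRUE
        break
      }
      if (!is.finite(gv) || s_lo < s_hat * 1e-3) break
      prev <- s_lo; s_lo <- s_lo / 1.35
    }
    if (!crossed) {
      if (!is_residual && g(0) <= 0) lower <- 0
      else if (is_residual)
        warning("lower profile bound not bracketed above 0; returning 0",
                call. = FALSE)
    }
  }
  c(lower = lower, upper = upper)
}

## simulate a response vector from a fitted model's estimates
simulate_from_fit <- function(fit) {
  d <- fit$design
  y <- as.vector(d$X %*% fit$betas$estimate)
  vars <- fit$components$var          # k random terms then residual
  for (i in seq_along(d$Zt)) {
    if (vars[i] <= 0) next
    b <- rnorm(nrow(d$Zt[[i]]), 0, sqrt(vars[i]))
    y <- y + as.vector(Matrix::crossprod(d$Zt[[i]], b))
  }
  y + rnorm(d$n_obs, 0, sqrt(vars[length(d$Zt) + 1L]))
}

boot_ci <- function(fit, idx, level, nsim, seed) {
  d <- fit$design
  vals <- with_local_seed(seed, vapply(seq_len(nsim), function(i) {
    d2 <- d
    d2$y <- simulate_from_fit(fit)
    f <- fit_lmm(d2, criterion = fit$criterion, restarts = 0L,
                 start = pmax(fit$theta, 0.05), compute_aic = FALSE)
    f$components$var[idx]
  }, 0))
  q <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = max(0, q[1]), upper = q[2])
}

#' Compare two maximum-likelihood fits by AIC
#'
#' @param fit_a,fit_b `sv_fit` objects fitted by ML on the identical set of
#'   observations.
#' @return list with `preferred` (the winning fit's model spec), `which`
#'   (`"a"` or `"b"`), and `delta_aic` (`aic_a - aic_b`).
#' @export
compare_aic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "sv_fit"), inherits(fit_b, "sv_fit"))
  if (fit_a$criterion != "ml" || fit_b$criterion != "ml")
    stop_sv("compare_aic requires ML fits (criterion = 'ml')")
  if (fit_a$n_obs != fit_b$n_obs ||
      !identical(sort(fit_a$obs_id), sort(fit_b$obs_id)))
    stop_sv("fits are on different observation sets; AIC is not comparable")
  delta <- fit_a$aic - fit_b$aic
  which <- if (delta <= 0) "a" else "b"
  list(preferred = (if (which == "a") fit_a else fit_b)$design$spec,
       which = which, delta_aic = delta)
}

#' Fit genotype-moderated variance (GxE) models
#'
#' For each genotype covariate (by default the cumulative 0-4 risk score
#' and each single SNP's 0/1 risk flag), fits the base model augmented with
#' the covariate as a fixed effect and with three genotype-scaled variance
#' terms -- one per base random term -- so that carriers (or higher risk
#' scores) can have inflated variance at the trait, indicator, or state
#' level. Individuals without the covariate are dropped (available-case);
#' a warning is issued if fewer than 90% of individuals carry it.
#'
#' @param observations person-observation table (standardized scores).
#' @param genotypes genotype table with risk coding (see
#'   [read_genotypes()] / [add_risk_coding()]).
#' @param covariates character vector of genotype covariate columns;
#'   default `risk_score` plus the four per-SNP flags.
#' @param criterion,restarts,seed passed to [fit_lmm()].
#' @return named list of `sv_fit` objects.
#' @export
fit_gxe_models <- function(observations, genotypes,
                           covariates = c("risk_score",
                                          paste0("risk_", names(snp_panel()))),
                           criterion = "reml", restarts = 3L, seed = 1L) {
  fits <- list()
  ids <- unique(as.character(observations$individual_id))
  for (cv in covariates) {
    if (!cv %in% names(genotypes))
      stop_sv("genotype table lacks covariate '", cv, "'")
    x <- genotypes[[cv]][match(ids, as.character(genotypes$individual_id))]
    covered <- mean(!is.na(x))
    if (covered < 0.9)
      warning(sprintf("covariate %s defined for only %.1f%% of individuals",
                      cv, 100 * covered), call. = FALSE)
    vals <- unique(x[!is.na(x)])
    gxe <- list()
    if (length(vals) < 2) {
      warning("covariate ", cv, " is degenerate (single value); ",
              "genotype-variance terms skipped", call. = FALSE)
    } else {
      gxe <- lapply(.sv_random_terms, function(tm)
        list(covariate = cv, term = tm))
    }
    spec <- model_spec(fixed = c("intercept", "age", "gender", cv, "wave"),
                       random = .sv_random_terms, gxe = gxe)
    des <- build_design(observations, genotypes, spec)
    fits[[cv]] <- fit_lmm(des, criterion = criterion, restarts = restarts,
                          seed = seed)
  }
  fits
}

#' Per-indicator genotype association test
#'
#' Tests one SNP's risk-group contrast against one indicator's
#' standardized longitudinal scores, using a mixed model with an
#' individual random intercept, age/gender/wave covariates, and a
#' sum-to-zero coded genotype group (+1 risk group, -1 other group), so
#' the two reported group deviations are equal and opposite. The contrast
#' is a 1-numerator-df Wald F with residual denominator degrees of freedom
#' `n_obs - rank(X)`.
#'
#' @param observations person-observation table (standardized scores).
#' @param genotypes genotype table with risk coding.
#' @param snp SNP identifier (see [snp_panel()]).
#' @param indicator indicator name to test.
#' @param criterion,restarts,seed passed to [fit_lmm()].
#' @return object of class `sv_assoc`: list with `groups` (per-group
#'   deviation estimates and SE, risk group first), `F`, `df`, `p_value`,
#'   `snp`, `indicator`, `n_obs`, and `warnings`.
#' @export
test_indicator_association <- function(observations, genotypes, snp,
                                       indicator, criterion = "reml",
                                       restarts = 1L, seed = 1L) {
  info <- snp_panel()[[snp]] %||% stop_sv("unknown SNP '", snp, "'")
  flag_col <- paste0("risk_", snp)
  if (!flag_col %in% names(genotypes))
    stop_sv("genotype table lacks column '", flag_col,
            "'; run add_risk_coding() first")
  obs <- observations[observations$indicator == indicator, , drop = FALSE]
  if (!nrow(obs)) stop_sv("no observations for indicator '", indicator, "'")
  flag <- genotypes[[flag_col]][match(as.character(obs$individual_id),
                                      as.character(genotypes$individual_id))]
  obs$g_sum <- ifelse(flag == 1L, 1, -1)   # sum-to-zero group coding

  warnings <- character()
  n_by_group <- tapply(obs$individual_id, flag,
                       function(id) length(unique(id)))
  small <- n_by_group < 10
  if (any(small, na.rm = TRUE)) {
    w <- sprintf("genotype group(s) with <10 individuals: %s",
                 paste(names(n_by_group)[which(small)], collapse = ", "))
    warning(w, call. = FALSE)
    warnings <- c(warnings, w)
  }

  spec <- model_spec(fixed = c("intercept", "age", "gender", "wave", "g_sum"),
                     random = "individual")
  des <- build_design(obs, genotypes = NULL, spec)
  fit <- fit_lmm(des, criterion = criterion, restarts = restarts, seed = seed)
  row <- fit$betas[fit$betas$term == "g_sum", ]
  Fval <- (row$estimate / row$se)^2
  ddf <- fit$n_obs - fit$design$p
  pval <- pf(Fval, 1, ddf, lower.tail = FALSE)

  pairs <- apply(utils::combn(rep(info$alleles, 2), 2), 2,
                 function(a) paste(sort(a), collapse = ""))
  risk_label <- paste(sort(unique(info$risk)), collapse = "/")
  other_label <- paste(sort(setdiff(unique(pairs), info$risk)), collapse = "/")

  structure(list(
    groups = data.frame(
      group = c(risk_label, other_label), risk = c(TRUE, FALSE),
      estimate = c(row$estimate, -row$estimate), se = rep(row$se, 2),
      stringsAsFactors = FALSE),
    F = Fval, df = c(1L, ddf), p_value = pval,
    snp = snp, indicator = indicator, n_obs = fit$n_obs,
    fit = fit, warnings = warnings
  ), class = "sv_assoc")
}

#' @exportS3Method base::print
print.sv_assoc <- function(x, digits = 3, ...) {
  cat(sprintf("<sv_assoc> %s vs %s (n_obs = %d)\n", x$snp, x$indicator,
              x$n_obs))
  g <- x$groups
  g$estimate <- signif(g$estimate, digits); g$se <- signif(g$se, digits)
  print(g, row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g\n", x$df[1], x$df[2], x$F,
              x$p_value))
  invisible(x)
}
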