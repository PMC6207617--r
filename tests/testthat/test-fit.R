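test_that("penalized least-squares criterion equals the dense V-matrix form", {
  # 10 individuals x 2 indicators x 2 waves = 40 observations <= 60
  sim <- simulate_cohort(mini_config(n_individuals = 10, seed = 11))
  d <- build_design(sim$observations, spec = model_spec())
  expect_lte(d$n_obs, 60)
  set.seed(5)
  for (i in 1:6) {
    vars <- runif(3, 0.02, 0.8)
    s2 <- runif(1, 0.05, 0.8)
    for (crit in c("reml", "ml")) {
      expect_equal(
        lmm_deviance(d, vars, s2, crit),
        dense_deviance(d$y, d$X, d$Zt, vars, s2, reml = crit == "reml"),
        tolerance = 1e-8)
    }
  }
})

test_that("the optimizer lands on the dense brute-force optimum", {
  sim <- simulate_cohort(mini_config(n_individuals = 10, seed = 12))
  d <- build_design(sim$observations, spec = model_spec())
  f <- fit_lmm(d, restarts = 2, compute_aic = FALSE)
  oracle <- dense_optimum(d$y, d$X, d$Zt, reml = TRUE)
  # agreement to 1e-4 on each variance (absolute scale)
  expect_lt(max(abs(f$components$var[1:3] - oracle$variances)), 1e-4)
  expect_lt(abs(f$components$var[4] - oracle$sigma2), 1e-4)
  expect_equal(f$deviance, oracle$deviance, tolerance = 1e-6)
})

test_that("balanced one-way layouts reproduce the ANOVA closed form", {
  # groups {(0,2), (4,6)}: MSB = 16, MSW = 2 -> between 7, within 2
  obs <- one_way_obs(list(A = c(0, 2), B = c(4, 6)))
  d <- build_design(obs, spec = model_spec(fixed = "intercept",
                                           random = "individual"))
  f <- fit_lmm(d, restarts = 1, compute_aic = FALSE)
  expect_equal(f$components$var[1], 7, tolerance = 1e-5)
  expect_equal(f$components$var[2], 2, tolerance = 1e-5)
  expect_equal(f$betas$estimate[1], 3, tolerance = 1e-8)

  # a larger balanced layout against the method-of-moments estimator
  set.seed(31)
  vals <- lapply(1:8, function(i) rnorm(5, mean = rnorm(1, 0, 2)))
  names(vals) <- paste0("g", 1:8)
  m <- sapply(vals, mean); obs2 <- one_way_obs(vals)
  msb <- 5 * var(m)
  msw <- mean(sapply(vals, var))
  d2 <- build_design(obs2, spec = model_spec(fixed = "intercept",
                                             random = "individual"))
  f2 <- fit_lmm(d2, restarts = 1, compute_aic = FALSE)
  expect_equal(f2$components$var[1], (msb - msw) / 5, tolerance = 1e-5)
  expect_equal(f2$components$var[2], msw, tolerance = 1e-5)
})

test_that("a constant response degenerates to zero variances", {
  obs <- one_way_obs(list(A = c(2, 2), B = c(2, 2)))
  d <- build_design(obs, spec = model_spec(fixed = "intercept",
                                           random = "individual"))
  f <- fit_lmm(d)
  expect_true(f$degenerate)
  expect_true(all(f$components$var == 0))
  expect_equal(f$betas$estimate[1], 2)
})

test_that("row permutation leaves the fit invariant", {
  sim <- simulate_cohort(mini_config(n_individuals = 15, seed = 13))
  d1 <- build_design(sim$observations, spec = model_spec())
  set.seed(1)
  perm <- sample(nrow(sim$observations))
  d2 <- build_design(sim$observations[perm, ], spec = model_spec())
  f1 <- fit_lmm(d1, restarts = 0, compute_aic = FALSE)
  f2 <- fit_lmm(d2, restarts = 0, compute_aic = FALSE)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-10)
  expect_equal(f1$betas$estimate, f2$betas$estimate, tolerance = 1e-10)
  expect_equal(f1$components$var, f2$components$var, tolerance = 1e-8)
})

test_that("estimates agree with an independent mixed-model implementation", {
  sim <- simulate_cohort(mini_config(n_individuals = 60,
                                     n_indicators = 3,
                                     waves = c(1997, 2001, 2007), seed = 14))
  d <- build_design(sim$observations, spec = model_spec())
  f <- fit_lmm(d, restarts = 1, compute_aic = FALSE)

  df <- sim$observations
  df$wave <- df$wave_year - 1997
  m <- lme4::lmer(
    score_std ~ age + gender + wave + (1 | individual_id) +
      (1 | individual_id:indicator) + (1 | individual_id:wave_year),
    data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(m))
  ref <- c(individual = vc$vcov[vc$grp == "individual_id"],
           indicator = vc$vcov[vc$grp == "individual_id:indicator"],
           wave = vc$vcov[vc$grp == "individual_id:wave_year"],
           residual = vc$vcov[vc$grp == "Residual"])
  expect_equal(f$deviance, -2 * as.numeric(logLik(m)), tolerance = 1e-5)
  expect_equal(f$components$var[1], ref[["individual"]], tolerance = 1e-3)
  expect_equal(f$components$var[2], ref[["indicator"]], tolerance = 1e-3)
  expect_equal(f$components$var[3], ref[["wave"]], tolerance = 1e-3)
  expect_equal(f$components$var[4], ref[["residual"]], tolerance = 1e-3)
  expect_equal(f$betas$estimate, unname(lme4::fixef(m)), tolerance = 1e-5)
  expect_equal(f$betas$se,
               unname(summary(m)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
})

test_that("a genotype-scaled variance model matches lme4's random-slope form", {
  cfg <- mini_config(n_individuals = 80, n_indicators = 3,
                     waves = c(1997, 2001, 2007), seed = 15,
                     gxe = list(list(covariate = "risk_rs2254298",
                                     term = "individual:indicator",
                                     xi_var = 0.3)))
  sim <- simulate_cohort(cfg)
  spec <- model_spec(
    fixed = c("intercept", "age", "gender", "risk_rs2254298", "wave"),
    gxe = list(list(covariate = "risk_rs2254298",
                    term = "individual:indicator")))
  d <- build_design(sim$observations, sim$genotypes, spec)
  f <- fit_lmm(d, restarts = 1, compute_aic = FALSE)

  df <- merge(sim$observations,
              sim$genotypes[c("individual_id", "risk_rs2254298")],
              by = "individual_id")
  df$wave <- df$wave_year - 1997
  m <- lme4::lmer(
    score_std ~ age + gender + risk_rs2254298 + wave + (1 | individual_id) +
      (1 | individual_id:indicator) + (1 | individual_id:wave_year) +
      (0 + risk_rs2254298 | individual_id:indicator),
    data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(f$deviance, -2 * as.numeric(logLik(m)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  xi_ref <- vc$vcov[vc$var1 == "risk_rs2254298" & !is.na(vc$var1)]
  xi_hat <- f$components$var[f$components$component ==
                               "risk_rs2254298 x individual:indicator"]
  expect_equal(xi_hat, xi_ref, tolerance = 5e-3)
})

test_that("AIC is definitional and fit guards against overparameterization", {
  sim <- simulate_cohort(mini_config(n_individuals = 20, seed = 16))
  d <- build_design(sim$observations, spec = model_spec())
  f <- fit_lmm(d, criterion = "ml", restarts = 1)
  expect_equal(f$aic, -2 * f$ml_loglik + 2 * f$n_params)
  fr <- fit_lmm(d, criterion = "reml", restarts = 1)  # warm-started ML AIC
  expect_equal(fr$aic, f$aic, tolerance = 1e-4)

  tiny <- sim$observations[1:6, ]
  expect_error(
    suppressWarnings(build_design(tiny, spec = model_spec())) |> fit_lmm(),
    "parameters")
})
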