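test_that("variance shares recompute the published worked examples", {
  # base model: trait/indicator/state/residual
  m1 <- variance_shares(c(trait = 0.212, indicator = 0.387, state = 0.048,
                          residual = 0.298))
  expect_equal(m1$share[m1$component == "residual"], 31.5)
  # risk-score model: same plus three genotype-variance terms
  m2 <- variance_shares(c(trait = 0.212, indicator = 0.370, state = 0.048,
                          residual = 0.298, g_trait = 0.000,
                          g_indicator = 0.004, g_state = 0.000))
  expect_equal(m2$share[m2$component == "indicator"], 39.7)
  # four equal components split evenly
  expect_equal(variance_shares(rep(0.1, 4))$share, rep(25, 4))
  expect_error(variance_shares(rep(0, 3)), "undefined")
  expect_error(variance_shares(c(-0.1, 0.5)), "nonnegative")
})

test_that("shares always sum to 100 within rounding", {
  set.seed(9)
  for (i in 1:50) {
    v <- runif(sample(2:7, 1), 0, 2)
    sh <- variance_shares(v, decimals = 1)$share
    expect_lt(abs(sum(sh) - 100), 0.05 * length(v))
  }
})

test_that("rounding is half-away-from-zero at the printed precision", {
  expect_equal(round_half_away(0.05, 1), 0.1)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(round_half_away(2.25, 1), 2.3)
  expect_equal(round_half_away(31.45, 1), 31.5)
  expect_equal(round_half_away(c(0.5, 1.5, 2.5), 0), c(1, 2, 3))
})

test_that("profile intervals bracket the estimate and respect the boundary", {
  sim <- simulate_cohort(mini_config(n_individuals = 60, n_indicators = 3,
                                     waves = c(1997, 2001, 2007), seed = 31))
  d <- build_design(sim$observations, spec = model_spec())
  f <- fit_lmm(d, restarts = 0, compute_aic = FALSE)
  for (comp in c("individual", "residual")) {
    ci <- profile_ci(f, comp)
    hat <- f$components$var[f$components$component == comp]
    expect_gte(ci[["lower"]], 0)
    expect_lt(ci[["lower"]], hat)
    expect_gt(ci[["upper"]], hat)
  }
  expect_error(profile_ci(f, "nonexistent"), "unknown component")
})

test_that("interval width shrinks stochastically with the sample size", {
  widths <- sapply(c(30, 120), function(n) {
    mean(sapply(1:3, function(s) {
      sim <- simulate_cohort(mini_config(n_individuals = n, seed = 40 + s))
      d <- build_design(sim$observations, spec = model_spec())
      f <- fit_lmm(d, restarts = 0, compute_aic = FALSE)
      ci <- suppressWarnings(profile_ci(f, "individual", tol = 0.005))
      ci[["upper"]] - ci[["lower"]]
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("parametric bootstrap intervals are ordered and nonnegative", {
  sim <- simulate_cohort(mini_config(n_individuals = 40, seed = 51))
  d <- build_design(sim$observations, spec = model_spec())
  f <- fit_lmm(d, restarts = 0, compute_aic = FALSE)
  ci <- profile_ci(f, "individual", method = "boot", nsim = 30, seed = 2)
  expect_gte(ci[["lower"]], 0)
  expect_gt(ci[["upper"]], ci[["lower"]])
})

test_that("AIC comparison prefers the generating model over noise terms", {
  expect_error(compare_aic(structure(list(criterion = "reml"),
                                     class = "sv_fit"),
                           structure(list(criterion = "reml"),
                                     class = "sv_fit")),
               "ML fits")
  prefer_true <- 0
  for (s in 1:9) {
    sim <- simulate_cohort(mini_config(n_individuals = 40, seed = 60 + s))
    obs <- sim$observations
    set.seed(1000 + s)
    noise <- rnorm(length(unique(obs$individual_id)))
    obs$noise_cov <- noise[match(obs$individual_id,
                                 unique(obs$individual_id))]
    f_true <- fit_lmm(build_design(obs, spec = model_spec()),
                      criterion = "ml", restarts = 0)
    f_noise <- fit_lmm(build_design(obs, spec = model_spec(
      fixed = c("intercept", "age", "gender", "wave", "noise_cov"))),
      criterion = "ml", restarts = 0)
    # identical models tie exactly
    expect_equal(compare_aic(f_true, f_true)$delta_aic, 0)
    if (compare_aic(f_true, f_noise)$which == "a") prefer_true <- prefer_true + 1
  }
  expect_gt(prefer_true, 4.5)  # majority of replicates

  # different observation sets are refused
  sim2 <- simulate_cohort(mini_config(n_individuals = 39, seed = 70))
  f_other <- fit_lmm(build_design(sim2$observations, spec = model_spec()),
                     criterion = "ml", restarts = 0)
  sim1 <- simulate_cohort(mini_config(n_individuals = 40, seed = 60))
  f_one <- fit_lmm(build_design(sim1$observations, spec = model_spec()),
                   criterion = "ml", restarts = 0)
  expect_error(compare_aic(f_one, f_other), "not comparable")
})

test_that("null genotype data leave the variance-interaction terms near zero", {
  sim <- simulate_cohort(mini_config(n_individuals = 200, n_indicators = 3,
                                     waves = c(1997, 2001, 2007), seed = 81))
  fits <- fit_gxe_models(sim$observations, sim$genotypes,
                         covariates = "risk_score", restarts = 1)
  comp <- fits$risk_score$components
  xi <- comp$var[grepl(" x ", comp$component)]
  expect_length(xi, 3)
  expect_true(all(xi < 0.02))
})

test_that("carrier-only indicator variance surfaces on the indicator term", {
  cfg <- mini_config(n_individuals = 250, n_indicators = 3,
                     waves = c(1997, 2001, 2007), seed = 82,
                     gxe = list(list(covariate = "risk_rs2254298",
                                     term = "individual:indicator",
                                     xi_var = 0.25)))
  sim <- simulate_cohort(cfg)
  fits <- fit_gxe_models(sim$observations, sim$genotypes,
                         covariates = "risk_rs2254298", restarts = 1)
  comp <- fits$risk_rs2254298$components
  xi <- setNames(comp$var[grepl(" x ", comp$component)],
                 comp$component[grepl(" x ", comp$component)])
  target <- "risk_rs2254298 x individual:indicator"
  expect_gt(xi[[target]], 0.08)
  expect_true(all(xi[setdiff(names(xi), target)] < xi[[target]]))

  # degenerate covariate: variance-interaction terms are skipped (and the
  # constant fixed column is dropped as collinear with the intercept)
  sim$genotypes$flat <- 1L
  w <- capture_warnings(
    fl <- fit_gxe_models(sim$observations, sim$genotypes,
                         covariates = "flat", restarts = 0))
  expect_true(any(grepl("degenerate", w)))
  expect_false(any(grepl(" x ", fl$flat$components$component)))
})

test_that("the per-indicator genotype test is a sum-to-zero 1-df contrast", {
  sim <- simulate_cohort(mini_config(n_individuals = 150, n_indicators = 3,
                                     waves = c(1997, 2001, 2007), seed = 91))
  a <- test_indicator_association(sim$observations, sim$genotypes,
                                  "rs53576", "IND2")
  expect_equal(sum(a$groups$estimate), 0, tolerance = 1e-12)
  expect_equal(a$groups$se[1], a$groups$se[2])
  expect_equal(a$df[1], 1L)
  expect_equal(a$df[2], a$n_obs - 5L)
  expect_equal(a$F, (a$groups$estimate[1] / a$groups$se[1])^2)
  expect_identical(a$groups$group, c("AA/AG", "GG"))

  # an additive effect planted on one indicator is found on that indicator
  sim2 <- simulate_cohort(mini_config(n_individuals = 250, n_indicators = 3,
                                      waves = c(1997, 2001, 2007), seed = 92))
  obs <- sim2$observations
  flag <- sim2$genotypes$risk_rs3796863[match(obs$individual_id,
                                              sim2$genotypes$individual_id)]
  obs$score_std <- obs$score_std +
    ifelse(obs$indicator == "IND1" & flag == 1, 0.5, 0)
  Fs <- sapply(paste0("IND", 1:3), function(ind)
    test_indicator_association(obs, sim2$genotypes, "rs3796863", ind)$F)
  expect_equal(names(which.max(Fs)), "IND1")

  # small groups attach a warning
  tiny <- simulate_cohort(mini_config(n_individuals = 12, seed = 93))
  expect_warning(
    test_indicator_association(tiny$observations, tiny$genotypes,
                               "rs1042778", "IND1"),
    "<10 individuals")
})
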