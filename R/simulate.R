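## Synthetic accelerated-longitudinal cohort generator. Emulates the study
## design the estimation engine targets: six 3-year-spaced birth cohorts,
## assessment waves 1997/2001/2007/2012, five sociability indicators (one
## fielded only at the last two waves), the crossed random-intercepts
## variance structure, gender/age/wave fixed effects, and oxytocin-pathway
## genotype frequencies.

## 2007 raw-score anchors (mean, SD) used for optional raw-metric emulation
.sv_raw_anchors <- list(
  "NEO-FFI-E" = c(3.39, 0.55),
  "TCI-RD1-Sentimentality" = c(3.05, 0.54),
  "TCI-RD3-SocialAttachment" = c(3.57, 0.74),
  "TCI-RD4-Dependence" = c(3.37, 0.54),
  "EAS-Sociability" = c(3.27, 0.72)
)

#' Configure a synthetic cohort simulation
#'
#' Defaults reproduce the reference study conditions: six birth cohorts at
#' 3-year spacing followed at four waves, five indicators with one
#' (NEO-FFI-E) restricted to the last two waves, generating variance
#' components and fixed effects set to the published Model-1 point
#' estimates, 59% women, and per-SNP risk-group frequencies matching the
#' published genotype prevalences.
#'
#' @param n_individuals number of individuals (default 1573, the analysed
#'   genotyped sample size).
#' @param birth_cohorts birth years, allocated evenly across individuals.
#' @param waves assessment years (strictly increasing).
#' @param indicators named list: indicator -> waves administered.
#' @param true_components named vector `gamma_var`, `alpha_var`,
#'   `delta_var`, `eps_var` (trait, indicator, state, residual variances).
#' @param true_betas named vector `intercept`, `age`, `gender`, `wave`,
#'   `genotype` (genotype multiplies the 0-4 risk score).
#' @param gxe optional list of `list(covariate=, term=, xi_var=)` triples
#'   adding genotype-scaled variance at one level (`term` one of
#'   `"individual"`, `"individual:indicator"`, `"individual:wave"`).
#' @param genotype_freqs per-SNP risk-group probabilities.
#' @param prop_women probability an individual is a woman (`gender = 0`).
#' @param missing_rate per-observation completely-at-random dropout
#'   probability (on top of design-driven absences).
#' @param genotype_missing_rate per-individual probability the whole
#'   genotype record is missing.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return object of class `sv_sim_config`.
#' @export
simulation_config <- function(
    n_individuals = 1573L,
    birth_cohorts = c(1962, 1965, 1968, 1971, 1974, 1977),
    waves = c(1997, 2001, 2007, 2012),
    indicators = NULL,
    true_components = c(gamma_var = 0.212, alpha_var = 0.387,
                        delta_var = 0.048, eps_var = 0.298),
    true_betas = c(intercept = 0.438, age = -0.007, gender = -0.442,
                   wave = -0.001, genotype = 0),
    gxe = NULL,
    genotype_freqs = c(rs1042778 = 0.154, rs2254298 = 0.843,
                       rs53576 = 0.664, rs3796863 = 0.408),
    prop_women = 0.59,
    missing_rate = 0,
    genotype_missing_rate = 0,
    seed = 1L) {
  if (is.null(indicators))
    indicators <- lapply(scale_definitions(), `[[`, "waves_administered")
  stopifnot(n_individuals >= 1, all(diff(waves) > 0),
            all(true_components >= 0),
            all(genotype_freqs >= 0 & genotype_freqs <= 1),
            missing_rate >= 0, missing_rate < 1)
  if (!length(indicators) || !length(waves))
    stop_sv("need at least one indicator and one wave")
  need_comp <- c("gamma_var", "alpha_var", "delta_var", "eps_var")
  stopifnot(all(need_comp %in% names(true_components)))
  for (g in gxe %||% list())
    stopifnot(all(c("covariate", "term", "xi_var") %in% names(g)),
              g$xi_var >= 0)
  structure(list(
    n_individuals = as.integer(n_individuals), birth_cohorts = birth_cohorts,
    waves = waves, indicators = indicators,
    true_components = true_components[need_comp], true_betas = true_betas,
    gxe = gxe, genotype_freqs = genotype_freqs, prop_women = prop_women,
    missing_rate = missing_rate,
    genotype_missing_rate = genotype_missing_rate, seed = as.integer(seed)
  ), class = "sv_sim_config")
}

## draw unordered genotype strings for one SNP under Hardy-Weinberg
## proportions chosen so the risk-group frequency matches `p_risk`
draw_snp <- function(snp, p_risk, n) {
  info <- .sv_snp_panel[[snp]]
  risk <- info$risk
  if (length(risk) == 1L) {
    hom <- strsplit(risk, "")[[1]][1]          # risk = one homozygote
    p_allele <- sqrt(p_risk)
    other <- setdiff(info$alleles, hom)
  } else {
    carrier <- strsplit(risk[1], "")[[1]][1]   # risk = carrier group (AA/AG)
    p_allele <- 1 - sqrt(1 - p_risk)
    hom <- carrier
    other <- setdiff(info$alleles, hom)
  }
  a1 <- ifelse(runif(n) < p_allele, hom, other)
  a2 <- ifelse(runif(n) < p_allele, hom, other)
  vapply(seq_len(n), function(i) paste(sort(c(a1[i], a2[i])), collapse = ""), "")
}

#' Simulate an accelerated-longitudinal cohort
#'
#' Draws individual (trait), individual-by-indicator, and
#' individual-by-wave (state) intercepts plus observation noise from the
#' configured variance components, adds the fixed linear predictor and any
#' genotype-scaled variance terms, and assembles the canonical long
#' phenotype table plus a genotype table. Deterministic given
#' `config$seed`.
#'
#' @param config an [simulation_config()].
#' @param raw_scale if `TRUE`, also emit `score_raw` by mapping the
#'   standardized score back to each indicator's 1-5 metric using the
#'   built-in reference-wave anchors (clamped to the response bounds).
#' @return list with elements `observations` (long data frame with
#'   `score_std` filled), `genotypes`, and `truth` (generating parameters
#'   and the latent random-effect draws).
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(n_individuals = 50, seed = 7))
#' head(sim$observations)
simulate_cohort <- function(config, raw_scale = FALSE) {
  stopifnot(inherits(config, "sv_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_individuals
    ids <- sprintf("id%05d", seq_len(n))
    cohort <- rep_len(config$birth_cohorts, n)
    gender <- rbinom(n, 1, 1 - config$prop_women)  # 0 = women, 1 = men

    geno <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
    for (s in names(config$genotype_freqs))
      geno[[s]] <- draw_snp(s, config$genotype_freqs[[s]], n)
    if (config$genotype_missing_rate > 0) {
      gone <- runif(n) < config$genotype_missing_rate
      for (s in names(config$genotype_freqs)) geno[[s]][gone] <- NA_character_
    }
    geno <- add_risk_coding(geno)

    grid <- do.call(rbind, lapply(names(config$indicators), function(ind)
      expand.grid(individual = seq_len(n),
                  wave_year = config$indicators[[ind]],
                  KEEP.OUT.ATTRS = FALSE) |> transform(indicator = ind)))
    grid <- grid[order(grid$individual, grid$indicator, grid$wave_year), ]
    m <- nrow(grid)

    tc <- config$true_components
    gamma <- rnorm(n, 0, sqrt(tc[["gamma_var"]]))
    cell_alpha <- interaction(grid$individual, grid$indicator, drop = TRUE)
    alpha <- rnorm(nlevels(cell_alpha), 0, sqrt(tc[["alpha_var"]]))
    cell_delta <- interaction(grid$individual, grid$wave_year, drop = TRUE)
    delta <- rnorm(nlevels(cell_delta), 0, sqrt(tc[["delta_var"]]))
    eps <- rnorm(m, 0, sqrt(tc[["eps_var"]]))

    age <- grid$wave_year - cohort[grid$individual]
    wave_num <- grid$wave_year - min(config$waves)
    tb <- config$true_betas
    rs <- geno$risk_score[grid$individual]
    y <- tb[["intercept"]] + tb[["age"]] * age +
      tb[["gender"]] * gender[grid$individual] + tb[["wave"]] * wave_num +
      (if (tb[["genotype"]] != 0) tb[["genotype"]] * ifelse(is.na(rs), 0, rs)
       else 0) +
      gamma[grid$individual] + alpha[as.integer(cell_alpha)] +
      delta[as.integer(cell_delta)] + eps

    xi_draws <- list()
    for (g in config$gxe %||% list()) {
      x <- geno[[g$covariate]][grid$individual]
      x[is.na(x)] <- 0
      cell <- switch(g$term,
        "individual" = factor(grid$individual),
        "individual:indicator" = cell_alpha,
        "individual:wave" = cell_delta,
        stop_sv("unknown gxe term '", g$term, "'"))
      xi <- rnorm(nlevels(cell), 0, sqrt(g$xi_var))
      y <- y + xi[as.integer(cell)] * x
      xi_draws[[paste0(g$covariate, " x ", g$term)]] <- xi
    }

    obs <- data.frame(
      individual_id = ids[grid$individual], indicator = grid$indicator,
      wave_year = grid$wave_year, age = age,
      gender = gender[grid$individual], score_raw = NA_real_,
      score_std = as.numeric(y), stringsAsFactors = FALSE)
    if (raw_scale) {
      for (ind in names(config$indicators)) {
        anc <- .sv_raw_anchors[[ind]] %||% c(3, 0.6)
        sel <- obs$indicator == ind
        obs$score_raw[sel] <-
          pmin(5, pmax(1, anc[1] + anc[2] * obs$score_std[sel]))
      }
    }
    if (config$missing_rate > 0)
      obs <- obs[runif(nrow(obs)) >= config$missing_rate, , drop = FALSE]
    rownames(obs) <- NULL

    truth <- list(
      config = unclass(config),
      latent = list(gamma = gamma, alpha = as.numeric(alpha),
                    delta = as.numeric(delta), xi = xi_draws),
      n_observations = nrow(obs))
    list(observations = obs, genotypes = geno, truth = truth)
  })
}

#' Cross-tabulate person-observations by wave and age band
#'
#' Summarises the accelerated design's occupancy: counts of distinct
#' person-observations per assessment wave and 3-year age band, with
#' margins (whose totals equal the number of observation rows).
#'
#' @param observations person-observation table with `wave_year` and `age`.
#' @param band_width width of the age bands in years (default 3).
#' @return integer matrix, waves x age bands, with `Sum` margins.
#' @export
design_occupancy <- function(observations, band_width = 3) {
  if (nrow(observations) == 0L)
    return(matrix(0L, 0, 0))
  age <- observations$age
  lo <- floor(min(age))
  breaks <- seq(lo, max(age) + band_width, by = band_width)
  band <- cut(age, breaks = breaks, right = FALSE,
              labels = paste(breaks[-length(breaks)],
                             breaks[-1] - 1, sep = "-"))
  tab <- table(wave = observations$wave_year, age_band = band)
  stats::addmargins(tab)
}
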