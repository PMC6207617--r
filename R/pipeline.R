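## Configuration-driven orchestration: score -> standardize -> join
## genotypes -> fit the variance-partition models -> per-SNP models and
## per-indicator association grid -> CSV/JSON reports with a run log.

#' Assemble or read a pipeline run configuration
#'
#' @param phenotype_csv long phenotype CSV (canonical schema); or
#' @param items_csv item-level CSV (scored via [score_item_table()]),
#'   requiring `demographics_csv` with `individual_id,birth_year,gender`.
#' @param demographics_csv see above.
#' @param genotype_csv genotype CSV (canonical schema).
#' @param vcf optional VCF path used instead of `genotype_csv`.
#' @param reference_wave standardisation anchor year (default 2007).
#' @param criterion `"reml"` or `"ml"`.
#' @param ci `"profile"`, `"boot"` or `"none"` -- intervals for the base
#'   model's variance components.
#' @param fixed,random,gxe optional overrides for the base model's terms
#'   (see [model_spec()]); defaults are the standard Model-1 specification.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all stochastic steps.
#' @param log_level `"INFO"` or `"DEBUG"`.
#' @return object of class `sv_run_config`.
#' @export
run_config <- function(phenotype_csv = NULL, items_csv = NULL,
                       demographics_csv = NULL, genotype_csv = NULL,
                       vcf = NULL, reference_wave = 2007,
                       criterion = "reml", ci = "profile",
                       fixed = NULL, random = NULL, gxe = NULL,
                       out_dir = "sociovar-out", seed = 1L,
                       log_level = "INFO") {
  if (is.null(phenotype_csv) && is.null(items_csv))
    stop_sv("need phenotype_csv or items_csv")
  if (!is.null(items_csv) && is.null(demographics_csv))
    stop_sv("items_csv requires demographics_csv (individual_id, birth_year, gender)")
  stopifnot(criterion %in% c("reml", "ml"), ci %in% c("profile", "boot", "none"))
  base_spec <- model_spec(
    fixed = fixed %||% c("intercept", "age", "gender", "wave"),
    random = random %||% c("individual", "individual:indicator",
                           "individual:wave"),
    gxe = gxe %||% list())
  structure(list(phenotype_csv = phenotype_csv, items_csv = items_csv,
                 demographics_csv = demographics_csv,
                 genotype_csv = genotype_csv, vcf = vcf,
                 reference_wave = reference_wave, criterion = criterion,
                 ci = ci, base_spec = base_spec, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "sv_run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys mirror the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

load_inputs <- function(config, logf) {
  if (!is.null(config$phenotype_csv)) {
    obs <- read_phenotypes(config$phenotype_csv)
    sv_log(sprintf("loaded %d person-observations from %s", nrow(obs),
                   config$phenotype_csv), logf)
  } else {
    items <- read.csv(config$items_csv, stringsAsFactors = FALSE,
                      colClasses = c(individual_id = "character"))
    sv_log(sprintf("loaded %d item rows from %s", nrow(items),
                   config$items_csv), logf)
    obs <- score_item_table(items)
    demo <- read.csv(config$demographics_csv, stringsAsFactors = FALSE,
                     colClasses = c(individual_id = "character"))
    obs <- merge(obs, demo, by = "individual_id", all.x = TRUE, sort = FALSE)
    obs$age <- obs$wave_year - obs$birth_year
    sv_log(sprintf("scored into %d person-observations", nrow(obs)), logf)
  }
  n0 <- nrow(obs)
  obs <- obs[!is.na(obs$score_raw) | !is.na(obs$score_std %||% NA), ,
             drop = FALSE]
  if (nrow(obs) < n0)
    sv_log(sprintf("dropped %d observation(s) without a score", n0 - nrow(obs)),
           logf)
  if (!"score_std" %in% names(obs) || anyNA(obs$score_std)) {
    obs <- standardize_to_reference(obs, config$reference_wave)
    sv_log(sprintf("standardized %d indicator(s) to reference wave %s",
                   length(unique(obs$indicator)), config$reference_wave), logf)
  }
  geno <- NULL
  if (!is.null(config$genotype_csv)) {
    geno <- read_genotypes(config$genotype_csv)
    sv_log(sprintf("loaded genotypes for %d individuals from %s", nrow(geno),
                   config$genotype_csv), logf)
  } else if (!is.null(config$vcf)) {
    geno <- extract_from_vcf(config$vcf)
    sv_log(sprintf("extracted genotypes for %d individuals from %s",
                   nrow(geno), config$vcf), logf)
  }
  list(observations = obs, genotypes = geno)
}

## Table-4-style layout: fixed-effect rows then variance-component rows
report_table <- function(fit, decimals = 3) {
  b <- fit$betas
  cm <- fit$components
  rbind(
    data.frame(term = b$term,
               estimate = round_half_away(b$estimate, decimals),
               se = round_half_away(b$se, decimals),
               p_value = signif(b$p_value, 3),
               var = NA_real_, sd = NA_real_, var_pct = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(term = cm$component, estimate = NA_real_, se = NA_real_,
               p_value = NA_real_,
               var = round_half_away(cm$var, decimals),
               sd = round_half_away(cm$sd, decimals),
               var_pct = round_half_away(cm$share, 1),
               stringsAsFactors = FALSE))
}

fit_to_list <- function(fit) {
  list(criterion = fit$criterion, converged = fit$converged,
       n_obs = fit$n_obs, n_individuals = fit$n_individuals,
       loglik = fit$loglik, aic = fit$aic,
       betas = fit$betas, components = fit$components,
       intervals = attr(fit, "intervals"))
}

#' Run the variance-partition pipeline
#'
#' Fits the base crossed random-intercepts model (Model 1: age, gender and
#' wave fixed effects; trait/indicator/state/residual components) and, if
#' genotypes are available, the genetic-risk-score model (Model 2: risk
#' score as fixed effect plus three genotype-scaled variance terms).
#' Writes `model1.csv`, `model2.csv`, `fit.json` and `run.log` to the
#' configured output directory. Input files are never modified.
#'
#' @param config an [run_config()].
#' @return invisibly, a list with the fitted models and output paths.
#' @export
run_variance_partition <- function(config) {
  stopifnot(inherits(config, "sv_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  sv_log(sprintf("run_variance_partition: seed=%d criterion=%s",
                 config$seed, config$criterion), logf)
  inp <- load_inputs(config, logf)
  obs <- inp$observations

  spec1 <- config$base_spec %||% model_spec()
  des1 <- build_design(obs, genotypes = inp$genotypes, spec = spec1)
  sv_log(sprintf("Model 1 design: %d observations, %d individuals (%d dropped)",
                 des1$n_obs, des1$n_individuals, des1$n_dropped), logf)
  fit1 <- fit_lmm(des1, criterion = config$criterion, seed = config$seed)
  sv_log(sprintf("Model 1 fit: logLik=%.3f AIC=%.3f converged=%s",
                 fit1$loglik, fit1$aic, fit1$converged), logf)
  if (!fit1$converged)
    stop_sv("Model 1 did not converge; see ", file.path(config$out_dir, "run.log"))
  if (config$ci != "none") {
    method <- config$ci
    ints <- lapply(fit1$components$component, function(cp)
      profile_ci(fit1, cp, method = if (method == "boot") "boot" else "profile",
                 seed = config$seed))
    names(ints) <- fit1$components$component
    attr(fit1, "intervals") <- ints
    sv_log(sprintf("Model 1 %s intervals computed for %d components",
                   method, length(ints)), logf)
  }
  m1_path <- file.path(config$out_dir, "model1.csv")
  write.csv(report_table(fit1), m1_path, row.names = FALSE, na = "")

  fit2 <- NULL
  m2_path <- NULL
  if (!is.null(inp$genotypes)) {
    ids <- unique(obs$individual_id)
    g <- inp$genotypes
    with_geno <- ids %in% g$individual_id[!is.na(g$risk_score)]
    sv_log(sprintf("genotype join: %d of %d individuals have a complete risk score",
                   sum(with_geno), length(ids)), logf)
    fit2 <- fit_gxe_models(obs, g, covariates = "risk_score",
                           criterion = config$criterion,
                           seed = config$seed)$risk_score
    sv_log(sprintf("Model 2 fit: %d observations, %d individuals, logLik=%.3f",
                   fit2$n_obs, fit2$n_individuals, fit2$loglik), logf)
    if (!fit2$converged)
      stop_sv("Model 2 did not converge; see ", file.path(config$out_dir, "run.log"))
    m2_path <- file.path(config$out_dir, "model2.csv")
    write.csv(report_table(fit2), m2_path, row.names = FALSE, na = "")
  }

  fj_path <- file.path(config$out_dir, "fit.json")
  jsonlite::write_json(
    list(seed = config$seed, model1 = fit_to_list(fit1),
         model2 = if (!is.null(fit2)) fit_to_list(fit2)),
    fj_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  sv_log("reports written", logf)
  invisible(list(model1 = fit1, model2 = fit2,
                 paths = c(model1 = m1_path, model2 = m2_path,
                           fit_json = fj_path,
                           log = file.path(config$out_dir, "run.log"))))
}

#' Run the per-SNP panel
#'
#' Fits one genotype-scaled variance model per panel SNP (risk flag as
#' fixed effect plus the three genotype-variance terms), writing
#' `snp_<id>.csv` each, and the per-indicator association grid
#' (`associations.csv`): for every SNP x indicator, the sum-to-zero group
#' deviations with SE, the 1-df Wald F and its p-value, with the risk
#' group flagged.
#'
#' @param config an [run_config()] (genotypes required).
#' @return invisibly, list of per-SNP fits, the association grid, paths.
#' @export
run_snp_panel <- function(config) {
  stopifnot(inherits(config, "sv_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "snp_run.log"), open = "wt")
  on.exit(close(logf))
  sv_log(sprintf("run_snp_panel: seed=%d", config$seed), logf)
  inp <- load_inputs(config, logf)
  if (is.null(inp$genotypes)) stop_sv("run_snp_panel needs a genotype table")
  obs <- inp$observations
  snps <- names(snp_panel())

  fits <- fit_gxe_models(obs, inp$genotypes,
                         covariates = paste0("risk_", snps),
                         criterion = config$criterion, seed = config$seed)
  paths <- character()
  for (s in snps) {
    p <- file.path(config$out_dir, paste0("snp_", s, ".csv"))
    write.csv(report_table(fits[[paste0("risk_", s)]]), p,
              row.names = FALSE, na = "")
    paths[s] <- p
    sv_log(sprintf("%s model: %d obs, logLik=%.3f", s,
                   fits[[paste0("risk_", s)]]$n_obs,
                   fits[[paste0("risk_", s)]]$loglik), logf)
  }

  indicators <- unique(obs$indicator)
  grid <- do.call(rbind, lapply(snps, function(s)
    do.call(rbind, lapply(indicators, function(ind) {
      a <- suppressWarnings(
        test_indicator_association(obs, inp$genotypes, s, ind,
                                   criterion = config$criterion,
                                   seed = config$seed))
      data.frame(snp = s, indicator = ind,
                 risk_group = a$groups$group[1],
                 risk_estimate = a$groups$estimate[1],
                 risk_se = a$groups$se[1],
                 other_group = a$groups$group[2],
                 other_estimate = a$groups$estimate[2],
                 other_se = a$groups$se[2],
                 F_value = a$F, df1 = a$df[1], df2 = a$df[2],
                 p_value = a$p_value, stringsAsFactors = FALSE)
    }))))
  grid_path <- file.path(config$out_dir, "associations.csv")
  write.csv(grid, grid_path, row.names = FALSE, na = "")
  sv_log(sprintf("association grid: %d SNPs x %d indicators", length(snps),
                 length(indicators)), logf)
  invisible(list(fits = fits, associations = grid,
                 paths = c(paths, associations = grid_path)))
}
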