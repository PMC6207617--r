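## Model specification and design-matrix construction for the crossed
## random-intercepts model
##
##   y_i = x_i' beta + gamma_k[i] + alpha_j[i] + delta_t[i] + eps_i
##
## where gamma is an individual intercept (trait), alpha an
## individual-by-indicator intercept, delta an individual-by-wave intercept
## (state), and eps observation noise. A genotype-moderated variance term
## enters as an extra random intercept whose design entries are the
## genotype covariate x_i instead of 1 (so for a 0/1 carrier flag, carriers
## get extra variance at that level).

.sv_random_terms <- c("individual", "individual:indicator", "individual:wave")

#' Declare a variance-partition model
#'
#' @param fixed character vector of fixed-effect terms, in the column order
#'   wanted. `"intercept"` and `"wave"` (years since the earliest observed
#'   wave) are special; any other name must be a column of the observation
#'   table or of the genotype table (e.g. `"age"`, `"gender"`,
#'   `"risk_score"`, `"risk_rs2254298"`).
#' @param random character vector of crossed random-intercept terms, a
#'   subset of `"individual"`, `"individual:indicator"`,
#'   `"individual:wave"`. The intercepts are mutually uncorrelated: no
#'   covariance parameters are estimated between terms.
#' @param gxe list of genotype-variance interaction terms; each element is
#'   `list(covariate = <column name>, term = <one of the random terms>)`.
#' @return object of class `sv_model_spec`.
#' @export
#' @examples
#' model_spec(gxe = list(list(covariate = "risk_score", term = "individual:wave")))
model_spec <- function(fixed = c("intercept", "age", "gender", "wave"),
                       random = .sv_random_terms,
                       gxe = list()) {
  stopifnot(is.character(fixed), is.character(random))
  if (anyDuplicated(random)) stop_sv("random terms must be distinct")
  bad <- setdiff(random, .sv_random_terms)
  if (length(bad))
    stop_sv("unknown random term(s): ", paste(bad, collapse = ", "),
            " (allowed: ", paste(.sv_random_terms, collapse = ", "), ")")
  for (g in gxe) {
    if (!is.list(g) || !all(c("covariate", "term") %in% names(g)))
      stop_sv("each gxe element must be list(covariate=, term=)")
    if (!g$term %in% random)
      stop_sv("gxe term grouping '", g$term, "' is not among the random terms")
  }
  structure(list(fixed = fixed, random = random, gxe = gxe),
            class = "sv_model_spec")
}

#' @exportS3Method base::print
print.sv_model_spec <- function(x, ...) {
  cat("<sv_model_spec>\n  fixed: ", paste(x$fixed, collapse = " + "),
      "\n  random:", paste(x$random, collapse = " + "), "\n")
  if (length(x$gxe))
    cat("  gxe:   ",
        paste(vapply(x$gxe, function(g)
          paste0(g$covariate, " x ", g$term), ""), collapse = ", "), "\n")
  invisible(x)
}

grouping_labels <- function(obs, term) {
  switch(term,
    "individual" = as.character(obs$individual_id),
    "individual:indicator" = paste(obs$individual_id, obs$indicator, sep = "\r"),
    "individual:wave" = paste(obs$individual_id, obs$wave_year, sep = "\r"),
    stop_sv("unknown grouping term '", term, "'"))
}

#' Build fixed- and random-effects design matrices
#'
#' Assembles the dense fixed-effects matrix `X` and one sparse
#' indicator-of-group block per random term (stored transposed, as
#' `t(Z)`, for the penalized least-squares solver). Plain blocks have a
#' single 1 per observation row; genotype-variance blocks carry the
#' genotype covariate value instead. Rows with a missing response or any
#' missing required covariate are dropped (available-case analysis) and
#' the count recorded.
#'
#' @param observations person-observation table with columns
#'   `individual_id`, `indicator`, `wave_year`, the response, and any
#'   fixed-effect covariates (`age`, `gender`, ...).
#' @param genotypes optional genotype table (see [read_genotypes()]) merged
#'   by `individual_id` when the spec references genotype columns.
#' @param spec an [model_spec()].
#' @param response name of the response column (default `"score_std"`).
#' @return object of class `sv_design`: list with elements `y`, `X`,
#'   `Zt` (named list of transposed sparse blocks), `block_cols`,
#'   `n_obs`, `n_individuals`, `obs_id`, `n_dropped`.
#' @export
build_design <- function(observations, genotypes = NULL, spec = model_spec(),
                         response = "score_std") {
  obs <- as.data.frame(observations)
  need <- c("individual_id", "indicator", "wave_year", response)
  if (!all(need %in% names(obs)))
    stop_sv("observations must have columns ", paste(need, collapse = ", "))
  obs$individual_id <- as.character(obs$individual_id)

  gxe_cov <- vapply(spec$gxe, `[[`, "", "covariate")
  special <- c("intercept", "wave")
  wanted <- unique(c(setdiff(spec$fixed, special), gxe_cov))
  from_geno <- setdiff(wanted, names(obs))
  if (length(from_geno)) {
    if (is.null(genotypes))
      stop_sv("term(s) ", paste(from_geno, collapse = ", "),
              " need a genotype table, but none was supplied")
    gt <- as.data.frame(genotypes)
    missing_cols <- setdiff(from_geno, names(gt))
    if (length(missing_cols))
      stop_sv("genotype table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
    gt$individual_id <- as.character(gt$individual_id)
    obs <- merge(obs, gt[c("individual_id", from_geno)],
                 by = "individual_id", all.x = TRUE, sort = FALSE)
  }

  wave0 <- min(obs$wave_year, na.rm = TRUE)  # earliest wave coded 0
  col_of <- function(term) {
    switch(term,
      intercept = rep(1, nrow(obs)),
      wave = obs$wave_year - wave0,
      {
        if (!term %in% names(obs))
          stop_sv("fixed term '", term, "' not found in observations/genotypes")
        as.numeric(obs[[term]])
      })
  }
  X <- do.call(cbind, lapply(spec$fixed, col_of))
  colnames(X) <- spec$fixed

  y <- as.numeric(obs[[response]])
  gxe_x <- if (length(gxe_cov)) sapply(gxe_cov, function(cv) as.numeric(obs[[cv]]))
           else NULL
  keep <- !is.na(y) & complete.cases(X)
  if (length(gxe_cov)) keep <- keep & complete.cases(gxe_x)
  n_dropped <- sum(!keep)
  obs <- obs[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(obs)
  if (n == 0L) stop_sv("no complete observations left after filtering")

  ## drop collinear fixed-effect columns (pivoted QR), keeping declared order
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- sort(qx$pivot[(qx$rank + 1):ncol(X)])
    warning("dropping collinear fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "), call. = FALSE)
    X <- X[, -drop_cols, drop = FALSE]
  }

  Zt <- list()
  block_cols <- integer()
  for (term in spec$random) {
    f <- factor(grouping_labels(obs, term))
    Zt[[term]] <- Matrix::sparseMatrix(i = as.integer(f), j = seq_len(n),
                                       x = 1, dims = c(nlevels(f), n))
    block_cols[term] <- nlevels(f)
  }
  for (g in spec$gxe) {
    lab <- paste0(g$covariate, " x ", g$term)
    f <- factor(grouping_labels(obs, g$term))
    x <- as.numeric(obs[[g$covariate]])
    Zt[[lab]] <- Matrix::sparseMatrix(i = as.integer(f), j = seq_len(n),
                                      x = x, dims = c(nlevels(f), n))
    block_cols[lab] <- nlevels(f)
  }

  structure(list(
    y = y, X = X, Zt = Zt, block_cols = block_cols, spec = spec,
    n_obs = n, p = ncol(X),
    n_individuals = length(unique(obs$individual_id)),
    obs_id = paste(obs$individual_id, obs$indicator, obs$wave_year, sep = "\r"),
    n_dropped = n_dropped
  ), class = "sv_design")
}

#' @exportS3Method base::print
print.sv_design <- function(x, ...) {
  cat(sprintf("<sv_design> %d observations, %d individuals, %d fixed column(s)\n",
              x$n_obs, x$n_individuals, x$p))
  for (nm in names(x$Zt))
    cat(sprintf("  Z[%s]: %d levels\n", nm, x$block_cols[[nm]]))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d incomplete row(s) dropped)\n", x$n_dropped))
  invisible(x)
}
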