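## Scale scoring and reference-wave standardisation for the five
## sociability indicators (NEO-FFI Extraversion, the three TCI Reward
## Dependence subscales, EAS Sociability).

#' Built-in sociability scale definitions
#'
#' Returns the definitions of the five self-report sociability indicators:
#' NEO-FFI Extraversion (12 items, administered 2007 and 2012 only), the
#' three TCI Reward Dependence subscales -- Sentimentality (10 items),
#' Social Attachment (8 items) and Dependence (6 items, all items keyed in
#' reverse so that disagreement indicates higher Dependence) -- and EAS
#' Sociability (5 items). All items use a five-point response scale (1-5).
#'
#' @param name optional indicator name; if given, the single matching
#'   definition is returned.
#' @return a named list of `scale_definition` objects (or one object).
#' @export
#' @examples
#' scale_definitions("TCI-RD4-Dependence")
scale_definitions <- function(name = NULL) {
  defs <- list(
    scale_definition("NEO-FFI-E", n_items = 12, waves_administered = c(2007, 2012)),
    scale_definition("TCI-RD1-Sentimentality", n_items = 10),
    scale_definition("TCI-RD3-SocialAttachment", n_items = 8),
    scale_definition("TCI-RD4-Dependence", n_items = 6, reversed_items = 1:6),
    scale_definition("EAS-Sociability", n_items = 5)
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  if (is.null(name)) return(defs)
  if (!name %in% names(defs))
    stop_sv("unknown scale '", name, "'; known: ", paste(names(defs), collapse = ", "))
  defs[[name]]
}

#' Define a questionnaire scale
#'
#' @param name indicator label.
#' @param n_items number of items.
#' @param reversed_items integer indices of reverse-keyed items (subset of
#'   `1:n_items`).
#' @param response_range inclusive integer bounds of valid responses.
#' @param waves_administered calendar years at which the scale was fielded.
#' @return object of class `scale_definition`.
#' @export
scale_definition <- function(name, n_items, reversed_items = integer(),
                             response_range = c(1L, 5L),
                             waves_administered = c(1997, 2001, 2007, 2012)) {
  stopifnot(is.character(name), length(name) == 1L,
            n_items >= 1, length(response_range) == 2L,
            response_range[1] < response_range[2])
  reversed_items <- as.integer(reversed_items)
  if (length(reversed_items) && !all(reversed_items %in% seq_len(n_items)))
    stop_sv("reversed_items must be a subset of 1..n_items for scale '", name, "'")
  structure(
    list(name = name, n_items = as.integer(n_items),
         reversed_items = reversed_items,
         response_range = as.numeric(response_range),
         waves_administered = as.numeric(waves_administered)),
    class = "scale_definition")
}

#' @exportS3Method base::print
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items (%d reversed), range %g-%g, waves %s\n",
              x$name, x$n_items, length(x$reversed_items),
              x$response_range[1], x$response_range[2],
              paste(x$waves_administered, collapse = "/")))
  invisible(x)
}

#' Score one set of item responses
#'
#' Reverse-keyed items are mapped `r -> (min + max - r)` before averaging.
#' The scale score is the mean over the answered items, computed only when
#' at least 75% of the items were answered (inclusive: 9 of 12 qualifies);
#' otherwise `NA`.
#'
#' @param responses numeric vector of length `scale$n_items`, `NA` for
#'   unanswered items.
#' @param scale a [scale_definition()].
#' @return scalar score on the raw response metric, or `NA_real_`.
#' @export
#' @examples
#' dep <- scale_definitions("TCI-RD4-Dependence")
#' score_scale(rep(5, 6), dep)  # fully reversed scale -> 1
score_scale <- function(responses, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (length(responses) != scale$n_items)
    stop_sv("scale '", scale$name, "' expects ", scale$n_items,
            " responses, got ", length(responses))
  responses <- as.numeric(responses)
  bad <- which(!is.na(responses) &
                 (responses < scale$response_range[1] |
                    responses > scale$response_range[2]))
  if (length(bad))
    stop_sv("response out of range [", scale$response_range[1], ",",
            scale$response_range[2], "] for scale '", scale$name,
            "' at item(s) ", paste(bad, collapse = ", "))
  if (length(scale$reversed_items)) {
    rev_map <- sum(scale$response_range)
    responses[scale$reversed_items] <- rev_map - responses[scale$reversed_items]
  }
  answered <- sum(!is.na(responses))
  if (answered / scale$n_items < 0.75) return(NA_real_)
  mean(responses, na.rm = TRUE)
}

#' Score an item-level response table
#'
#' @param items data frame with columns `individual_id`, `wave_year`,
#'   `scale`, and item columns `item_1..item_k` (unused trailing item
#'   columns may be `NA` for shorter scales).
#' @param scales list of scale definitions, default [scale_definitions()].
#' @return long data frame `individual_id, indicator, wave_year, score_raw`.
#' @export
score_item_table <- function(items, scales = scale_definitions()) {
  need <- c("individual_id", "wave_year", "scale")
  if (!all(need %in% names(items)))
    stop_sv("item table must have columns ", paste(need, collapse = ", "))
  item_cols <- grep("^item_\\d+$", names(items), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  out <- lapply(seq_len(nrow(items)), function(r) {
    sc_name <- as.character(items$scale[r])
    sc <- if (sc_name %in% names(scales)) scales[[sc_name]] else
      stop_sv("row ", r, ": unknown scale '", sc_name, "'")
    if (!items$wave_year[r] %in% sc$waves_administered)
      stop_sv("row ", r, ": scale '", sc_name, "' was not administered in wave ",
              items$wave_year[r])
    resp <- as.numeric(items[r, item_cols[seq_len(sc$n_items)]])
    data.frame(individual_id = as.character(items$individual_id[r]),
               indicator = sc_name,
               wave_year = as.numeric(items$wave_year[r]),
               score_raw = score_scale(resp, sc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardize indicator scores to a reference wave
#'
#' Each indicator is rescaled so that its population mean is 0 and its
#' variance 1 at the reference wave; the same affine map is then applied to
#' that indicator's scores at every other wave (whose variances therefore
#' need not be 1).
#'
#' @param observations data frame with columns `individual_id`, `indicator`,
#'   `wave_year`, `score_raw` (other columns are carried through).
#' @param reference_wave calendar year used as the standardisation anchor.
#' @return `observations` with a filled `score_std` column, plus attribute
#'   `"reference"` holding the per-indicator reference means/SDs.
#' @export
standardize_to_reference <- function(observations, reference_wave = 2007) {
  stopifnot(all(c("individual_id", "indicator", "wave_year", "score_raw")
                %in% names(observations)))
  obs <- observations
  inds <- unique(obs$indicator)
  ref <- data.frame(indicator = inds, mean = NA_real_, sd = NA_real_,
                    n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(inds)) {
    at_ref <- obs$indicator == inds[i] & obs$wave_year == reference_wave &
      !is.na(obs$score_raw)
    n <- sum(at_ref)
    if (n < 2)
      stop_sv("indicator '", inds[i], "' has ", n, " non-missing score(s) at ",
              "reference wave ", reference_wave, "; cannot standardize")
    m <- mean(obs$score_raw[at_ref])
    s <- sd(obs$score_raw[at_ref])  # n-1 denominator
    if (s == 0)
      stop_sv("indicator '", inds[i], "' has zero variance at reference wave ",
              reference_wave)
    ref$mean[i] <- m; ref$sd[i] <- s; ref$n[i] <- n
    sel <- obs$indicator == inds[i]
    obs$score_std[sel] <- (obs$score_raw[sel] - m) / s
  }
  attr(obs, "reference") <- ref
  obs
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability `alpha = k/(k-1) * (1 - sum(item
#' variances) / var(total score))` from complete item responses.
#'
#' @param item_matrix numeric matrix or data frame, rows = respondents,
#'   columns = items; rows with any `NA` are dropped.
#' @return scalar alpha.
#' @export
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(x + rnorm(100))  # shared row effect inflates alpha
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop_sv("cronbach_alpha needs at least 2 items")
  if (nrow(m) < 3) stop_sv("cronbach_alpha needs at least 3 complete rows")
  total_var <- var(rowSums(m))
  if (total_var == 0)
    stop_sv("total-score variance is zero; alpha is undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Skewness and excess kurtosis
#'
#' Moment-based sample skewness `m3 / m2^(3/2)` and excess kurtosis
#' `m4 / m2^2 - 3`, where `m_j` are central moments with denominator `n`.
#'
#' @param scores numeric vector (at least 4 non-missing values).
#' @return named numeric vector `c(skewness, excess_kurtosis)`.
#' @export
distribution_diagnostics <- function(scores) {
  x <- scores[!is.na(scores)]
  if (length(x) < 4) stop_sv("need at least 4 values")
  n <- length(x)
  xc <- x - mean(x)
  m2 <- sum(xc^2) / n
  if (m2 == 0) stop_sv("zero variance; skewness/kurtosis undefined")
  c(skewness = sum(xc^3) / n / m2^1.5,
    excess_kurtosis = sum(xc^4) / n / m2^2 - 3)
}

#' Read / write the canonical long phenotype CSV
#'
#' Columns: `individual_id,indicator,wave_year,age,gender,score_raw,score_std`.
#' Missing values are empty fields or `NA`.
#'
#' @param path file path.
#' @return data frame of person-observations.
#' @export
read_phenotypes <- function(path) {
  obs <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(individual_id = "character"))
  need <- c("individual_id", "indicator", "wave_year")
  if (!all(need %in% names(obs)))
    stop_sv("phenotype CSV must have columns ", paste(need, collapse = ", "))
  obs
}

#' @rdname read_phenotypes
#' @param observations data frame of person-observations.
#' @export
write_phenotypes <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}
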