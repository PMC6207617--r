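#' @importFrom stats aggregate optim optimize pchisq pf pnorm qchisq rbinom
#'   rnorm runif sd setNames uniroot var complete.cases
#' @importFrom methods as is
#' @importFrom utils read.csv write.csv
#' @importFrom Matrix crossprod tcrossprod t solve determinant update
#'   Cholesky sparseMatrix Diagonal
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding: ties are rounded away from zero (so 0.5 -> 1,
#' -0.5 -> -1), matching how report tables are conventionally printed,
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.05, 0.15, -0.25), 1)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library internals never disturb user streams
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_sv <- function(...) stop(..., call. = FALSE)

## minimal leveled logger used by the pipeline; writes to an open connection
## (or stdout) and returns the message invisibly
sv_log <- function(msg, con = NULL, level = "INFO") {
  line <- sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (!is.null(con)) writeLines(line, con) else message(line)
  invisible(line)
}
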