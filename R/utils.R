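#' @importFrom stats rnorm rpois rlnorm runif rbinom rgamma median mad sd
#'   quantile shapiro.test t.test p.adjust cor ppoints qnorm var aggregate
#'   setNames complete.cases lm coef
#' @importFrom utils head read.csv write.csv
#' @import data.table
NULL

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Percentage ratio as reported in screen summaries
#'
#' Computes `100 * n / d` rounded to the nearest integer, the form in which
#' screen summary rates (hit rate, validation rate, QC retention) are
#' reported.
#'
#' @param n numerator count.
#' @param d denominator count.
#' @return Integer percentage; `NA` if `d` is zero.
#' @examples
#' percent_ratio(55, 133) # 41
#' @export
percent_ratio <- function(n, d) {
  if (length(d) != length(n)) stop("n and d must have equal length")
  out <- ifelse(d == 0, NA_real_, round(100 * n / d))
  out
}

# mean absolute deviation about the mean (the screen's control "error")
mean_abs_dev <- function(x) mean(abs(x - mean(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
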