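#' Two-sided normal p-value from a Z statistic, computed in log space
#'
#' Returns both the p-value (which underflows to 0 in double precision for
#' |z| beyond ~38.6) and its natural logarithm, which stays finite for any
#' finite z.  All significance decisions in the package that may involve
#' extreme statistics are taken on the log scale.
#'
#' @param z numeric vector of signed standardized statistics.
#' @return list with components `p` (two-sided p, possibly 0 by underflow)
#'   and `log_p` (natural log of the two-sided p, always finite).
#' @examples
#' p_from_z(1.96)$p     # ~0.05
#' p_from_z(60)$log_p   # finite, ~ -1805
#' @export
p_from_z <- function(z) {
  log_p <- log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  list(p = exp(log_p), log_p = log_p)
}

#' Bonferroni significance threshold with display formatting
#'
#' The decision threshold is always the exact `alpha / m`.  The display value
#' mirrors the rounding convention used when such thresholds are reported:
#' thresholds below 1e-3 are shown to two significant figures, larger ones
#' rounded to three decimals (so 0.05/894 displays as 5.6e-5 and 0.05/27 as
#' 0.002).
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param m number of tests.
#' @return list with `exact` and `display` threshold values.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  stopifnot(alpha > 0, m >= 1)
  exact <- alpha / m
  display <- if (exact < 1e-3) signif(exact, 2) else round(exact, 3)
  list(exact = exact, display = display)
}

# Run code with a temporary RNG state seeded by `seed`; restores the caller's
# RNG afterwards so seeded bootstraps do not perturb outer simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
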