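#' Harmonized instrument set for two-sample Mendelian randomization
#'
#' One row per genetic instrument: the variant's effect on the exposure
#' (`gamma_x`, exposure-SD per effect allele, with SE `se_x`) and on the
#' outcome (`Gamma_y`, log-odds or outcome-SD per the same allele, SE
#' `se_y`), estimated in non-overlapping samples and harmonized to a
#' common effect-allele orientation upstream.  Optional additional
#' exposure columns (a matrix `exposures`, e.g. effects on systolic and
#' diastolic blood pressure) support multivariable MR.
#'
#' @param gamma_x,se_x exposure effects and SEs (SEs positive).
#' @param Gamma_y,se_y outcome effects and SEs (SEs positive).
#' @param snp optional variant ids.
#' @param exposures optional named matrix of further exposure effects, one
#'   row per instrument.
#' @return object of class `mr_instruments` (a data frame; `exposures`
#'   kept as an attribute).
#' @export
mr_instruments <- function(gamma_x, se_x, Gamma_y, se_y, snp = NULL,
                           exposures = NULL) {
  k <- length(gamma_x)
  stopifnot(length(se_x) == k, length(Gamma_y) == k, length(se_y) == k)
  if (any(se_x <= 0) || any(se_y <= 0)) stop("all SEs must be positive")
  if (is.null(snp)) snp <- paste0("iv", seq_len(k))
  out <- data.frame(snp = snp, gamma_x = gamma_x, se_x = se_x,
                    Gamma_y = Gamma_y, se_y = se_y,
                    stringsAsFactors = FALSE)
  if (!is.null(exposures)) {
    exposures <- as.matrix(exposures)
    stopifnot(nrow(exposures) == k)
    attr(out, "exposures") <- exposures
  }
  class(out) <- c("mr_instruments", "data.frame")
  out
}

# orient instruments so gamma_x >= 0 (flips Gamma_y and exposure columns
# jointly); required for an interpretable Egger intercept
orient_instruments <- function(ins) {
  flip <- ins$gamma_x < 0
  ins$gamma_x[flip] <- -ins$gamma_x[flip]
  ins$Gamma_y[flip] <- -ins$Gamma_y[flip]
  ex <- attr(ins, "exposures")
  if (!is.null(ex)) { ex[flip, ] <- -ex[flip, ]; attr(ins, "exposures") <- ex }
  ins
}

new_mr_fit <- function(method, theta, se, k, df = Inf, extra = list()) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  stat <- theta / se
  p <- if (is.finite(df)) 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
       else p_from_z(stat)$p
  structure(c(list(method = method, theta = theta, se = se,
                   ci_low = theta - crit * se, ci_high = theta + crit * se,
                   p = p, k = k, df = df), extra),
            class = "mr_fit")
}

#' Fit a two-sample Mendelian randomization model
#'
#' The central fitting function of the package.  Given a harmonized
#' [mr_instruments] set, estimates the causal effect of the exposure on
#' the outcome (per exposure SD) by the requested estimator and returns a
#' fitted-model object with `print`, `summary`, `coef`, `confint` and
#' `plot` methods.
#'
#' Methods:
#' \describe{
#'   \item{`wald`}{single-instrument ratio `Gamma_y/gamma_x` (k = 1).}
#'   \item{`ivw`}{inverse-variance-weighted regression of `Gamma_y` on
#'     `gamma_x` through the origin, weights `1/se_y^2`; fixed-effect SE
#'     by default, with between-instrument heterogeneity reported as
#'     Cochran's Q over the per-instrument ratios.}
#'   \item{`egger`}{the same weighted regression with a free intercept;
#'     the intercept estimates average directional pleiotropy (requires
#'     the InSIDE assumption); t-based inference on k - 2 df.}
#'   \item{`wmedian`}{weighted median of the per-instrument ratios —
#'     consistent when at least half the weight comes from valid
#'     instruments; SE by seeded parametric bootstrap.}
#'   \item{`pwmedian`}{penalized weighted median: weights of instruments
#'     with outlying heterogeneity contributions are down-weighted before
#'     re-applying the weighted-median rule.}
#'   \item{`mvmr`}{multivariable MR over the instrument set's exposure
#'     matrix (see [mr_multivariable()]).}
#' }
#'
#' @param instruments an [mr_instruments] object.
#' @param method estimator, see above.
#' @param ... passed to the individual estimator (e.g. `n_boot`, `seed`,
#'   `penalty`, `random_effects`).
#' @return object of class `mr_fit`.
#' @seealso [wald_ratio()], [mr_ivw()], [mr_egger()],
#'   [mr_weighted_median()], [mr_penalized_weighted_median()],
#'   [mr_multivariable()], [scale_and_transform()]
#' @export
mr_fit <- function(instruments,
                   method = c("ivw", "egger", "wmedian", "pwmedian",
                              "wald", "mvmr"), ...) {
  method <- match.arg(method)
  switch(method,
         wald = with(instruments,
                     wald_ratio(gamma_x, se_x, Gamma_y, se_y)),
         ivw = mr_ivw(instruments, ...),
         egger = mr_egger(instruments, ...),
         wmedian = mr_weighted_median(instruments, ...),
         pwmedian = mr_penalized_weighted_median(instruments, ...),
         mvmr = mr_multivariable(instruments, ...))
}

#' Wald ratio estimate from a single instrument
#'
#' `theta = Gamma_y / gamma_x` with the first-order delta-method SE
#' `|se_y / gamma_x|` (exposure-side uncertainty ignored at leading
#' order).  Invariant to jointly negating the instrument's orientation.
#'
#' @param gamma_x,se_x instrument-exposure effect and SE (`gamma_x != 0`).
#' @param Gamma_y,se_y instrument-outcome effect and SE.
#' @return an `mr_fit` of method `"wald"`.
#' @export
wald_ratio <- function(gamma_x, se_x, Gamma_y, se_y) {
  stopifnot(length(gamma_x) == 1)
  if (gamma_x == 0) stop("gamma_x must be non-zero for a Wald ratio")
  theta <- Gamma_y / gamma_x
  se <- abs(se_y / gamma_x)
  new_mr_fit("wald", theta, se, k = 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' `theta = sum(g G / se_y^2) / sum(g^2 / se_y^2)`; the fixed-effect SE is
#' `(sum(g^2/se_y^2))^(-1/2)`.  Equivalent to weighted regression of the
#' outcome effects on the exposure effects through the origin with weights
#' `1/se_y^2`.  With `random_effects = TRUE` the SE is inflated by the
#' residual scale when it exceeds 1 (multiplicative random-effects model);
#' the default is fixed-effect, with heterogeneity reported separately as
#' Cochran's Q over the per-instrument Wald ratios.
#'
#' @param instruments an [mr_instruments] object (k >= 1).
#' @param random_effects inflate the SE by the residual scale, default
#'   FALSE.
#' @return an `mr_fit` of method `"ivw"` with `q`, `q_df`, `q_p`.
#' @export
mr_ivw <- function(instruments, random_effects = FALSE, ...) {
  ins <- instruments
  k <- nrow(ins)
  if (k < 1) stop("at least one instrument required")
  w <- 1 / ins$se_y^2
  denom <- sum(w * ins$gamma_x^2)
  theta <- sum(w * ins$gamma_x * ins$Gamma_y) / denom
  se <- sqrt(1 / denom)
  qv <- list(q = NA_real_, df = NA_integer_, q_p = NA_real_)
  if (k >= 2) {
    ratio <- ins$Gamma_y / ins$gamma_x
    ratio_se <- abs(ins$se_y / ins$gamma_x)
    qv <- cochran_q(ratio, ratio_se, theta)
    if (random_effects) {
      phi <- max(1, qv$q / (k - 1))
      se <- se * sqrt(phi)
    }
  }
  new_mr_fit("ivw", theta, se, k,
             extra = list(q = qv$q, q_df = qv$df, q_p = qv$q_p,
                          random_effects = random_effects))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1/se_y^2`, after orienting every
#' instrument so `gamma_x >= 0`.  The slope is the causal estimate; the
#' intercept, with its SE and two-sided p (t distribution, k - 2 df), is
#' the test for average directional pleiotropy.
#'
#' @param instruments an [mr_instruments] object (k >= 3).
#' @return an `mr_fit` of method `"egger"` with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(instruments, ...) {
  ins <- orient_instruments(instruments)
  k <- nrow(ins)
  if (k < 3) stop("MR-Egger requires at least 3 instruments")
  w <- 1 / ins$se_y^2
  fit <- stats::lm(Gamma_y ~ gamma_x, data = ins, weights = w)
  cf <- suppressWarnings(summary(fit))$coefficients
  new_mr_fit("egger", theta = cf["gamma_x", 1], se = cf["gamma_x", 2],
             k = k, df = k - 2,
             extra = list(egger_intercept = cf["(Intercept)", 1],
                          egger_intercept_se = cf["(Intercept)", 2],
                          egger_intercept_p = cf["(Intercept)", 4]))
}

# the weighted-median rule: ratios theta sorted ascending with normalized
# weights w; cumulative midpoints s_j = cumsum(w)_j - w_j/2; linear
# interpolation of theta across s at s = 1/2
weighted_median_rule <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

mr_boot_se <- function(ins, estimator, n_boot, seed) {
  with_seed(seed, {
    k <- nrow(ins)
    est <- vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(k, ins$gamma_x, ins$se_x)
      G <- stats::rnorm(k, ins$Gamma_y, ins$se_y)
      estimator(g, G, ins$se_y)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median MR estimate
#'
#' Per-instrument ratios `Gamma_y/gamma_x` are combined by the weighted
#' median rule with inverse-variance weights `gamma_x^2/se_y^2` (the
#' leading-order precision of each ratio).  The estimate is consistent
#' when at least 50% of the total weight comes from valid instruments.
#' The SE comes from a seeded parametric bootstrap: instrument effects are
#' redrawn from normal distributions centred on the observed values with
#' the reported SEs, the rule is re-applied, and the SD over replicates is
#' taken.
#'
#' @param instruments an [mr_instruments] object (k >= 3).
#' @param n_boot bootstrap replicates, default 5000.
#' @param seed RNG seed for the bootstrap (bit-reproducible when set).
#' @return an `mr_fit` of method `"wmedian"` with `n_boot`, `seed`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 5000, seed = NULL) {
  ins <- instruments
  k <- nrow(ins)
  if (k < 3) stop("weighted median MR requires at least 3 instruments")
  w <- ins$gamma_x^2 / ins$se_y^2
  theta <- weighted_median_rule(ins$Gamma_y / ins$gamma_x, w)
  se <- mr_boot_se(ins, function(g, G, se_y)
    weighted_median_rule(G / g, g^2 / se_y^2), n_boot, seed)
  new_mr_fit("wmedian", theta, se, k,
             extra = list(n_boot = n_boot, seed = seed))
}

pw_median_estimate <- function(g, G, se_y, penalty) {
  w <- g^2 / se_y^2
  ratio <- G / g
  t_wm <- weighted_median_rule(ratio, w)
  # one-df chi-square tail of each instrument's heterogeneity contribution
  Qj <- w * (ratio - t_wm)^2
  qj <- stats::pchisq(Qj, df = 1, lower.tail = FALSE)
  # penalty = Inf recovers the unpenalized rule (Inf * 0 must not give NaN)
  fac <- if (is.infinite(penalty)) rep(1, length(qj)) else
    pmin(1, penalty * qj)
  w_pen <- w * fac
  if (sum(w_pen) == 0) return(t_wm)
  weighted_median_rule(ratio, w_pen)
}

#' Penalized weighted median MR estimate
#'
#' Down-weights heterogeneous instruments before applying the weighted
#' median rule: each instrument's contribution to Cochran's Q about the
#' unpenalized weighted-median estimate is converted to a one-df
#' chi-square upper-tail probability `q_j`, and its weight multiplied by
#' `min(1, penalty * q_j)`.  Instruments consistent with the consensus are
#' untouched (the factor caps at 1), so homogeneous sets reproduce the
#' plain weighted median exactly, as does `penalty = Inf`.
#'
#' @inheritParams mr_weighted_median
#' @param penalty penalization constant, default 20.
#' @return an `mr_fit` of method `"pwmedian"`.
#' @export
mr_penalized_weighted_median <- function(instruments, penalty = 20,
                                         n_boot = 5000, seed = NULL) {
  ins <- instruments
  k <- nrow(ins)
  if (k < 3) stop("penalized weighted median MR requires at least 3 instruments")
  theta <- pw_median_estimate(ins$gamma_x, ins$Gamma_y, ins$se_y, penalty)
  se <- mr_boot_se(ins, function(g, G, se_y)
    pw_median_estimate(g, G, se_y, penalty), n_boot, seed)
  new_mr_fit("pwmedian", theta, se, k,
             extra = list(penalty = penalty, n_boot = n_boot, seed = seed))
}

#' Multivariable MR (mediation-adjusted direct effects)
#'
#' Weighted least squares of the instrument-outcome effects on the
#' instruments' effects on several exposures jointly, without intercept
#' and with weights `1/se_y^2`.  Each coefficient is the direct effect of
#' its exposure on the outcome holding the other exposures fixed; with
#' exposure 1 the metabolite and exposures 2+ blood-pressure traits, the
#' first coefficient is the metabolite effect adjusted for blood pressure.
#' Exposure columns that are identically zero are dropped (coefficient
#' `NA`), which reduces the fit to the univariable model in the remaining
#' columns; genuinely collinear exposure columns (condition number above
#' 1e8) raise an error.
#'
#' @param instruments an [mr_instruments] carrying an `exposures` matrix
#'   (its first column defaults to `gamma_x` if absent); at least
#'   `#exposures + 1` instruments.
#' @return an `mr_fit` of method `"mvmr"` whose `theta`, `se`, `ci_*`,
#'   `p` are named vectors, one entry per exposure.
#' @export
mr_multivariable <- function(instruments, ...) {
  ins <- instruments
  X <- attr(ins, "exposures")
  if (is.null(X)) X <- cbind(exposure = ins$gamma_x)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(ins)
  if (k < ncol(X) + 1)
    stop("need at least #exposures + 1 instruments")
  zero_col <- apply(X, 2, function(c) all(c == 0))
  Xf <- X[, !zero_col, drop = FALSE]
  if (ncol(Xf) == 0) stop("all exposure columns are zero")
  w <- 1 / ins$se_y^2
  Xw <- Xf * sqrt(w)
  if (ncol(Xf) > 1) {
    cn <- kappa(crossprod(Xw), exact = TRUE)
    if (!is.finite(cn) || cn > 1e8)
      stop(sprintf("collinear exposure columns (condition %.3g)", cn))
  }
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(Xf * w, ins$Gamma_y)
  beta <- solve(XtWX, XtWy)
  se <- sqrt(diag(solve(XtWX)))
  theta <- se_full <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  theta[!zero_col] <- as.numeric(beta)
  se_full[!zero_col] <- se
  crit <- stats::qnorm(0.975)
  p <- p_from_z(theta / se_full)$p
  structure(list(method = "mvmr", theta = theta, se = se_full,
                 ci_low = theta - crit * se_full,
                 ci_high = theta + crit * se_full,
                 p = p, k = k, df = Inf, dropped = colnames(X)[zero_col]),
            class = "mr_fit")
}

#' Rescale an MR estimate and express it as an odds ratio
#'
#' When instrument-exposure effects were estimated in raw exposure units,
#' dividing them by the exposure SD before estimation or multiplying the
#' fitted causal effect by the SD afterwards are equivalent; this helper
#' takes the second path.  For binary outcomes (log-odds `Gamma_y`), the
#' exponential of the estimate and its confidence bounds gives the odds
#' ratio per exposure SD, preserving the ordering of the bounds.
#'
#' @param estimate an `mr_fit`.
#' @param exposure_sd positive SD of the exposure in the units of
#'   `gamma_x` (e.g. a sex-specific raw-scale SD), default 1.
#' @param as_odds_ratio exponentiate the (rescaled) estimate, default
#'   FALSE.
#' @return an `mr_fit` with rescaled `theta`, `se`, `ci_low`, `ci_high`
#'   (and `or`, `or_ci_low`, `or_ci_high` fields when requested); p-value
#'   unchanged (scale-invariant).
#' @export
scale_and_transform <- function(estimate, exposure_sd = 1,
                                as_odds_ratio = FALSE) {
  stopifnot(inherits(estimate, "mr_fit"))
  if (exposure_sd <= 0) stop("exposure_sd must be positive")
  est <- estimate
  est$theta <- est$theta * exposure_sd
  est$se <- est$se * exposure_sd
  est$ci_low <- est$ci_low * exposure_sd
  est$ci_high <- est$ci_high * exposure_sd
  if (as_odds_ratio) {
    est$or <- exp(est$theta)
    est$or_ci_low <- exp(est$ci_low)
    est$or_ci_high <- exp(est$ci_high)
  }
  est
}
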