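#' Standardize a phenotype within sex strata
#'
#' Centers and scales the phenotype to mean 0, SD 1 separately within each
#' sex stratum, and returns the raw per-sex SDs for downstream unit
#' conversion (e.g. expressing per-SD causal effects on the raw scale).
#'
#' @param values numeric phenotype vector.
#' @param sex factor/character vector with exactly two levels.
#' @return list with `values` (standardized, same order) and `sds` (named
#'   raw per-stratum SDs).
#' @export
standardize_by_sex <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  sex <- as.factor(sex)
  if (nlevels(sex) != 2) stop("exactly two sex strata required")
  out <- numeric(length(values))
  sds <- stats::setNames(numeric(2), levels(sex))
  for (lv in levels(sex)) {
    i <- sex == lv
    if (sum(i) < 2) stop("stratum '", lv, "' has fewer than 2 values")
    s <- stats::sd(values[i])
    if (s == 0) stop("stratum '", lv, "' has zero variance")
    sds[lv] <- s
    out[i] <- (values[i] - mean(values[i])) / s
  }
  list(values = out, sds = sds)
}

#' Test for a sex difference in per-variant genetic effects
#'
#' Contrasts female and male effect estimates (each in within-sex SD
#' units) with
#' \deqn{z_{sex} = (\beta_f - \beta_m) / \sqrt{se_f^2 + se_m^2}}
#' and a two-sided normal p computed in log space, so that extreme
#' statistics (|z| beyond ~38, where the p-value underflows double
#' precision) still produce finite, comparable log p-values.  The
#' Bonferroni decision over `m_tests` loci always uses the exact
#' `alpha/m`.  The same contrast applies to any pair of (estimate, SE)
#' summaries, e.g. sex-specific Mendelian-randomization estimates.
#'
#' @param beta_f,se_f,beta_m,se_m female and male effects and SEs
#'   (vectorized; SEs positive).
#' @param m_tests number of tests in the Bonferroni family, default 1.
#' @param alpha family-wise error rate, default 0.05.
#' @return data frame `z_sex, p_sex, log_p, significant` with threshold
#'   attributes as in [trait_scan()].
#' @examples
#' sex_diff_test(0.691, 0.009, 0.233, 0.007)  # |z| ~ 40, log_p finite
#' @export
sex_diff_test <- function(beta_f, se_f, beta_m, se_m, m_tests = 1,
                          alpha = 0.05) {
  stopifnot(all(se_f > 0), all(se_m > 0))
  z <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  pv <- p_from_z(z)
  thr <- bonferroni_threshold(alpha, m_tests)
  out <- data.frame(z_sex = z, p_sex = pv$p, log_p = pv$log_p,
                    significant = pv$log_p < log(thr$exact))
  attr(out, "threshold_exact") <- thr$exact
  attr(out, "threshold_display") <- thr$display
  out
}

#' Pool sex-specific effects across cohorts, then test the sex contrast
#'
#' Fixed-effect inverse-variance pooling of the female estimates and of
#' the male estimates across cohorts (each cohort having standardized
#' within sex before estimation), followed by [sex_diff_test()] on the
#' pooled pair.
#'
#' @param cohorts data frame with one row per cohort: columns
#'   `beta_f, se_f, beta_m, se_m`.
#' @param m_tests,alpha passed to [sex_diff_test()].
#' @return one-row data frame with pooled `beta_f, se_f, beta_m, se_m` and
#'   the contrast columns of [sex_diff_test()].
#' @export
combine_sex_across_cohorts <- function(cohorts, m_tests = 1, alpha = 0.05) {
  x <- as.data.frame(cohorts)
  stopifnot(all(c("beta_f", "se_f", "beta_m", "se_m") %in% names(x)))
  f <- ivw_effect_meta(x$beta_f, x$se_f)
  m <- ivw_effect_meta(x$beta_m, x$se_m)
  test <- sex_diff_test(f$beta_meta, f$se_meta, m$beta_meta, m$se_meta,
                        m_tests = m_tests, alpha = alpha)
  cbind(data.frame(beta_f = f$beta_meta, se_f = f$se_meta,
                   beta_m = m$beta_meta, se_m = m$se_meta), test)
}
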