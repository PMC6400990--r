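#' Sample-size-weighted Z-score meta-analysis
#'
#' Combines per-study signed Z statistics with weights proportional to the
#' square root of each study's sample size (the standard sample-size
#' scheme):
#' \deqn{z_{meta} = \sum_i \sqrt{n_i}\, z_i \Big/ \sqrt{\sum_i n_i}.}
#' This scheme pools evidence across studies whose effect sizes are not on
#' a common scale (different metabolomics platforms, transformations),
#' using only p-values, directions and sample sizes.
#'
#' @param z numeric vector of signed per-study Z statistics; `NA` entries
#'   (variant missing in a study) contribute nothing and appear as `?` in
#'   the direction string.
#' @param n per-study sample sizes, positive.
#' @return list with `z_meta`, `p_meta` (two-sided normal), `log_p` and
#'   `direction` (one character per study, in input order: `+`, `-`, `0`,
#'   or `?`).
#' @examples
#' stouffer_meta(c(2, 2), c(5000, 5000))$z_meta  # 4/sqrt(2)
#' @export
stouffer_meta <- function(z, n) {
  if (length(z) == 0) stop("no studies to meta-analyse")
  stopifnot(length(z) == length(n))
  if (any(!is.na(z) & (is.na(n) | n <= 0)))
    stop("all sample sizes must be positive")
  direction <- ifelse(is.na(z), "?", ifelse(z > 0, "+", ifelse(z < 0, "-", "0")))
  ok <- !is.na(z)
  if (!any(ok)) stop("no non-missing z entries")
  w <- sqrt(n[ok])
  z_meta <- sum(w * z[ok]) / sqrt(sum(n[ok]))
  pv <- p_from_z(z_meta)
  list(z_meta = z_meta, p_meta = pv$p, log_p = pv$log_p,
       direction = paste(direction, collapse = ""))
}

#' Fixed-effect inverse-variance effect-size meta-analysis
#'
#' Pools per-study effect estimates with weights `1/se^2`:
#' `beta_meta = sum(beta/se^2)/sum(1/se^2)`, `se_meta = sqrt(1/sum(1/se^2))`.
#' Invariant to entry order; identical to weighted least squares of the
#' betas on a constant.
#'
#' @param beta per-study effect estimates.
#' @param se per-study standard errors, positive.
#' @return list with `beta_meta`, `se_meta`, `z_meta`, `p_meta`.
#' @export
ivw_effect_meta <- function(beta, se) {
  if (length(beta) == 0) stop("no studies to meta-analyse")
  stopifnot(length(beta) == length(se))
  ok <- !is.na(beta) & !is.na(se)
  if (!any(ok)) stop("no complete (beta, se) entries")
  if (any(se[ok] <= 0)) stop("all SEs must be positive")
  w <- 1 / se[ok]^2
  beta_meta <- sum(w * beta[ok]) / sum(w)
  se_meta <- sqrt(1 / sum(w))
  z <- beta_meta / se_meta
  list(beta_meta = beta_meta, se_meta = se_meta, z_meta = z,
       p_meta = p_from_z(z)$p)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((beta - pooled)^2 / se^2)` with a chi-square upper-tail p on
#' `k - 1` degrees of freedom.  Used both for between-study heterogeneity
#' of effect sizes and for between-instrument heterogeneity of Wald ratios
#' in Mendelian randomization.
#'
#' @param beta per-entry estimates (at least 2).
#' @param se per-entry standard errors.
#' @param pooled_beta the pooled estimate the deviations are taken from;
#'   defaults to the inverse-variance pooled value.
#' @return list with `q`, `df`, `q_p`.
#' @export
cochran_q <- function(beta, se, pooled_beta = NULL) {
  if (length(beta) < 2) stop("Cochran's Q needs at least 2 entries")
  stopifnot(length(beta) == length(se), all(se > 0))
  if (is.null(pooled_beta)) pooled_beta <- ivw_effect_meta(beta, se)$beta_meta
  q <- sum((beta - pooled_beta)^2 / se^2)
  df <- length(beta) - 1L
  list(q = q, df = df, q_p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Meta-analyse several summary-statistic studies variant by variant
#'
#' Merges studies on variant id, harmonizes every study to the effect
#' allele of the first study carrying each variant, and combines:
#' `scheme = "zscore"` applies [stouffer_meta()] (p-value/direction/
#' sample-size pooling); `scheme = "ivw"` applies [ivw_effect_meta()].
#' Both attach Cochran's Q across studies (where at least two studies
#' carry betas) and the per-study direction string in study input order.
#'
#' @param studies list of [sumstats] objects, in registration order.
#' @param scheme `"zscore"` or `"ivw"`.
#' @param ambiguity_maf palindromic threshold for cross-study harmonization.
#' @return data frame of class `meta_result`: one row per variant with
#'   `snp, chr, pos, ea, oa, eaf, z_meta, p_meta, log_p, beta_meta,
#'   se_meta, n_total, k_studies, direction, q, q_df, q_p`.  `eaf` is the
#'   sample-size-weighted mean effect-allele frequency.
#' @export
meta_sumstats <- function(studies, scheme = c("zscore", "ivw"),
                          ambiguity_maf = 0.40) {
  scheme <- match.arg(scheme)
  stopifnot(length(studies) >= 1, all(vapply(studies, inherits,
                                             logical(1), "sumstats")))
  k <- length(studies)
  all_snps <- unique(unlist(lapply(studies, function(s) s$snp)))
  # per-study aligned statistics, NA when absent
  Z <- B <- SE <- N <- F <- matrix(NA_real_, length(all_snps), k)
  ref <- NULL  # first-seen row per variant provides orientation + coords
  ref_rows <- vector("list", length(all_snps))
  for (j in seq_len(k)) {
    s <- as.data.frame(studies[[j]])
    idx <- match(all_snps, s$snp)
    for (i in which(!is.na(idx))) {
      row <- s[idx[i], ]
      if (is.null(ref_rows[[i]])) {
        ref_rows[[i]] <- row
      } else {
        h <- tryCatch(harmonize_pair(ref_rows[[i]], row, ambiguity_maf),
                      error = function(e) NULL)
        if (is.null(h) || h$action == "ambiguous-dropped") next
        row <- as.data.frame(h$b, stringsAsFactors = FALSE)
      }
      Z[i, j] <- row$z; B[i, j] <- row$beta; SE[i, j] <- row$se
      N[i, j] <- row$n; F[i, j] <- row$eaf
    }
  }
  res <- lapply(seq_along(all_snps), function(i) {
    ok <- !is.na(Z[i, ]) | !is.na(B[i, ])
    ki <- sum(ok)
    n_tot <- sum(N[i, ok], na.rm = TRUE)
    eafw <- if (any(!is.na(F[i, ok]) & !is.na(N[i, ok]))) {
      w <- N[i, ok]; f <- F[i, ok]
      sum(w * f, na.rm = TRUE) / sum(w[!is.na(f)], na.rm = TRUE)
    } else NA_real_
    sm <- tryCatch(stouffer_meta(Z[i, ], N[i, ]), error = function(e) NULL)
    im <- tryCatch(ivw_effect_meta(B[i, ], SE[i, ]), error = function(e) NULL)
    qv <- list(q = NA_real_, df = NA_integer_, q_p = NA_real_)
    okb <- !is.na(B[i, ]) & !is.na(SE[i, ])
    if (sum(okb) >= 2)
      qv <- cochran_q(B[i, okb], SE[i, okb],
                      if (!is.null(im)) im$beta_meta else NULL)
    r <- ref_rows[[i]]
    data.frame(snp = all_snps[i], chr = r$chr, pos = r$pos, ea = r$ea,
               oa = r$oa, eaf = eafw,
               z_meta = if (scheme == "zscore" && !is.null(sm)) sm$z_meta
                        else if (!is.null(im)) im$z_meta else NA_real_,
               p_meta = if (scheme == "zscore" && !is.null(sm)) sm$p_meta
                        else if (!is.null(im)) im$p_meta else NA_real_,
               log_p = if (scheme == "zscore" && !is.null(sm)) sm$log_p
                       else NA_real_,
               beta_meta = if (!is.null(im)) im$beta_meta else NA_real_,
               se_meta = if (!is.null(im)) im$se_meta else NA_real_,
               n_total = n_tot, k_studies = ki,
               direction = if (!is.null(sm)) sm$direction
                           else paste(rep("?", k), collapse = ""),
               q = qv$q, q_df = qv$df, q_p = qv$q_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Coverage and frequency restriction of meta-analysis results
#'
#' Studies differing in imputation strategy cover different variant sets;
#' the meta-analysis is restricted to variants observed in at least two
#' studies, covering more than half the grand total sample size, and with
#' minor-allele frequency of at least 0.1%.
#'
#' @param meta `meta_result` data frame (needs `k_studies`, `n_total`,
#'   `eaf` or a `maf` column).
#' @param n_grand_total combined sample size of all contributing studies.
#' @param min_studies,min_n_frac,maf_min thresholds (defaults 2, 0.5, 0.001).
#' @return the surviving subset, same class; exclusion counts in
#'   `attr(, "coverage_report")`.
#' @export
coverage_filter <- function(meta, n_grand_total, min_studies = 2,
                            min_n_frac = 0.5, maf_min = 0.001) {
  stopifnot(n_grand_total > 0)
  maf <- if (!is.null(meta$maf)) meta$maf else pmin(meta$eaf, 1 - meta$eaf)
  fail_k <- meta$k_studies < min_studies
  fail_n <- meta$n_total <= min_n_frac * n_grand_total
  fail_maf <- !is.na(maf) & maf < maf_min
  keep <- !(fail_k | fail_n | fail_maf)
  out <- meta[keep, , drop = FALSE]
  attr(out, "coverage_report") <- c(n_studies = sum(fail_k),
                                    n_frac = sum(fail_n),
                                    maf = sum(fail_maf))
  out
}
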