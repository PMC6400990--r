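#' Ground-truth configuration for synthetic cohorts
#'
#' Fixes every generative parameter of the synthetic metabolite-GWAS /
#' disease-outcome system so that pipeline estimates can be compared with
#' known truth.  The genetic architecture emulates a metabolite with one
#' dominant locus and sex-dimorphic per-allele effects: per-variant true
#' effects are expressed in within-sex SD units of the latent (log-scale)
#' metabolite, the first variant carries `dominant_share` of the male
#' heritability and its female effect is `dominant_sex_ratio` times the
#' male one (default 3, the observed near-three-fold dimorphism of the
#' strongest glycine locus); raw metabolite values are log-normal with
#' configurable per-sex log-scale SDs (defaults 0.321 women / 0.195 men).
#' Minor-allele frequencies are drawn once, reproducibly, from
#' `maf_range`.
#'
#' @param seed integer seed; fixes MAFs and true effect vectors.
#' @param n_exposure,n_outcome sample sizes of the two non-overlapping
#'   samples (defaults 20000 each).
#' @param m_variants number of variants (default 24, the common-locus
#'   score size).
#' @param maf_range MAF range for the uniform draw, default c(0.05, 0.5).
#' @param ld_blocks list of `list(size, rho)` blocks; sizes must sum to
#'   `m_variants`; default independent variants (all blocks size 1).
#' @param h2 male-stratum heritability target in [0,1), default 0.10;
#'   the female value follows from the effect vectors.
#' @param dominant_share share of male h2 at the dominant locus, default
#'   0.25.
#' @param dominant_sex_ratio female/male per-allele effect ratio at the
#'   dominant locus, default 3.
#' @param beta_f,beta_m explicit per-variant true effects (within-sex SD
#'   units); when supplied they override the h2-based construction and
#'   `h2` is derived from them.
#' @param sex_sd_f,sex_sd_m raw-scale (log) SDs per sex, defaults
#'   0.321 and 0.195.
#' @param theta causal effect of the standardized exposure on outcome
#'   liability, default -0.05 (a modest protective effect).
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param tau2 pleiotropy variance, `mu_alpha` directional mean.
#' @param outcome_type `"binary"` (liability threshold) or
#'   `"quantitative"`; `case_fraction` for binary outcomes, default 0.15.
#' @return object of class `sim_config` (a list of the above plus the
#'   realized `maf` vector).
#' @export
sim_config <- function(seed = 1, n_exposure = 20000, n_outcome = 20000,
                       m_variants = 24, maf_range = c(0.05, 0.5),
                       ld_blocks = NULL, h2 = 0.10,
                       dominant_share = 0.25, dominant_sex_ratio = 3,
                       beta_f = NULL, beta_m = NULL,
                       sex_sd_f = 0.321, sex_sd_m = 0.195,
                       theta = -0.05,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       tau2 = 0, mu_alpha = 0,
                       outcome_type = c("binary", "quantitative"),
                       case_fraction = 0.15) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5, tau2 >= 0,
            m_variants >= 1, h2 >= 0, h2 < 1)
  if (is.null(ld_blocks))
    ld_blocks <- lapply(seq_len(m_variants), function(i) list(size = 1, rho = 0))
  sizes <- vapply(ld_blocks, function(b) b$size, numeric(1))
  if (sum(sizes) != m_variants)
    stop("ld_blocks sizes must sum to m_variants")
  maf <- with_seed(seed, stats::runif(m_variants, maf_range[1], maf_range[2]))
  v <- 2 * maf * (1 - maf)
  if (is.null(beta_m)) {
    share <- if (m_variants == 1) 1 else
      c(dominant_share, rep((1 - dominant_share) / (m_variants - 1),
                            m_variants - 1))
    beta_m <- sqrt(h2 * share / v)
    beta_f <- beta_m
    beta_f[1] <- dominant_sex_ratio * beta_m[1]
  } else if (is.null(beta_f)) beta_f <- beta_m
  stopifnot(length(beta_f) == m_variants, length(beta_m) == m_variants)
  h2_m <- sum(v * beta_m^2); h2_f <- sum(v * beta_f^2)
  if (h2_m >= 1 || h2_f >= 1)
    stop(sprintf("h2 infeasible given betas (male %.3f, female %.3f)",
                 h2_m, h2_f))
  # per-allele effect on the pooled-standardized (sex-combined) metabolite:
  # raw log values are sigma_sex * latent, so the pooled marginal effect is
  # the sex-average of sigma * beta over the pooled SD
  beta_combined <- (sex_sd_f * beta_f + sex_sd_m * beta_m) / 2 /
    sqrt((sex_sd_f^2 + sex_sd_m^2) / 2)
  structure(list(seed = seed, n_exposure = n_exposure, n_outcome = n_outcome,
                 m_variants = m_variants, maf_range = maf_range, maf = maf,
                 ld_blocks = ld_blocks, beta_f = beta_f, beta_m = beta_m,
                 beta_combined = beta_combined,
                 h2_m = h2_m, h2_f = h2_f, sex_sd_f = sex_sd_f,
                 sex_sd_m = sex_sd_m, theta = theta,
                 pleiotropy_mode = pleiotropy_mode, tau2 = tau2,
                 mu_alpha = mu_alpha, outcome_type = outcome_type,
                 case_fraction = case_fraction),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort config: %d variants, n = %d/%d ",
                     "(exposure/outcome)\n  h2 male %.3f, female %.3f; ",
                     "theta = %g; pleiotropy %s (tau2 = %g, mu = %g); ",
                     "outcome %s\n"),
              x$m_variants, x$n_exposure, x$n_outcome, x$h2_m, x$h2_f,
              x$theta, x$pleiotropy_mode, x$tau2, x$mu_alpha,
              x$outcome_type))
  invisible(x)
}

#' Simulate LD-blocked diploid genotypes
#'
#' Draws two haplotypes per individual from a latent-Gaussian threshold
#' model: within a block, haplotype-level latents share an equicorrelation
#' `rho` and an allele is carried when the latent falls below the MAF
#' quantile; blocks are independent; the dosage is the sum of the two
#' haplotypes.  Thresholding attenuates the latent `rho` into a smaller
#' dosage correlation; the attenuation is characterized exactly by the
#' bivariate-normal orthant probability (see tests), not assumed.
#'
#' @param config a [sim_config].
#' @param n number of individuals; default `config$n_exposure`.
#' @param seed optional seed (identical matrices for identical seeds);
#'   `NULL` uses the current RNG stream.
#' @param haplotypes also return the haplotype matrix (for D').
#' @return list with `dosages` (n x m, columns `v1..vm`), `ld` (an
#'   [ld_ref] computed from the generated sample, with D' when
#'   `haplotypes = TRUE`), `config`.
#' @export
simulate_genotypes <- function(config, n = config$n_exposure, seed = NULL,
                               haplotypes = FALSE) {
  with_seed(seed, {
    m <- config$m_variants
    H <- matrix(0L, 2 * n, m)
    col <- 1L
    for (b in config$ld_blocks) {
      s <- b$size; rho <- b$rho
      Z <- matrix(stats::rnorm(2 * n * s), 2 * n, s)
      if (s > 1 && rho > 0) {
        common <- stats::rnorm(2 * n)
        Z <- sqrt(rho) * common + sqrt(1 - rho) * Z
      }
      thr <- stats::qnorm(config$maf[col:(col + s - 1)])
      H[, col:(col + s - 1)] <- (Z < matrix(thr, 2 * n, s, byrow = TRUE)) + 0L
      col <- col + s
    }
    D <- H[seq_len(n) * 2 - 1, , drop = FALSE] +
         H[seq_len(n) * 2, , drop = FALSE]
    colnames(D) <- paste0("v", seq_len(m))
    colnames(H) <- colnames(D)
    vars <- data.frame(snp = colnames(D), chr = "1",
                       pos = 100000L * seq_len(m), ea = "A", oa = "G",
                       eaf = colMeans(D) / 2, stringsAsFactors = FALSE)
    ld <- ld_from_dosages(D, vars, haplotypes = if (haplotypes) H else NULL)
    list(dosages = D, ld = ld, config = config)
  })
}

#' Simulate raw (log-normal) metabolite values
#'
#' Latent value = sum of sex-specific per-allele effects (within-sex SD
#' units) on centred dosages plus normal noise with variance `1 - h2_sex`,
#' so the genetic fraction of the latent variance is the configured
#' per-sex heritability.  Raw values are `exp(sigma_sex * latent)` with
#' the configured per-sex log-scale SDs, so the pipeline's log transform,
#' winsorization and standardization are all exercised.
#'
#' @param dosages n x m dosage matrix.
#' @param sex character/factor of `"F"`/`"M"` per individual.
#' @param config a [sim_config].
#' @param seed optional seed.
#' @return list with `raw` (positive values), `latent` (within-sex
#'   standardized scale), `config`.
#' @export
simulate_metabolite <- function(dosages, sex, config, seed = NULL) {
  with_seed(seed, {
    n <- nrow(dosages)
    stopifnot(length(sex) == n)
    female <- sex == "F"
    ctr <- sweep(dosages, 2, 2 * config$maf)
    g <- numeric(n)
    g[female] <- as.numeric(ctr[female, , drop = FALSE] %*% config$beta_f)
    g[!female] <- as.numeric(ctr[!female, , drop = FALSE] %*% config$beta_m)
    noise_sd <- ifelse(female, sqrt(1 - config$h2_f), sqrt(1 - config$h2_m))
    latent <- g + stats::rnorm(n, 0, noise_sd)
    sigma <- ifelse(female, config$sex_sd_f, config$sex_sd_m)
    raw <- exp(sigma * latent)
    list(raw = raw, latent = latent, config = config)
  })
}

# draw per-variant direct (pleiotropic) outcome effects
draw_pleiotropy <- function(config) {
  m <- config$m_variants
  switch(config$pleiotropy_mode,
         none = rep(0, m),
         balanced = stats::rnorm(m, 0, sqrt(config$tau2)),
         directional = stats::rnorm(m, config$mu_alpha, sqrt(config$tau2)))
}

#' Simulate a disease outcome from exposure and genotypes
#'
#' Liability = `theta * standardized exposure + sum_j alpha_j dosage_j +
#' noise`, with per-variant direct effects `alpha` drawn according to the
#' configured pleiotropy mode (`none`: all zero; `balanced`: mean-zero
#' normal with variance `tau2`; `directional`: mean `mu_alpha`).  Binary
#' outcomes threshold the liability at its `1 - case_fraction` quantile;
#' quantitative outcomes return the liability itself.
#'
#' @param dosages n x m dosage matrix for the outcome sample.
#' @param exposure exposure values for the same individuals (standardized
#'   internally).
#' @param config a [sim_config].
#' @param seed optional seed.
#' @return list with `outcome` (0/1 or numeric), `alpha` (realized direct
#'   effects), `config`.
#' @export
simulate_outcome <- function(dosages, exposure, config, seed = NULL) {
  with_seed(seed, {
    n <- nrow(dosages)
    stopifnot(length(exposure) == n)
    alpha <- draw_pleiotropy(config)
    x <- (exposure - mean(exposure)) / stats::sd(exposure)
    liability <- config$theta * x +
      as.numeric(dosages %*% alpha) + stats::rnorm(n)
    outcome <- if (config$outcome_type == "binary") {
      thr <- stats::quantile(liability, 1 - config$case_fraction)
      as.integer(liability > thr)
    } else liability
    list(outcome = outcome, alpha = alpha, config = config)
  })
}

#' Per-variant marginal association scan (summary-statistic GWAS)
#'
#' Least-squares marginal regression of the phenotype on each variant's
#' dosage, optionally adjusted for covariates (phenotype and dosages are
#' residualized on the covariates first, which is equivalent to including
#' them in each model).  Binary phenotypes are fitted per variant by
#' logistic regression, giving effects on the log-odds scale.  Monomorphic
#' variants yield a row with missing effect, reported by message.
#'
#' @param dosages n x m dosage matrix with column names.
#' @param phenotype numeric vector (analysis-ready, see
#'   [prep_phenotype()]) or 0/1 for `family = "binomial"`.
#' @param covariates optional numeric matrix/data frame.
#' @param family `"gaussian"` or `"binomial"`.
#' @param variant_info optional data frame (`snp, chr, pos, ea, oa`) for
#'   the output; synthetic coordinates are used when absent.
#' @param study_id,trait metadata for the returned [sumstats].
#' @return a [sumstats] object with per-variant `eaf, beta, se, z, p, n`.
#' @export
cohort_gwas <- function(dosages, phenotype, covariates = NULL,
                        family = c("gaussian", "binomial"),
                        variant_info = NULL, study_id = "sim",
                        trait = "metabolite") {
  family <- match.arg(family)
  D <- as.matrix(dosages)
  n <- nrow(D); m <- ncol(D)
  stopifnot(length(phenotype) == n)
  snp <- colnames(D) %||% paste0("v", seq_len(m))
  mono <- apply(D, 2, function(x) stats::var(x) == 0)
  if (any(mono))
    message(sum(mono), " monomorphic variant(s): effect set to NA")
  beta <- se <- rep(NA_real_, m)
  if (family == "gaussian") {
    q <- 0
    if (!is.null(covariates)) {
      C <- cbind(1, as.matrix(covariates))
      q <- ncol(C) - 1
      qrC <- qr(C)
      y <- qr.resid(qrC, phenotype)
      X <- qr.resid(qrC, D)
    } else {
      y <- phenotype - mean(phenotype)
      X <- sweep(D, 2, colMeans(D))
    }
    sxx <- colSums(X^2)
    syy <- sum(y^2)
    sxy <- as.numeric(crossprod(X, y))
    ok <- !mono
    beta[ok] <- sxy[ok] / sxx[ok]
    rss <- syy - beta[ok]^2 * sxx[ok]
    df <- n - 2 - q
    se[ok] <- sqrt(pmax(rss, 0) / df / sxx[ok])
  } else {
    for (j in which(!mono)) {
      Xj <- cbind(1, D[, j], if (!is.null(covariates)) as.matrix(covariates))
      fit <- suppressWarnings(
        stats::glm.fit(Xj, phenotype, family = stats::binomial()))
      cf <- fit$coefficients[2]
      # observed-information SE
      W <- fit$weights
      V <- tryCatch(solve(crossprod(Xj * sqrt(W))), error = function(e) NULL)
      if (is.null(V) || !is.finite(cf)) next
      beta[j] <- cf
      se[j] <- sqrt(V[2, 2])
    }
  }
  if (is.null(variant_info))
    variant_info <- data.frame(snp = snp, chr = "1",
                               pos = 100000L * seq_len(m),
                               ea = "A", oa = "G", stringsAsFactors = FALSE)
  tab <- data.frame(variant_info, eaf = colMeans(D) / 2, beta = beta,
                    se = se, n = n, stringsAsFactors = FALSE)
  sumstats(tab, study_id = study_id, trait = trait, n_total = n)
}

#' Prepare a raw metabolite for association analysis
#'
#' Natural-log transform, winsorize at 5 SDs from the mean (SD computed
#' before clipping), then standardize to mean 0, SD 1 — in exactly that
#' order.
#'
#' @param raw positive raw values.
#' @param winsor_sd clipping bound in SDs, default 5.
#' @return standardized analysis-ready vector.
#' @export
prep_phenotype <- function(raw, winsor_sd = 5) {
  if (any(raw <= 0)) stop("raw metabolite values must be positive")
  y <- log(raw)
  mu <- mean(y); s <- stats::sd(y)
  y <- pmin(pmax(y, mu - winsor_sd * s), mu + winsor_sd * s)
  (y - mean(y)) / stats::sd(y)
}

#' Adjust measured blood pressure for antihypertensive treatment
#'
#' Adds 15 mmHg to systolic and 10 mmHg to diastolic pressure for treated
#' individuals, approximating the untreated value; untreated individuals
#' are unchanged.  Apply to raw measurements once only.
#'
#' @param sbp,dbp measured pressures (mmHg).
#' @param on_treatment logical vector.
#' @return data frame with adjusted `sbp`, `dbp`.
#' @export
bp_medication_adjust <- function(sbp, dbp, on_treatment) {
  stopifnot(length(sbp) == length(dbp), length(sbp) == length(on_treatment))
  data.frame(sbp = sbp + 15 * as.numeric(on_treatment),
             dbp = dbp + 10 * as.numeric(on_treatment))
}

#' Summary-level two-sample instrument generator
#'
#' Generates a harmonized instrument set directly at the summary level,
#' emulating a sex-combined exposure GWAS: true exposure effects are the
#' configured sex-combined per-allele effects on the pooled-standardized
#' metabolite; observed effects are drawn from normal sampling distributions
#' with the SEs implied by the two sample sizes
#' (`se = 1/sqrt(2 p (1-p) n)` for a standardized trait); outcome effects
#' are `theta * gamma + alpha` with pleiotropy `alpha` redrawn per call.
#' Orders of magnitude faster than the individual-level chain, with the
#' same first-two-moment structure, so estimator calibration can be
#' replicated cheaply.
#'
#' @param config a [sim_config].
#' @param seed optional seed.
#' @return an [mr_instruments]; ground truth in `attr(, "truth")`
#'   (`theta`, `gamma_true`, `alpha`).
#' @export
simulate_mr_summary <- function(config, seed = NULL) {
  with_seed(seed, {
    v <- 2 * config$maf * (1 - config$maf)
    gamma_true <- config$beta_combined
    se_x <- 1 / sqrt(v * config$n_exposure)
    se_y <- 1 / sqrt(v * config$n_outcome)
    alpha <- draw_pleiotropy(config)
    g <- stats::rnorm(config$m_variants, gamma_true, se_x)
    G <- stats::rnorm(config$m_variants, config$theta * gamma_true + alpha,
                      se_y)
    ins <- mr_instruments(g, se_x, G, se_y,
                          snp = paste0("v", seq_len(config$m_variants)))
    attr(ins, "truth") <- list(theta = config$theta,
                               gamma_true = gamma_true, alpha = alpha)
    ins
  })
}

#' Full individual-level two-sample simulation chain
#'
#' Generates two non-overlapping samples (the two-sample design: exposure
#' and outcome GWAS never share individuals), runs the per-variant
#' association scans in each, harmonizes the shared variants, and returns
#' the instrument set together with all ground truth.
#'
#' @param config a [sim_config].
#' @param seed seed for the whole chain (deterministic end to end).
#' @return list with `exposure` and `outcome` [sumstats], `ld` (exposure
#'   sample [ld_ref]), `instruments` ([mr_instruments]), `truth`.
#' @export
simulate_two_sample <- function(config, seed = 1) {
  with_seed(seed, {
    # exposure sample
    gx <- simulate_genotypes(config, n = config$n_exposure)
    sex_x <- sample(c("F", "M"), config$n_exposure, replace = TRUE)
    met <- simulate_metabolite(gx$dosages, sex_x, config)
    pheno <- prep_phenotype(met$raw)
    ss_x <- cohort_gwas(gx$dosages, pheno, study_id = "exposure_sample")
    # outcome sample
    gy <- simulate_genotypes(config, n = config$n_outcome)
    sex_y <- sample(c("F", "M"), config$n_outcome, replace = TRUE)
    met_y <- simulate_metabolite(gy$dosages, sex_y, config)
    # theta acts per SD of the measured (log-scale) exposure, the same
    # quantity the exposure GWAS estimates effects on
    out <- simulate_outcome(gy$dosages, log(met_y$raw), config)
    ss_y <- cohort_gwas(gy$dosages, out$outcome,
                        family = if (config$outcome_type == "binary")
                          "binomial" else "gaussian",
                        study_id = "outcome_sample", trait = "disease")
    h <- harmonize_sumstats(ss_x, ss_y)
    ins <- mr_instruments(h$beta.x, h$se.x, h$beta.y, h$se.y, snp = h$snp)
    list(exposure = ss_x, outcome = ss_y, ld = gx$ld, instruments = ins,
         truth = list(theta = config$theta, alpha = out$alpha,
                      config = config))
  })
}
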