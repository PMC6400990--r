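test_that("configuration validates its generative parameters", {
  cfg <- sim_config(seed = 1, m_variants = 6)
  expect_s3_class(cfg, "sim_config")
  expect_length(cfg$maf, 6)
  expect_true(all(cfg$maf >= 0.05 & cfg$maf <= 0.5))
  # identical seeds give identical ground truth
  expect_identical(cfg$maf, sim_config(seed = 1, m_variants = 6)$maf)
  expect_identical(cfg$beta_f, sim_config(seed = 1, m_variants = 6)$beta_f)
  # female h2 exceeds male under the default dimorphic dominant locus
  expect_gt(cfg$h2_f, cfg$h2_m)
  expect_error(sim_config(ld_blocks = list(list(size = 3, rho = 0.5))),
               "sum to m_variants")
  expect_error(sim_config(m_variants = 2, maf_range = c(0.4, 0.5),
                          beta_m = c(2, 2)), "infeasible")
})

test_that("genotype generation is reproducible and matches its MAFs", {
  cfg <- sim_config(seed = 71, m_variants = 10)
  g1 <- simulate_genotypes(cfg, n = 10000, seed = 5)
  g2 <- simulate_genotypes(cfg, n = 10000, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))
  # empirical frequencies within binomial sampling error of the configured
  eaf <- colMeans(g1$dosages) / 2
  se <- sqrt(cfg$maf * (1 - cfg$maf) / (2 * 10000))
  expect_true(all(abs(eaf - cfg$maf) < 4 * se))
})

test_that("uncorrelated blocks show no LD at n = 10000", {
  cfg <- sim_config(seed = 72, m_variants = 12)   # all blocks size 1
  g <- simulate_genotypes(cfg, n = 10000, seed = 6)
  off <- abs(g$ld$R[upper.tri(g$ld$R)])
  expect_lt(quantile(off, 0.99), 0.05)
})

test_that("block correlation matches the bivariate-normal oracle", {
  # oracle: dosage correlation implied by thresholding latent Gaussians
  # with correlation rho at the MAF quantile, via the orthant probability
  orthant <- function(q, rho) {
    integrate(function(x) pnorm((q - rho * x) / sqrt(1 - rho^2)) * dnorm(x),
              -Inf, q, rel.tol = 1e-10)$value
  }
  maf <- 0.3; rho <- 0.9
  q <- qnorm(maf)
  p11 <- orthant(q, rho)
  r_oracle <- (p11 - maf^2) / (maf * (1 - maf))
  cfg <- sim_config(seed = 73, m_variants = 2, maf_range = c(0.3, 0.3),
                    ld_blocks = list(list(size = 2, rho = 0.9)))
  g <- simulate_genotypes(cfg, n = 10000, seed = 7)
  r_emp <- g$ld$R[1, 2]
  # thresholding attenuates the latent rho = 0.9 to a dosage correlation
  # near 0.7 at this MAF; the oracle, not a guessed band, is the reference
  expect_gt(r_emp, 0.6); expect_lt(r_emp, 0.95)
  expect_lt(abs(r_emp - r_oracle), 0.03)
})

test_that("haplotype output yields a D' matrix near 1 within a block", {
  cfg <- sim_config(seed = 74, m_variants = 2, maf_range = c(0.2, 0.2),
                    ld_blocks = list(list(size = 2, rho = 0.95)))
  g <- simulate_genotypes(cfg, n = 5000, seed = 8, haplotypes = TRUE)
  expect_false(is.null(g$ld$dprime))
  expect_gt(g$ld$dprime[1, 2], 0.5)
  expect_lte(g$ld$dprime[1, 2], 1)
})

test_that("LD reference round-trips through its text format", {
  cfg <- sim_config(seed = 75, m_variants = 4,
                    ld_blocks = list(list(size = 4, rho = 0.5)))
  g <- simulate_genotypes(cfg, n = 2000, seed = 9, haplotypes = TRUE)
  mp <- tempfile(); sp <- tempfile(); dp <- tempfile()
  write_ld_ref(g$ld, mp, sp, dp)
  ld2 <- read_ld_ref(mp, sp, dp)
  expect_equal(ld2$R, g$ld$R, tolerance = 1e-12)
  expect_equal(ld2$dprime, g$ld$dprime, tolerance = 1e-12)
  expect_equal(ld2$variants$eaf, g$ld$variants$eaf, tolerance = 1e-12)
  expect_equal(ld2$n_ref, g$ld$n_ref)
})

test_that("sex-dimorphic effects are recovered on the standardized scale", {
  cfg <- sim_config(seed = 76, m_variants = 24, h2 = 0.10,
                    dominant_share = 1 / 24, dominant_sex_ratio = 3)
  set.seed(600)
  g <- simulate_genotypes(cfg, n = 40000)
  sex <- rep(c("F", "M"), 20000)
  met <- simulate_metabolite(g$dosages, sex, cfg)
  st <- standardize_by_sex(log(met$raw), sex)
  f <- sex == "F"
  bf <- cov(g$dosages[f, 1], st$values[f]) / var(g$dosages[f, 1])
  bm <- cov(g$dosages[!f, 1], st$values[!f]) / var(g$dosages[!f, 1])
  expect_gt(bf / bm, 2.6); expect_lt(bf / bm, 3.4)
})

test_that("null architectures produce null association scans", {
  cfg <- sim_config(seed = 77, m_variants = 400, h2 = 0,
                    beta_m = rep(0, 400), beta_f = rep(0, 400))
  set.seed(601)
  g <- simulate_genotypes(cfg, n = 2000)
  sex <- rep(c("F", "M"), 1000)
  met <- simulate_metabolite(g$dosages, sex, cfg)
  ss <- cohort_gwas(g$dosages, prep_phenotype(met$raw))
  expect_equal(sum(ss$p < 5e-8), 0)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.03)
})

test_that("heritability programmed into the simulator is recovered", {
  cfg <- sim_config(seed = 78, m_variants = 24, h2 = 0.15,
                    dominant_sex_ratio = 1)
  set.seed(602)
  g <- simulate_genotypes(cfg, n = 20000)
  sex <- rep(c("F", "M"), 10000)
  met <- simulate_metabolite(g$dosages, sex, cfg)
  ph <- prep_phenotype(met$raw)
  sc <- build_score(data.frame(snp = paste0("v", 1:24), ea = "A", oa = "G",
                               beta = cfg$beta_m))
  r2 <- score_r2(score_values(g$dosages, sc), ph)
  expect_gt(r2, 0.13); expect_lt(r2, 0.17)
})

test_that("per-variant association scan has OLS sampling behaviour", {
  set.seed(603)
  n <- 10000
  cfg <- sim_config(seed = 79, m_variants = 5)
  g <- simulate_genotypes(cfg, n = n)
  y <- 0.5 * g$dosages[, 3] + rnorm(n)
  ss <- cohort_gwas(g$dosages, y)
  expect_lt(abs(ss$beta[3] - 0.5), 3 * ss$se[3])
  expect_equal(ss$n[3], n)
  # permuted phenotype: null calibration
  ssp <- cohort_gwas(g$dosages, sample(y))
  expect_true(all(ssp$p > 1e-4))
  # adjusting for the noise component shrinks the SE, leaves beta unbiased
  noise <- y - 0.5 * g$dosages[, 3]
  ssa <- cohort_gwas(g$dosages, y, covariates = cbind(noise))
  expect_lt(ssa$se[3], ss$se[3])
  expect_lt(abs(ssa$beta[3] - 0.5), 3 * ssa$se[3])
  # monomorphic variants yield NA rows, with a message
  D <- g$dosages; D[, 2] <- 0
  expect_message(ssm <- cohort_gwas(D, y), "monomorphic")
  expect_true(is.na(ssm$beta[2]))
})

test_that("logistic scan returns log-odds effects for binary outcomes", {
  set.seed(604)
  n <- 6000
  cfg <- sim_config(seed = 80, m_variants = 3)
  g <- simulate_genotypes(cfg, n = n)
  lin <- -2 + 0.4 * g$dosages[, 1]
  y <- rbinom(n, 1, plogis(lin))
  ss <- cohort_gwas(g$dosages, y, family = "binomial")
  expect_lt(abs(ss$beta[1] - 0.4), 3 * ss$se[1])
  fit <- glm(y ~ g$dosages[, 1], family = binomial())
  expect_equal(ss$beta[1], unname(coef(fit)[2]), tolerance = 1e-6)
})

test_that("phenotype preparation follows log, winsorize, standardize", {
  set.seed(605)
  raw <- exp(rnorm(1000))
  y <- prep_phenotype(raw)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sd(y), 1, tolerance = 1e-12)
  # without outliers winsorization changes nothing
  expect_equal(y, as.numeric(scale(log(raw))), tolerance = 1e-12)
  # a 7-SD point sits at exactly +5 pre-standardization SDs
  lg <- rnorm(10000)
  s0 <- sd(c(lg, 7 * sd(lg)))  # SD including the outlier, pre-clipping
  raw2 <- exp(c(lg, 0))
  mu <- mean(log(raw2)); s <- sd(log(raw2))
  raw2[length(raw2)] <- exp(mu + 7 * s)
  mu2 <- mean(log(raw2)); s2 <- sd(log(raw2))
  clipped <- pmin(pmax(log(raw2), mu2 - 5 * s2), mu2 + 5 * s2)
  expect_equal(max(clipped), mu2 + 5 * s2)
  y2 <- prep_phenotype(raw2)
  expect_equal(y2[which.max(raw2)],
               ((mu2 + 5 * s2) - mean(clipped)) / sd(clipped))
  expect_error(prep_phenotype(c(1, 0, 2)), "positive")
})

test_that("blood-pressure medication adjustment adds 15/10 mmHg once", {
  adj <- bp_medication_adjust(c(140, 120), c(90, 80), c(TRUE, FALSE))
  expect_equal(adj$sbp, c(155, 120))
  expect_equal(adj$dbp, c(100, 80))
})

test_that("summary-level generator centres on its ground truth", {
  cfg <- sim_config(seed = 81, theta = 0.2, dominant_sex_ratio = 1,
                    outcome_type = "quantitative")
  ins <- simulate_mr_summary(cfg, seed = 10)
  expect_identical(ins, simulate_mr_summary(cfg, seed = 10))
  truth <- attr(ins, "truth")
  expect_equal(truth$theta, 0.2)
  expect_equal(truth$alpha, rep(0, 24))
  # observed effects scatter around truth at the stated SEs
  z <- (ins$gamma_x - truth$gamma_true) / ins$se_x
  expect_lt(abs(mean(z)), 3 / sqrt(24) + 1)
  expect_lt(max(abs(z)), 5)
})

test_that("the full two-sample chain recovers the causal effect", {
  cfg <- sim_config(seed = 82, n_exposure = 8000, n_outcome = 8000,
                    theta = 0.2, outcome_type = "quantitative",
                    dominant_sex_ratio = 1)
  sim <- simulate_two_sample(cfg, seed = 12)
  expect_identical(sim$instruments,
                   simulate_two_sample(cfg, seed = 12)$instruments)
  f <- mr_ivw(sim$instruments)
  expect_lt(abs(f$theta - 0.2), 3 * f$se)
  # binary outcomes give log-odds instrument-outcome effects
  cfgb <- sim_config(seed = 83, n_exposure = 3000, n_outcome = 3000,
                     m_variants = 6, theta = 0.3, outcome_type = "binary",
                     case_fraction = 0.3, dominant_sex_ratio = 1)
  simb <- simulate_two_sample(cfgb, seed = 13)
  expect_setequal(unique(simb$outcome$n), 3000)
  fb <- mr_ivw(simb$instruments)
  expect_gt(fb$theta, 0)   # protective/adverse direction preserved
})
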