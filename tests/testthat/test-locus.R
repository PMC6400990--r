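make_meta <- function(snp, chr, pos, p) {
  data.frame(snp = snp, chr = chr, pos = pos, p_meta = p,
             stringsAsFactors = FALSE)
}

test_that("distance clumping groups variants greedily by significance", {
  # two significant variants 0.5 Mb apart within a 1 Mb half-window: one locus
  m <- make_meta(c("a", "b"), "1", c(10.0e6, 10.5e6), c(1e-10, 1e-9))
  loci <- clump(m, half_window = 1e6)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$lead$snp, "a")
  expect_equal(nrow(loci[[1]]$members), 2)
  # a third variant outside the window founds its own locus
  m2 <- rbind(m, make_meta("c", "1", 12.1e6, 1e-9))
  loci2 <- clump(m2, half_window = 1e6)
  expect_length(loci2, 2)
  expect_equal(loci2[[2]]$lead$snp, "c")
  # non-significant variants never appear
  m3 <- rbind(m2, make_meta("d", "1", 10.2e6, 1e-5))
  expect_equal(sum(vapply(clump(m3, half_window = 1e6),
                          function(l) nrow(l$members), numeric(1))), 3)
  # different chromosomes never merge
  m4 <- make_meta(c("a", "b"), c("1", "2"), c(1e6, 1e6), c(1e-10, 1e-9))
  expect_length(clump(m4), 2)
})

test_that("per-variant window overrides widen a locus", {
  m <- make_meta(c("lead", "far"), "2", c(10e6, 12.5e6), c(1e-300, 1e-9))
  # default 0.5 Mb half-window: two loci
  expect_length(clump(m), 2)
  # 3 Mb on both sides of the top variant: absorbed
  loci <- clump(m, special_windows = c(lead = 3e6))
  expect_length(loci, 1)
  expect_equal(loci[[1]]$window, c(7e6, 13e6))
})

test_that("clump leads are separated and assignment is a partition", {
  set.seed(9)
  n <- 200
  m <- make_meta(paste0("v", 1:n), sample(c("1", "2"), n, TRUE),
                 sample.int(5e7, n), 10^-runif(n, 4, 30))
  loci <- clump(m, p_thresh = 5e-8, half_window = 5e5)
  assigned <- unlist(lapply(loci, function(l) l$members$snp))
  expect_equal(sort(assigned), sort(m$snp[m$p_meta < 5e-8]))
  expect_false(anyDuplicated(assigned) > 0)
  for (i in seq_along(loci)) for (j in seq_along(loci)) {
    if (i >= j) next
    a <- loci[[i]]; b <- loci[[j]]
    if (a$lead$chr == b$lead$chr)
      expect_gt(abs(a$lead$pos - b$lead$pos),
                max(a$half_window, b$half_window))
  }
})

test_that("ties in clumping break by position then id", {
  m <- make_meta(c("b", "a"), "1", c(2000, 1000), c(1e-9, 1e-9))
  expect_equal(clump(m, half_window = 100)[[1]]$lead$snp, "a")
})

test_that("joint model reduces to marginal for k = 1 and orthogonal LD", {
  mem <- data.frame(snp = "rs1", beta = 0.4, se = 0.05, n = 8000, eaf = 0.3)
  fit <- cojo_joint(mem, toy_ld(1, eaf = 0.3, snps = "rs1"))
  expect_equal(fit$beta_joint, 0.4, tolerance = 1e-9)
  expect_equal(fit$se_joint, 0.05, tolerance = 0.01)
  mem2 <- data.frame(snp = c("rs1", "rs2"), beta = c(0.4, 0.2),
                     se = c(0.05, 0.05), n = 8000, eaf = c(0.3, 0.3))
  fit2 <- cojo_joint(mem2, toy_ld(2, r = 0, eaf = c(0.3, 0.3),
                                  snps = c("rs1", "rs2")))
  expect_equal(fit2$beta_joint, c(0.4, 0.2), tolerance = 1e-9)
})

test_that("joint estimates from summaries match multiple regression", {
  # brute-force OLS oracle on the generating genotypes
  cfg <- sim_config(seed = 21, n_exposure = 5000, m_variants = 5,
                    ld_blocks = list(list(size = 5, rho = 0.6)),
                    beta_m = c(0.25, 0, 0.15, 0, 0.1),
                    dominant_sex_ratio = 1)
  set.seed(100)
  g <- simulate_genotypes(cfg, n = 5000)
  y <- as.numeric(g$dosages %*% cfg$beta_m) + rnorm(5000)
  y <- (y - mean(y)) / sd(y)
  marg <- cohort_gwas(g$dosages, y)
  joint <- cojo_joint(data.frame(snp = marg$snp, beta = marg$beta,
                                 se = marg$se, n = marg$n, eaf = marg$eaf),
                      g$ld)
  ols <- coef(lm(y ~ g$dosages))[-1]
  expect_lt(max(abs(joint$beta_joint - ols)), 0.02)
  expect_lt(max(abs(joint$beta_joint - ols)) / max(abs(ols)), 0.05)
  # SEs are on the right scale too
  se_ols <- summary(lm(y ~ g$dosages))$coefficients[-1, 2]
  expect_lt(max(abs(joint$se_joint / se_ols - 1)), 0.15)
})

test_that("collinear members raise an error naming the offending pair", {
  mem <- data.frame(snp = c("rs1", "rs2"), beta = c(0.4, 0.39),
                    se = 0.05, n = 8000, eaf = 0.3)
  ld <- toy_ld(2, r = 0.999999999, eaf = c(0.3, 0.3), snps = c("rs1", "rs2"))
  expect_error(cojo_joint(mem, ld), "collinear.*rs[12].*rs[12]")
})

test_that("stepwise selection finds true signals, not LD shadows", {
  # one causal variant with pure-LD shadows at rho = 0.9
  cfg <- sim_config(seed = 31, n_exposure = 8000, m_variants = 4,
                    ld_blocks = list(list(size = 4, rho = 0.9)),
                    beta_m = c(0.25, 0, 0, 0), dominant_sex_ratio = 1)
  set.seed(200)
  g <- simulate_genotypes(cfg, n = 8000)
  y <- scale(as.numeric(g$dosages %*% cfg$beta_m) + rnorm(8000))[, 1]
  marg <- cohort_gwas(g$dosages, y)
  mem <- data.frame(snp = marg$snp, beta = marg$beta, se = marg$se,
                    n = marg$n, eaf = marg$eaf, p = marg$p, pos = marg$pos)
  sel <- cojo_stepwise(mem, g$ld)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$snp, "v1")

  # two independent causal variants, both genome-wide significant
  cfg2 <- sim_config(seed = 32, n_exposure = 8000, m_variants = 4,
                     ld_blocks = list(list(size = 2, rho = 0.1),
                                      list(size = 2, rho = 0.1)),
                     beta_m = c(0.2, 0, 0.15, 0), dominant_sex_ratio = 1)
  set.seed(201)
  g2 <- simulate_genotypes(cfg2, n = 8000)
  y2 <- scale(as.numeric(g2$dosages %*% cfg2$beta_m) + rnorm(8000))[, 1]
  marg2 <- cohort_gwas(g2$dosages, y2)
  mem2 <- data.frame(snp = marg2$snp, beta = marg2$beta, se = marg2$se,
                     n = marg2$n, eaf = marg2$eaf, p = marg2$p,
                     pos = marg2$pos)
  sel2 <- cojo_stepwise(mem2, g2$ld)
  expect_setequal(sel2$snp, c("v1", "v3"))

  # nothing beyond the lead clears the threshold (independent variants,
  # flat candidates)
  mem3 <- data.frame(snp = c("a", "b", "c"), beta = c(0.4, 0.02, 0.01),
                     se = 0.02, n = 8000, eaf = 0.3,
                     p = 2 * pnorm(-abs(c(0.4, 0.02, 0.01) / 0.02)))
  ld3 <- toy_ld(3, r = 0, eaf = rep(0.3, 3), snps = c("a", "b", "c"))
  sel3 <- cojo_stepwise(mem3, ld3)
  expect_equal(sel3$snp, "a")
})

test_that("candidates below the MAF floor are omitted from selection", {
  mem <- data.frame(snp = c("rs1", "rs2"), beta = c(0.4, 0.5),
                    se = 0.02, n = 8000, eaf = c(0.3, 0.005),
                    p = c(1e-80, 1e-100))
  ld <- toy_ld(2, r = 0, eaf = c(0.3, 0.005), snps = c("rs1", "rs2"))
  sel <- cojo_stepwise(mem, ld)
  expect_equal(sel$snp, "rs1")
})

test_that("LD pruning drops correlated selections and D' haplotype sharers", {
  sel <- data.frame(snp = c("s1", "s2", "s3"),
                    p_joint = c(1e-20, 1e-10, 1e-9),
                    eaf = c(0.3, 0.3, 0.3))
  R <- diag(3); R[1, 2] <- R[2, 1] <- sqrt(0.2)   # r2 = 0.2 with kept s1
  ld <- ld_ref(data.frame(snp = c("s1", "s2", "s3"), eaf = 0.3), R, 1000)
  out <- prune_selected(sel, ld)
  expect_equal(out$snp, c("s1", "s3"))
  expect_equal(attr(out, "prune_report")$dropped_r2, "s2")
  # r2 = 0.01: both kept; r2 exactly 0.05 kept (strict inequality)
  for (r2 in c(0.01, 0.05)) {
    R2 <- diag(2); R2[1, 2] <- R2[2, 1] <- sqrt(r2)
    ld2 <- ld_ref(data.frame(snp = c("s1", "s2"), eaf = 0.3), R2, 1000)
    expect_equal(nrow(prune_selected(sel[1:2, ], ld2)), 2)
  }
  # low-frequency variant in near-complete haplotype sharing with the
  # common sentinel is removed by the D' stage
  dp <- matrix(1, 2, 2)
  ldd <- ld_ref(data.frame(snp = c("s1", "s2"), eaf = c(0.3, 0.004)),
                diag(2), 1000, dprime = dp)
  sel2 <- data.frame(snp = c("s1", "s2"), p_joint = c(1e-20, 1e-10),
                     eaf = c(0.3, 0.004))
  out2 <- prune_selected(sel2, ldd)
  expect_equal(out2$snp, "s1")
  expect_equal(attr(out2, "prune_report")$dropped_dprime, "s2")
  # common variants are exempt from the D' stage
  sel3 <- data.frame(snp = c("s1", "s2"), p_joint = c(1e-20, 1e-10),
                     eaf = c(0.3, 0.2))
  expect_equal(nrow(prune_selected(sel3, ldd)), 2)
})

test_that("variance explained follows 2p(1-p)beta^2", {
  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_equal(variance_explained(0, 0.27), 0)
  # the strongest glycine locus: printed beta and EAF give 13.7%
  expect_equal(round(100 * variance_explained(0.565, 0.313), 1), 13.7)
  # allele-relabelling symmetry
  expect_equal(variance_explained(0.3, 0.2), variance_explained(-0.3, 0.8))
  # cumulative version is a non-decreasing sum over independent variants
  cv <- variance_explained(c(0.5, 0.1, 0.3), c(0.3, 0.2, 0.4),
                           cumulative = TRUE)
  expect_true(all(diff(cv) >= 0))
  expect_equal(cv[3], sum(variance_explained(c(0.5, 0.1, 0.3),
                                             c(0.3, 0.2, 0.4))))
  expect_error(variance_explained(0.5, 1), "eaf")
})
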