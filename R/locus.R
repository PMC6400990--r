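#' Distance-based clumping of meta-analysis results into loci
#'
#' Greedy assignment by ascending p-value: the most significant remaining
#' variant below `p_thresh` becomes a locus lead; every variant on the
#' same chromosome within `half_window` basepairs of it joins that locus
#' and is removed from further consideration; repeat until no variant
#' below the threshold remains.  Per-variant window overrides (e.g. a wide
#' 3 Mb window on both sides of an exceptionally strong, broad signal)
#' are given via `special_windows`.  Ties on p are broken by ascending
#' position, then variant id, for determinism.
#'
#' @param meta data frame with `snp, chr, pos` and `p_meta` (or `p`);
#'   `log_p` is used to order extreme p-values when present.
#' @param p_thresh genome-wide significance threshold, default 5e-8.
#' @param half_window half-width in bp around the lead; default 5e5
#'   (a 1 Mb total window).
#' @param special_windows named numeric vector, snp -> half-width in bp.
#' @return list of `locus` objects (class `loci`), each with `lead` (the
#'   lead variant's row), `window` (start, end), `members` (rows assigned),
#'   `n_signals` (1 until conditional analysis adds secondaries).
#' @export
clump <- function(meta, p_thresh = 5e-8, half_window = 5e5,
                  special_windows = NULL) {
  x <- as.data.frame(meta)
  if (is.null(x$p_meta) && !is.null(x$p)) x$p_meta <- x$p
  stopifnot(!is.null(x$p_meta), !is.null(x$pos), !is.null(x$chr))
  ord_key <- if (!is.null(x$log_p) && !anyNA(x$log_p)) x$log_p else x$p_meta
  x <- x[order(ord_key, x$pos, x$snp), , drop = FALSE]
  x <- x[!is.na(x$p_meta) & x$p_meta < p_thresh, , drop = FALSE]
  loci <- list()
  while (nrow(x) > 0) {
    lead <- x[1, ]
    hw <- half_window
    if (!is.null(special_windows) && lead$snp %in% names(special_windows))
      hw <- special_windows[[lead$snp]]
    in_win <- x$chr == lead$chr & abs(x$pos - lead$pos) <= hw
    members <- x[in_win, , drop = FALSE]
    loci[[length(loci) + 1]] <- structure(
      list(lead = lead, window = c(lead$pos - hw, lead$pos + hw),
           half_window = hw, members = members, secondary = NULL,
           n_signals = 1L),
      class = "locus")
    x <- x[!in_win, , drop = FALSE]
  }
  structure(loci, class = "loci")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("Locus %s (chr%s:%d), lead p = %.3g, %d member(s), %d signal(s)\n",
              x$lead$snp, x$lead$chr, x$lead$pos, x$lead$p_meta,
              nrow(x$members), x$n_signals))
  invisible(x)
}

#' @export
print.loci <- function(x, ...) {
  cat(length(x), "loci\n")
  for (l in x) print(l)
  invisible(x)
}

# reconstructed normal equations for a set of variants:
# v_j = 2 eaf_j (1-eaf_j); S_jk = sqrt(v_j v_k) R_jk;
# (X'X)_jk = sqrt(n_j n_k) S_jk; (X'y)_j = n_j v_j beta_j
cojo_normal_eq <- function(members, ld) {
  v <- 2 * members$eaf * (1 - members$eaf)
  R <- ld$R
  S <- sqrt(outer(v, v)) * R
  n <- members$n
  XtX <- sqrt(outer(n, n)) * S
  Xty <- n * v * members$beta
  list(XtX = XtX, Xty = Xty, v = v, S = S)
}

#' Approximate joint association model from marginal statistics
#'
#' Reconstructs the multiple-regression normal equations from marginal
#' per-variant summary statistics and an external LD correlation matrix
#' (the COJO approximation): with `v_j = 2 eaf_j (1 - eaf_j)` the
#' Hardy-Weinberg dosage variance, `S = sqrt(v v') * R` approximates the
#' genotype covariance, `X'X ~ sqrt(n_j n_k) S_jk` and
#' `(X'y)_j ~ n_j v_j beta_j`; the joint coefficients are
#' `(X'X)^{-1} X'y`.  The phenotypic variance is estimated robustly as the
#' median over member variants of `v_j beta_j^2 + v_j n_j se_j^2`, the
#' residual variance from the fitted model, and joint SEs from the
#' diagonal of `sigma^2 (X'X)^{-1}` with two-sided normal p-values.
#'
#' @param members data frame of summary rows (`snp, beta, se, n, eaf`),
#'   all present in `ld`.
#' @param ld an [ld_ref] (will be subset/reordered to `members$snp`).
#' @return data frame `snp, beta_joint, se_joint, z_joint, p_joint, log_p`.
#' @export
cojo_joint <- function(members, ld) {
  members <- as.data.frame(members)
  stopifnot(all(c("snp", "beta", "se", "n", "eaf") %in% names(members)))
  ld <- ld_subset(ld, members$snp)
  eq <- cojo_normal_eq(members, ld)
  k <- nrow(members)
  if (k > 1) {
    cn <- kappa(eq$S, exact = TRUE)
    if (!is.finite(cn) || cn > 1e8) {
      A <- abs(ld$R); diag(A) <- 0
      worst <- which(A == max(A), arr.ind = TRUE)[1, ]
      stop(sprintf("collinear variants in joint model (condition %.3g): %s and %s",
                   cn, members$snp[worst[1]], members$snp[worst[2]]))
    }
  }
  beta_j <- solve(eq$XtX, eq$Xty)
  sigma2_y <- stats::median(eq$v * members$beta^2 +
                              eq$v * members$n * members$se^2)
  n_eff <- stats::median(members$n)
  yty <- n_eff * sigma2_y
  rss <- yty - sum(beta_j * eq$Xty)
  df <- max(n_eff - k, 1)
  sigma2 <- max(rss / df, .Machine$double.eps)
  se_j <- sqrt(sigma2 * diag(solve(eq$XtX)))
  z <- beta_j / se_j
  pv <- p_from_z(z)
  data.frame(snp = members$snp, beta_joint = as.numeric(beta_j),
             se_joint = se_j, z_joint = as.numeric(z),
             p_joint = pv$p, log_p = pv$log_p,
             stringsAsFactors = FALSE)
}

#' Stepwise selection of conditionally independent signals at a locus
#'
#' Forward selection seeded with the locus lead (smallest marginal p).
#' Candidates with minor-allele frequency below `maf_min` are omitted.  At
#' each step the candidate with the smallest conditional p (its joint p in
#' a model with the currently selected variants) is added if that p is
#' below `p_joint_thresh` and its squared correlation with every selected
#' variant does not exceed the collinearity guard `r2_guard`; after each
#' addition the model is re-fitted jointly and any selected variant whose
#' joint p has risen above the threshold is dropped (the lead may itself be
#' displaced by a better-fitting neighbour).  Terminates when no candidate
#' qualifies; the result is order-stable for identical inputs.
#'
#' @param locus_members data frame of summary rows at the locus
#'   (`snp, beta, se, n, eaf, p`).
#' @param ld an [ld_ref] covering the members.
#' @param p_joint_thresh joint significance threshold, default 5e-8.
#' @param r2_guard collinearity guard on r2 within the model, default 0.9.
#' @param maf_min candidate MAF floor, default 0.01.
#' @param max_iter safety cap on selection steps.
#' @return data frame of selected variants with their joint statistics
#'   (columns of [cojo_joint()]), ordered by selection step.
#' @export
cojo_stepwise <- function(locus_members, ld, p_joint_thresh = 5e-8,
                          r2_guard = 0.9, maf_min = 0.01, max_iter = 50) {
  x <- as.data.frame(locus_members)
  if (is.null(x$p)) x$p <- p_from_z(x$beta / x$se)$p
  maf <- pmin(x$eaf, 1 - x$eaf)
  x <- x[maf >= maf_min, , drop = FALSE]
  if (nrow(x) == 0) stop("no candidates at MAF >= ", maf_min)
  x <- x[order(x$p, x$pos %||% seq_len(nrow(x)), x$snp), , drop = FALSE]
  selected <- x$snp[1]
  for (iter in seq_len(max_iter)) {
    candidates <- setdiff(x$snp, selected)
    best <- NULL
    for (cand in candidates) {
      r2s <- ld_subset(ld, c(selected, cand))$R[length(selected) + 1,
                                                seq_along(selected)]^2
      if (any(r2s > r2_guard)) next
      fit <- tryCatch(
        cojo_joint(x[match(c(selected, cand), x$snp), ], ld),
        error = function(e) NULL)
      if (is.null(fit)) next
      lp <- fit$log_p[nrow(fit)]
      if (is.null(best) || lp < best$lp) best <- list(snp = cand, lp = lp)
    }
    if (is.null(best) || best$lp >= log(p_joint_thresh)) break
    selected <- c(selected, best$snp)
    # backward pass: drop any variant whose joint p rose above threshold
    repeat {
      fit <- cojo_joint(x[match(selected, x$snp), ], ld)
      weak <- fit$log_p >= log(p_joint_thresh)
      if (!any(weak) || length(selected) == 1) break
      drop_i <- which.max(fit$log_p)
      selected <- selected[-drop_i]
    }
  }
  fit <- cojo_joint(x[match(selected, x$snp), ], ld)
  fit
}

#' LD pruning of conditionally selected variants
#'
#' Two-stage filter of a jointly selected variant set, ordered by joint p
#' ascending: (1) greedily keep the most significant variant and drop any
#' later variant with `r2 > r2_max` (strict) to an already-kept variant;
#' (2) optionally, for low-frequency variants (MAF below `low_freq_maf`),
#' drop those whose |D'| with the common sentinel variant exceeds
#' `dprime_max` — haplotype-sharing with the sentinel makes their
#' conditional estimates unreliable.  The D' threshold is configurable
#' because reported conventions for this filter conflict.
#'
#' @param selected data frame with `snp`, `p_joint` (or `log_p`), `eaf`.
#' @param ld an [ld_ref]; D' stage requires `ld$dprime`.
#' @param r2_max r2 ceiling between kept variants, default 0.05.
#' @param dprime_max D' ceiling against the sentinel, default 0.95.
#' @param sentinel snp id of the common sentinel for the D' stage; default
#'   the most significant kept variant.
#' @param low_freq_maf MAF bound defining "low-frequency", default 0.01.
#' @return the pruned subset of `selected`; dropped ids and stage in
#'   `attr(, "prune_report")`.
#' @export
prune_selected <- function(selected, ld, r2_max = 0.05, dprime_max = 0.95,
                           sentinel = NULL, low_freq_maf = 0.01) {
  x <- as.data.frame(selected)
  key <- if (!is.null(x$log_p)) x$log_p else x$p_joint
  x <- x[order(key, x$snp), , drop = FALSE]
  kept <- integer(0)
  dropped <- character(0)
  for (i in seq_len(nrow(x))) {
    if (length(kept)) {
      r2 <- ld_subset(ld, c(x$snp[kept], x$snp[i]))$R[length(kept) + 1,
                                                      seq_along(kept)]^2
      if (any(r2 > r2_max)) { dropped <- c(dropped, x$snp[i]); next }
    }
    kept <- c(kept, i)
  }
  out <- x[kept, , drop = FALSE]
  dropped_dp <- character(0)
  if (!is.null(ld$dprime) && nrow(out) > 1) {
    if (is.null(sentinel)) sentinel <- out$snp[1]
    if (sentinel %in% out$snp) {
      maf <- pmin(out$eaf, 1 - out$eaf)
      sub <- ld_subset(ld, out$snp)
      dp <- sub$dprime[, match(sentinel, out$snp)]
      hit <- out$snp != sentinel & !is.na(maf) & maf < low_freq_maf &
        abs(dp) > dprime_max
      dropped_dp <- out$snp[hit]
      out <- out[!hit, , drop = FALSE]
    }
  }
  attr(out, "prune_report") <- list(dropped_r2 = dropped,
                                    dropped_dprime = dropped_dp)
  out
}

#' Variance in a standardized trait explained by a biallelic variant
#'
#' For a trait standardized to unit variance, a variant with per-allele
#' effect `beta_std` (trait SD per allele) and effect-allele frequency
#' `eaf` explains `2 eaf (1 - eaf) beta_std^2` of the trait variance under
#' Hardy-Weinberg equilibrium.  The cumulative variance over independent
#' variants is the sum of the per-variant terms.
#'
#' @param beta_std per-allele effect in trait SD units (vectorized).
#' @param eaf effect-allele frequency, strictly inside (0,1).
#' @param cumulative if TRUE return the cumulative sum over the vector.
#' @return fraction(s) of variance explained.
#' @examples
#' variance_explained(0.565, 0.313)  # ~0.137
#' @export
variance_explained <- function(beta_std, eaf, cumulative = FALSE) {
  if (any(eaf <= 0 | eaf >= 1))
    stop("eaf must be strictly between 0 and 1")
  r2 <- 2 * eaf * (1 - eaf) * beta_std^2
  if (cumulative) cumsum(r2) else r2
}
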