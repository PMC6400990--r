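#' Build an effect-size-weighted genetic score
#'
#' Constructs a per-allele-weighted score from meta-analysed summary
#' statistics.  Every weight is oriented to the exposure-raising allele:
#' variants whose listed effect allele lowers the exposure have their
#' alleles swapped and the weight made positive, so that tiered subsets of
#' a score are unambiguous.  Variants named in `exclude` (e.g.
#' low-frequency or rare variants without look-ups in all outcome
#' datasets) are removed and reported.
#'
#' @param rows summary rows (`snp, ea, oa, beta`), typically meta results
#'   (columns `beta_meta` accepted).
#' @param variants character vector naming the variants to include;
#'   default all rows.
#' @param name score name.
#' @param tier_parent optional [genetic_score] (or its name) this score is
#'   a tier (subset) of; the subset invariant is checked.
#' @param exclude variant ids to drop, reported in the result.
#' @return object of class `genetic_score`: data frame
#'   `snp, ea, weight` with attributes `name`, `tier_parent`, `excluded`.
#' @export
build_score <- function(rows, variants = NULL, name = "score",
                        tier_parent = NULL, exclude = NULL) {
  x <- as.data.frame(rows)
  if (is.null(x$beta) && !is.null(x$beta_meta)) x$beta <- x$beta_meta
  stopifnot(all(c("snp", "ea", "oa", "beta") %in% names(x)))
  if (is.null(variants)) variants <- x$snp
  variants <- setdiff(variants, exclude)
  idx <- match(variants, x$snp)
  if (anyNA(idx))
    stop("score variant absent from summary statistics: ",
         paste(variants[is.na(idx)], collapse = ", "))
  x <- x[idx, , drop = FALSE]
  flip <- x$beta < 0
  ea <- ifelse(flip, x$oa, x$ea)
  w <- abs(x$beta)
  if (any(!is.finite(w))) stop("non-finite weight in score")
  parent_name <- NULL
  if (!is.null(tier_parent)) {
    if (inherits(tier_parent, "genetic_score")) {
      if (!all(variants %in% tier_parent$snp))
        stop("tier is not a subset of its parent score")
      parent_name <- attr(tier_parent, "name")
    } else parent_name <- as.character(tier_parent)
  }
  structure(data.frame(snp = x$snp, ea = ea, weight = w,
                       stringsAsFactors = FALSE),
            class = c("genetic_score", "data.frame"),
            name = name, tier_parent = parent_name,
            excluded = exclude %||% character(0))
}

#' @export
print.genetic_score <- function(x, ...) {
  cat(sprintf("Genetic score '%s': %d variants%s\n", attr(x, "name"),
              nrow(x),
              if (is.null(attr(x, "tier_parent"))) ""
              else paste0(" (tier of '", attr(x, "tier_parent"), "')")))
  if (length(attr(x, "excluded")))
    cat("  excluded:", paste(attr(x, "excluded"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Per-individual genetic score values
#'
#' `value_i = sum_j weight_j * dosage_ij`, linear in the dosages.  Dosage
#' columns are matched to score variants by name and must already count
#' the score's effect allele; if the matrix carries an `effect_allele`
#' attribute (named by snp), mismatched columns are flipped (`2 - dosage`).
#'
#' @param dosages individuals x variants matrix with values in [0,2],
#'   columns named by snp.
#' @param score a [genetic_score].
#' @return numeric vector of per-individual score values.
#' @export
score_values <- function(dosages, score) {
  stopifnot(inherits(score, "genetic_score"))
  dosages <- as.matrix(dosages)
  idx <- match(score$snp, colnames(dosages))
  if (anyNA(idx))
    stop("missing dosage column(s): ",
         paste(score$snp[is.na(idx)], collapse = ", "))
  D <- dosages[, idx, drop = FALSE]
  ea <- attr(dosages, "effect_allele")
  if (!is.null(ea)) {
    flip <- ea[score$snp] != score$ea
    flip[is.na(flip)] <- FALSE
    if (any(flip)) D[, flip] <- 2 - D[, flip]
  }
  as.numeric(D %*% score$weight)
}

#' Variance in a phenotype explained by a genetic score
#'
#' Squared Pearson correlation between the individual score values and the
#' (standardized) phenotype.
#'
#' @param values per-individual score values.
#' @param phenotype phenotype vector, same length.
#' @return r2 in [0,1].
#' @export
score_r2 <- function(values, phenotype) {
  stopifnot(length(values) == length(phenotype))
  if (stats::sd(values) == 0) stop("zero-variance score")
  if (stats::sd(phenotype) == 0) stop("zero-variance phenotype")
  stats::cor(values, phenotype)^2
}

#' Scan a genetic score against a panel of traits
#'
#' Fits, per trait, the linear model `trait ~ score + covariates` by least
#' squares and reports the score coefficient with a two-sided normal
#' p-value (appropriate at cohort-scale n).  Multiple testing is
#' controlled by Bonferroni over the scanned traits: the significance
#' decision always uses the exact `alpha/m`; the threshold is also
#' reported in display rounding (see [bonferroni_threshold()]).  Constant
#' trait columns are flagged and skipped.  Decisions are invariant to
#' trait column order.
#'
#' @param values per-individual score values.
#' @param traits matrix or data frame, one standardized trait per column.
#' @param covariates optional matrix/data frame of adjustment columns
#'   (e.g. sex, measurement batch).
#' @param alpha family-wise error rate, default 0.05.
#' @return data frame `trait, beta, se, z, p, log_p, significant, skipped`
#'   with attributes `threshold_exact`, `threshold_display`, `m`.
#' @export
trait_scan <- function(values, traits, covariates = NULL, alpha = 0.05) {
  traits <- as.matrix(traits)
  m <- ncol(traits)
  if (is.null(colnames(traits))) colnames(traits) <- paste0("trait", 1:m)
  X <- cbind(intercept = 1, score = values)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  thr <- bonferroni_threshold(alpha, m)
  qrX <- qr(X)
  XtXinv_score <- chol2inv(qr.R(qrX))[2, 2]
  n <- length(values)
  res <- lapply(seq_len(m), function(j) {
    y <- traits[, j]
    if (stats::sd(y) == 0)
      return(data.frame(trait = colnames(traits)[j], beta = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        log_p = NA_real_, significant = NA, skipped = TRUE))
    fit <- qr.coef(qrX, y)
    resid <- y - qr.fitted(qrX, y)
    sigma2 <- sum(resid^2) / (n - ncol(X))
    se <- sqrt(sigma2 * XtXinv_score)
    z <- fit[2] / se
    pv <- p_from_z(z)
    data.frame(trait = colnames(traits)[j], beta = fit[2], se = se, z = z,
               p = pv$p, log_p = pv$log_p,
               significant = pv$log_p < log(thr$exact), skipped = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "threshold_exact") <- thr$exact
  attr(out, "threshold_display") <- thr$display
  attr(out, "m") <- m
  out
}
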