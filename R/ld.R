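#' LD reference panel
#'
#' Holds the pairwise correlation matrix `R` (unit diagonal, symmetric) of
#' a set of variants in a reference sample, their effect-allele
#' frequencies, the reference sample size, and optionally a matrix of D'
#' values.  Used by the approximate conditional/joint machinery and by the
#' LD pruning rules.
#'
#' @param variants data frame with at least `snp` and `eaf` (optionally
#'   `chr, pos, ea, oa`).
#' @param R square correlation matrix, rows/cols in `variants` order.
#' @param n_ref reference panel sample size.
#' @param dprime optional square matrix of D' values in [0,1].
#' @return object of class `ld_ref`.
#' @export
ld_ref <- function(variants, R, n_ref, dprime = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(!is.null(variants$snp), !is.null(variants$eaf))
  m <- nrow(variants)
  R <- as.matrix(R)
  if (!all(dim(R) == c(m, m)))
    stop("R dimensions do not match the variant table")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  if (max(abs(R)) > 1 + 1e-8) stop("|R| entries must be <= 1")
  if (!is.null(dprime)) {
    dprime <- as.matrix(dprime)
    if (!all(dim(dprime) == c(m, m)))
      stop("dprime dimensions do not match the variant table")
  }
  dimnames(R) <- list(variants$snp, variants$snp)
  if (!is.null(dprime)) dimnames(dprime) <- dimnames(R)
  structure(list(variants = variants, R = R, n_ref = n_ref,
                 dprime = dprime),
            class = "ld_ref")
}

#' @export
print.ld_ref <- function(x, ...) {
  cat(sprintf("LD reference: %d variants, n_ref = %s%s\n",
              nrow(x$variants), format(x$n_ref),
              if (is.null(x$dprime)) "" else ", with D'"))
  invisible(x)
}

# subset an ld_ref to named variants, preserving order of `snps`
ld_subset <- function(ld, snps) {
  idx <- match(snps, ld$variants$snp)
  if (anyNA(idx))
    stop("variant(s) absent from LD reference: ",
         paste(snps[is.na(idx)], collapse = ", "))
  ld_ref(ld$variants[idx, , drop = FALSE],
         ld$R[idx, idx, drop = FALSE], ld$n_ref,
         if (!is.null(ld$dprime)) ld$dprime[idx, idx, drop = FALSE])
}

#' Build an LD reference from a dosage matrix
#'
#' Computes the sample correlation matrix of the dosages and, when phased
#' haplotypes are supplied, the D' matrix from haplotype allele
#' frequencies (D' = D / Dmax with D the haplotype-frequency covariance).
#'
#' @param dosages n x m matrix of dosages in [0,2], columns named by snp.
#' @param variants variant table (snp, eaf filled from the sample if absent).
#' @param haplotypes optional (2n) x m 0/1 haplotype matrix for D'.
#' @return an [ld_ref].
#' @export
ld_from_dosages <- function(dosages, variants = NULL, haplotypes = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(variants))
    variants <- data.frame(snp = colnames(dosages) %||%
                             paste0("v", seq_len(ncol(dosages))),
                           stringsAsFactors = FALSE)
  if (is.null(variants$eaf)) variants$eaf <- colMeans(dosages) / 2
  sds <- apply(dosages, 2, stats::sd)
  if (any(sds == 0)) stop("monomorphic variant(s) in LD sample: ",
                          paste(variants$snp[sds == 0], collapse = ", "))
  R <- stats::cor(dosages)
  R <- (R + t(R)) / 2; diag(R) <- 1
  dp <- NULL
  if (!is.null(haplotypes)) {
    H <- as.matrix(haplotypes)
    p <- colMeans(H)
    m <- ncol(H)
    dp <- matrix(1, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      pab <- mean(H[, i] * H[, j])
      D <- pab - p[i] * p[j]
      dmax <- if (D >= 0) min(p[i] * (1 - p[j]), (1 - p[i]) * p[j])
              else min(p[i] * p[j], (1 - p[i]) * (1 - p[j]))
      dp[i, j] <- dp[j, i] <- if (dmax == 0) 0 else abs(D) / dmax
    }
  }
  ld_ref(variants, R, nrow(dosages), dp)
}

#' Write / read an LD reference as plain text
#'
#' The correlation matrix is a tab-separated square of floats; the sidecar
#' TSV lists the variants (SNP, CHR, POS, EA, OA, EAF); an optional D'
#' matrix has the same shape as R.
#'
#' @param ld an [ld_ref].
#' @param matrix_path,sidecar_path,dprime_path file paths (`dprime_path`
#'   optional).
#' @return paths invisibly (write) or an [ld_ref] (read).
#' @export
write_ld_ref <- function(ld, matrix_path, sidecar_path, dprime_path = NULL) {
  utils::write.table(format(ld$R, digits = 17, trim = TRUE), matrix_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  v <- ld$variants
  out <- data.frame(SNP = v$snp, CHR = v$chr %||% NA, POS = v$pos %||% NA,
                    EA = v$ea %||% NA, OA = v$oa %||% NA, EAF = v$eaf,
                    N_REF = ld$n_ref)
  utils::write.table(out, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dprime_path) && !is.null(ld$dprime))
    utils::write.table(format(ld$dprime, digits = 17, trim = TRUE),
                       dprime_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, sidecar_path, dprime_path))
}

#' @rdname write_ld_ref
#' @export
read_ld_ref <- function(matrix_path, sidecar_path, dprime_path = NULL) {
  R <- as.matrix(utils::read.table(matrix_path, sep = "\t"))
  side <- utils::read.delim(sidecar_path, sep = "\t",
                            stringsAsFactors = FALSE)
  v <- data.frame(snp = as.character(side$SNP), chr = as.character(side$CHR),
                  pos = side$POS, ea = side$EA, oa = side$OA,
                  eaf = side$EAF, stringsAsFactors = FALSE)
  dp <- if (!is.null(dprime_path))
    as.matrix(utils::read.table(dprime_path, sep = "\t")) else NULL
  ld_ref(v, R, n_ref = side$N_REF[1], dprime = dp)
}
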