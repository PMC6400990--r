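#' GWAS summary statistics container
#'
#' A `sumstats` object is a data frame of per-variant association records
#' with one row per biallelic variant and the canonical columns
#' `snp, chr, pos, ea, oa, eaf, beta, se, z, p, n, info, hwe_p`.
#' `ea` is the effect allele to which `beta`, `z` and `eaf` refer; `pos` is
#' 1-based.  Study-level metadata (study id, trait, total sample size,
#' genome build) are carried as attributes.
#'
#' Missing `z` is reconstructed as `beta/se`, missing `p` from the two-sided
#' normal tail of `z`, and missing `se` as `|beta/z|` when both are present.
#' The constructor enforces the row invariants: positive `se`, `eaf` in
#' [0,1], `|z - beta/se| < 1e-6` when all three are present, unique variant
#' ids, and alleles drawn from {A,C,G,T} (any length) or the indel tokens
#' I/D/R.
#'
#' @param x data frame with at least `snp, chr, pos, ea, oa`.
#' @param study_id,trait,genome_build character metadata.
#' @param n_total total study sample size; defaults to `max(x$n)`.
#' @return object of class `c("sumstats","data.frame")`.
#' @export
sumstats <- function(x, study_id = "study", trait = "trait",
                     n_total = NULL, genome_build = "GRCh37") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("snp", "chr", "pos", "ea", "oa")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("eaf", "beta", "se", "z", "p", "n", "info", "hwe_p"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_real_, nrow(x))
  x <- x[, c(needed, "eaf", "beta", "se", "z", "p", "n", "info", "hwe_p")]
  x$snp <- as.character(x$snp); x$chr <- as.character(x$chr)
  x$ea <- toupper(as.character(x$ea)); x$oa <- toupper(as.character(x$oa))
  x$pos <- as.integer(x$pos)

  if (anyDuplicated(x$snp))
    stop("duplicate variant_id within study: ",
         x$snp[duplicated(x$snp)][1])
  bad_allele <- !(valid_allele(x$ea) & valid_allele(x$oa))
  if (any(bad_allele))
    stop("invalid allele code at variant ", x$snp[which(bad_allele)[1]])

  # reconstruct redundant statistics
  fix <- is.na(x$se) & !is.na(x$beta) & !is.na(x$z) & x$z != 0
  x$se[fix] <- abs(x$beta[fix] / x$z[fix])
  fix <- is.na(x$z) & !is.na(x$beta) & !is.na(x$se)
  x$z[fix] <- x$beta[fix] / x$se[fix]
  fix <- is.na(x$p) & !is.na(x$z)
  x$p[fix] <- p_from_z(x$z[fix])$p

  with_se <- !is.na(x$se)
  if (any(x$se[with_se] <= 0))
    stop("non-positive SE at variant ",
         x$snp[with_se][which(x$se[with_se] <= 0)[1]])
  full <- !is.na(x$beta) & !is.na(x$se) & !is.na(x$z)
  if (any(abs(x$z[full] - x$beta[full] / x$se[full]) >= 1e-6))
    stop("inconsistent z/beta/se at variant ",
         x$snp[full][which(abs(x$z[full] - x$beta[full] / x$se[full]) >= 1e-6)[1]])
  ok_eaf <- is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)
  if (!all(ok_eaf))
    stop("eaf outside [0,1] at variant ", x$snp[which(!ok_eaf)[1]])

  if (is.null(n_total))
    n_total <- if (all(is.na(x$n))) NA_integer_ else max(x$n, na.rm = TRUE)
  structure(x, class = c("sumstats", "data.frame"),
            study_id = study_id, trait = trait,
            n_total = n_total, genome_build = genome_build)
}

valid_allele <- function(a) {
  !is.na(a) & nzchar(a) &
    (grepl("^[ACGT]+$", a) | a %in% c("I", "D", "R"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: study '%s', trait '%s' (%s)\n",
              attr(x, "study_id"), attr(x, "trait"), attr(x, "genome_build")))
  cat(sprintf("  %d variants, n_total = %s\n", nrow(x),
              format(attr(x, "n_total"))))
  rep <- attr(x, "parse_report")
  if (!is.null(rep) && rep$n_bad > 0)
    cat(sprintf("  %d input row(s) rejected at parse time\n", rep$n_bad))
  qc <- attr(x, "qc_report")
  if (!is.null(qc))
    cat(sprintf("  QC: %d removed (%s)\n", qc$n_removed,
                paste(names(qc$counts), qc$counts, sep = "=", collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# canonical TSV header used on disk
.sumstats_header <- c(SNP = "snp", CHR = "chr", POS = "pos", EA = "ea",
                      OA = "oa", EAF = "eaf", BETA = "beta", SE = "se",
                      Z = "z", P = "p", N = "n", INFO = "info",
                      HWE_P = "hwe_p")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads the canonical tab-separated dialect (header
#' `SNP CHR POS EA OA EAF BETA SE Z P N INFO [HWE_P]`, `NA` for missing,
#' transparently gunzipped for `.gz` paths).  A `dialect` mapping renames
#' foreign headers to canonical ones, e.g.
#' `c(SNP = "rsid", BETA = "effect")`.  Rows that cannot be parsed
#' (unreadable numerics, invalid alleles, multi-allelic records with
#' comma-separated alleles) are rejected, counted, and reported through the
#' `parse_report` attribute with their line numbers — never silently
#' dropped.
#'
#' @param path file path.
#' @param dialect named character vector, canonical name -> file column name.
#' @param ... metadata passed to [sumstats()] (`study_id`, `trait`, ...).
#' @return a [sumstats] object; `attr(, "parse_report")` lists rejected rows.
#' @export
read_sumstats <- function(path, dialect = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  # file() auto-detects gzip on read, so .gz needs no special handling
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = "NA", check.names = FALSE)
  canon <- .sumstats_header
  if (!is.null(dialect)) {
    for (k in names(dialect)) {
      if (!k %in% names(canon)) stop("unknown canonical column in dialect: ", k)
      idx <- match(dialect[[k]], names(raw))
      if (is.na(idx)) stop("dialect column not in file header: ", dialect[[k]])
      names(raw)[idx] <- k
    }
  }
  mandatory <- c("SNP", "CHR", "POS", "EA", "OA")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("format error: missing mandatory column(s) ",
         paste(miss, collapse = ", "))

  out <- data.frame(snp = raw$SNP, chr = raw$CHR,
                    pos = rep(NA_integer_, nrow(raw)),
                    ea = toupper(raw$EA), oa = toupper(raw$OA),
                    stringsAsFactors = FALSE)
  bad <- rep(FALSE, nrow(raw))
  reasons <- character(nrow(raw))
  num_field <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    fail <- !is.na(raw[[col]]) & is.na(v)
    bad[fail] <<- TRUE
    reasons[fail] <<- paste0(reasons[fail], col, " unparseable;")
    v
  }
  out$pos  <- as.integer(num_field("POS"))
  out$eaf  <- num_field("EAF"); out$beta <- num_field("BETA")
  out$se   <- num_field("SE");  out$z    <- num_field("Z")
  out$p    <- num_field("P");   out$n    <- num_field("N")
  out$info <- num_field("INFO"); out$hwe_p <- num_field("HWE_P")

  multi <- grepl(",", out$ea) | grepl(",", out$oa)
  if (any(multi)) {
    bad[multi] <- TRUE
    reasons[multi] <- paste0(reasons[multi], "multi-allelic;")
    warning(sum(multi), " multi-allelic record(s) rejected")
  }
  badallele <- !multi & !(valid_allele(out$ea) & valid_allele(out$oa))
  bad[badallele] <- TRUE
  reasons[badallele] <- paste0(reasons[badallele], "invalid allele;")
  # non-positive SE violates the row invariants: reject at parse, counted
  badse <- !is.na(out$se) & out$se <= 0
  bad[badse] <- TRUE
  reasons[badse] <- paste0(reasons[badse], "non-positive SE;")

  report <- list(n_bad = sum(bad),
                 lines = which(bad) + 1L,  # +1 for the header line
                 reasons = reasons[bad])
  if (report$n_bad > 0)
    message(report$n_bad, " row(s) rejected at parse (lines ",
            paste(report$lines, collapse = ","), ")")
  res <- sumstats(out[!bad, , drop = FALSE], ...)
  attr(res, "parse_report") <- report
  res
}

#' Write summary statistics in the canonical TSV dialect
#'
#' Inverse of [read_sumstats()]: `read_sumstats(write_sumstats(s, f))`
#' reproduces `s` field for field.  Missing values are written as `NA`;
#' paths ending in `.gz` are gzip-compressed.
#'
#' @param study a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(study, path) {
  stopifnot(inherits(study, "sumstats"))
  out <- as.data.frame(study)[, .sumstats_header]
  names(out) <- names(.sumstats_header)
  # full precision so round-trips are exact
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- format(out[[col]], digits = 17,
                                                     trim = TRUE,
                                                     scientific = NA)
  out[] <- lapply(out, function(v) ifelse(v == "NA" | is.na(v), "NA", v))
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Applies the standard per-variant exclusions: SE above `se_max` or
#' non-positive, absolute beta above `beta_abs_max`, Hardy-Weinberg
#' equilibrium p below `hwe_p_min`, or imputation INFO below `info_min`.
#' Rules are evaluated independently — a row failing several rules is
#' counted under each of them but removed once — and a rule is skipped
#' (and the skip counted) for rows missing the field it tests.  Filtering
#' is order-independent.
#'
#' @param study a [sumstats] object.
#' @param se_max,beta_abs_max,hwe_p_min,info_min thresholds
#'   (defaults 10, 5, 1e-6, 0.4; INFO thresholds differ between genotyping
#'   platforms, so `info_min` is per-study configuration).
#' @return the surviving [sumstats]; `attr(, "qc_report")` holds per-rule
#'   exclusion counts, per-rule missing-field skip counts and removed ids.
#' @export
qc_filter <- function(study, se_max = 10, beta_abs_max = 5,
                      hwe_p_min = 1e-6, info_min = 0.4) {
  stopifnot(inherits(study, "sumstats"))
  x <- as.data.frame(study)
  fail_se   <- !is.na(x$se)    & (x$se > se_max | x$se <= 0)
  fail_beta <- !is.na(x$beta)  & abs(x$beta) > beta_abs_max
  fail_hwe  <- !is.na(x$hwe_p) & x$hwe_p < hwe_p_min
  fail_info <- !is.na(x$info)  & x$info < info_min
  drop <- fail_se | fail_beta | fail_hwe | fail_info
  report <- list(
    counts = c(se = sum(fail_se), beta = sum(fail_beta),
               hwe = sum(fail_hwe), info = sum(fail_info)),
    skipped_missing = c(se = sum(is.na(x$se)), beta = sum(is.na(x$beta)),
                        hwe = sum(is.na(x$hwe_p)), info = sum(is.na(x$info))),
    n_removed = sum(drop),
    removed = x$snp[drop])
  res <- sumstats(x[!drop, , drop = FALSE],
                  study_id = attr(study, "study_id"),
                  trait = attr(study, "trait"),
                  n_total = attr(study, "n_total"),
                  genome_build = attr(study, "genome_build"))
  attr(res, "qc_report") <- report
  res
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 & oa == complement_allele(ea)
}

#' Harmonize a pair of summary-statistic rows to a common effect allele
#'
#' Aligns row `b` to the effect-allele orientation of row `a` for the same
#' variant.  Flipping (effect and other allele swapped in `b`) negates
#' `beta` and `z` and maps `eaf` to `1 - eaf`; strand flips (alleles
#' reported on the opposite strand) relabel alleles by their complements,
#' possibly combined with an orientation flip.  Palindromic variants (A/T
#' or C/G) whose minor-allele frequency exceeds `ambiguity_maf` in either
#' row cannot be aligned reliably and are tagged `"ambiguous-dropped"` and
#' left untouched.  Harmonizing an already-aligned pair is the identity,
#' so the operation is idempotent after a first application.
#'
#' @param a,b single-row data frames (or lists) with fields
#'   `snp, ea, oa, eaf, beta, z` (missing statistics tolerated).
#' @param ambiguity_maf palindromic-ambiguity MAF threshold, default 0.40
#'   (the common two-sample MR convention).
#' @return list with elements `a`, `b` (aligned) and `action`, one of
#'   `"identity"`, `"flipped"`, `"strand"`, `"strand-flipped"`,
#'   `"ambiguous-dropped"`.
#' @export
harmonize_pair <- function(a, b, ambiguity_maf = 0.40) {
  a <- as.list(a); b <- as.list(b)
  pal <- isTRUE(is_palindromic(a$ea, a$oa)) ||
         isTRUE(is_palindromic(b$ea, b$oa))
  if (pal) {
    maf <- function(f) if (is.null(f) || is.na(f)) NA_real_ else min(f, 1 - f)
    mafs <- c(maf(a$eaf), maf(b$eaf))
    if (any(!is.na(mafs) & mafs > ambiguity_maf))
      return(list(a = a, b = b, action = "ambiguous-dropped"))
  }
  flip_b <- function(b) {
    tmp <- b$ea; b$ea <- b$oa; b$oa <- tmp
    if (!is.null(b$beta)) b$beta <- -b$beta
    if (!is.null(b$z)) b$z <- -b$z
    if (!is.null(b$eaf) && !is.na(b$eaf)) b$eaf <- 1 - b$eaf
    b
  }
  strand_b <- function(b) {
    b$ea <- complement_allele(b$ea); b$oa <- complement_allele(b$oa); b
  }
  if (identical(b$ea, a$ea) && identical(b$oa, a$oa))
    return(list(a = a, b = b, action = "identity"))
  if (identical(b$ea, a$oa) && identical(b$oa, a$ea))
    return(list(a = a, b = flip_b(b), action = "flipped"))
  bs <- strand_b(b)
  if (identical(bs$ea, a$ea) && identical(bs$oa, a$oa))
    return(list(a = a, b = bs, action = "strand"))
  if (identical(bs$ea, a$oa) && identical(bs$oa, a$ea))
    return(list(a = a, b = flip_b(bs), action = "strand-flipped"))
  stop(sprintf("incompatible variant: alleles %s/%s vs %s/%s at %s",
               a$ea, a$oa, b$ea, b$oa, a$snp %||% "?"))
}

#' Harmonize two summary-statistic sets on their shared variants
#'
#' Joins two [sumstats] objects on variant id and aligns the second to the
#' effect alleles of the first with [harmonize_pair()].  Ambiguous
#' palindromic and incompatible variants are dropped (and tallied).
#'
#' @param x,y [sumstats] objects (x provides the reference orientation).
#' @param ambiguity_maf passed to [harmonize_pair()].
#' @return data frame with one row per retained shared variant: columns
#'   `snp, ea, oa`, x's statistics suffixed `.x`, aligned y statistics
#'   suffixed `.y`, and `action`; dropped counts in `attr(, "harmonize_report")`.
#' @export
harmonize_sumstats <- function(x, y, ambiguity_maf = 0.40) {
  shared <- intersect(x$snp, y$snp)
  xi <- as.data.frame(x)[match(shared, x$snp), ]
  yi <- as.data.frame(y)[match(shared, y$snp), ]
  rows <- vector("list", length(shared))
  actions <- character(length(shared))
  for (i in seq_along(shared)) {
    h <- tryCatch(harmonize_pair(xi[i, ], yi[i, ], ambiguity_maf),
                  error = function(e) NULL)
    if (is.null(h)) { actions[i] <- "incompatible"; next }
    actions[i] <- h$action
    if (h$action == "ambiguous-dropped") next
    b <- h$b
    rows[[i]] <- data.frame(
      snp = shared[i], ea = xi$ea[i], oa = xi$oa[i],
      eaf.x = xi$eaf[i], beta.x = xi$beta[i], se.x = xi$se[i],
      z.x = xi$z[i], n.x = xi$n[i],
      eaf.y = b$eaf, beta.y = b$beta, se.y = b$se, z.y = b$z, n.y = b$n,
      action = h$action, stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) out <- data.frame()
  attr(out, "harmonize_report") <- table(actions)
  out
}
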