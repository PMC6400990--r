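# small in-code fixtures shared across test files

# an mr_fit with given theta/se, via a unit instrument
new_mr_fit_for_test <- function(theta, se) wald_ratio(1, 0.01, theta, se)

with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

# a tiny valid summary-statistics table
toy_sumstats_df <- function() {
  data.frame(
    snp = c("rs1", "rs2", "rs3"),
    chr = c("1", "1", "2"),
    pos = c(1000L, 2000L, 500L),
    ea = c("A", "C", "T"),
    oa = c("G", "T", "C"),
    eaf = c(0.30, 0.10, 0.45),
    beta = c(0.20, -0.05, 0.01),
    se = c(0.04, 0.02, 0.03),
    n = c(5000, 5000, 4800),
    info = c(0.95, 0.80, NA),
    stringsAsFactors = FALSE)
}

toy_sumstats <- function() sumstats(toy_sumstats_df(), study_id = "toy")

write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv"),
                          header = c(SNP = "snp", CHR = "chr", POS = "pos",
                                     EA = "ea", OA = "oa", EAF = "eaf",
                                     BETA = "beta", SE = "se", P = "p",
                                     N = "n", Z = "z", INFO = "info")) {
  out <- df
  keep <- header[header %in% names(df)]
  out <- out[, keep, drop = FALSE]
  names(out) <- names(keep)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

# equicorrelated ld_ref over m variants
toy_ld <- function(m = 3, r = 0, eaf = rep(0.3, m), n_ref = 10000,
                   snps = paste0("rs", seq_len(m)), dprime = NULL) {
  R <- matrix(r, m, m); diag(R) <- 1
  ld_ref(data.frame(snp = snps, eaf = eaf, stringsAsFactors = FALSE),
         R, n_ref, dprime)
}

# instruments with an exact linear relation Gamma = theta * gamma
exact_instruments <- function(theta = 0.3, k = 10, se_y = 0.05) {
  g <- seq(0.05, 0.3, length.out = k)
  mr_instruments(g, rep(0.01, k), theta * g, rep(se_y, k))
}
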