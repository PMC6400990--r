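Package: sumstatmr
Title: Summary-Statistic GWAS Meta-Analysis and Two-Sample Mendelian
    Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A summary-statistics workflow for metabolite genome-wide
    association studies: reading, quality-filtering and harmonizing
    per-cohort summary statistics; sample-size-weighted Z-score and
    inverse-variance effect-size meta-analysis with heterogeneity
    diagnostics; distance-based clumping and approximate conditional/joint
    (COJO-style) selection of secondary signals against an external LD
    reference; effect-size-weighted genetic scores with tiered subsets and
    Bonferroni-controlled trait scans; sex-stratified effect comparison;
    and a robust two-sample Mendelian randomization engine (Wald ratio,
    IVW, MR-Egger, weighted median, penalized weighted median,
    multivariable MR).  Includes a synthetic-cohort generator with known
    ground truth (LD-blocked genotypes, log-normal metabolite with
    sex-dimorphic effects, liability-threshold outcomes, configurable
    pleiotropy) so every pipeline stage can be validated end-to-end
    without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
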