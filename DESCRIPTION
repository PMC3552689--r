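Package: dmstrat
Title: Age-Stratified Nonparametric Tests for Differentially Methylated Loci
Version: 0.1.0
Authors@R:
    person("dmstrat", "developers", email = "dmstrat@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated loci across K conditions in
    Illumina-array beta-value data while absorbing the age-methylation
    association nonparametrically. Samples are binned into age strata; within
    each stratum a K-sample location test (Kruskal-Wallis, one-way ANOVA,
    Mood's median, or Welch's heteroscedastic F) is applied per locus, and the
    per-stratum p-values are combined into one per-locus p-value by Fisher's
    method or a sample-size-weighted one-sided Z. Includes a genome-scale
    pipeline with QC filtering and cutoff counting, a Monte-Carlo harness for
    type-I-error and power studies under beta and truncated-normal data, TSV
    readers/writers, a synthetic fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
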