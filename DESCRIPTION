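Package: xpgreml
Title: Cross-Population Genetic Correlation from Genome-Wide SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the correlation of SNP effects on a complex trait between
    two ancestry groups. Provides a two-population genotype/phenotype simulator
    (Balding-Nichols allele-frequency divergence, latent-Gaussian LD blocks,
    correlated polygenic effects), sample and variant quality control, genomic
    relationship matrices under population-specific or pooled allele-frequency
    standardisation with GCTA-format IO, bivariate average-information REML for
    cross-population genetic correlation (r_g) and SNP heritability with full
    sampling covariances, per-SNP FST and LD-score stratification with
    MAF/LD-matched binning and a chi-squared test for differences in r_g between
    SNP strata, and an errors-in-variables SNP-effect correlation (r_b) from
    GWAS summary statistics at clumped sentinel SNPs with jackknife standard
    errors. PLINK BED/BIM/FAM and COJO-style .ma files are read and written
    natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
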