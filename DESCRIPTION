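Package: hetchd
Title: Multilocus Heterozygosity and Disease Risk in Nested Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools to test whether genome-wide multilocus heterozygosity is
    associated with incident disease risk and with continuous risk-factor
    levels in nested case-control studies. Provides a synthetic-cohort
    simulator (Balding-Nichols population structure, per-individual
    inbreeding, logistic discrete-time hazards, risk-set-sampled matched
    controls, biomarkers), genotype input/output (VCF and PLINK bed/bim/fam),
    genotyping quality control (sample call rate, sex consistency,
    control-only Hardy-Weinberg exact test, cross-platform SNP intersection),
    per-individual heterozygous-locus counts over autosomal, genic and
    nonsynonymous SNP strata, principal-component covariates for population
    stratification, and unconditional logistic and mixed-model association
    fits reported per standardized SNP units.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
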