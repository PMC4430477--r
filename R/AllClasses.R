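#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowData colData
#'   "colData<-"
#' @importFrom stats qlogis plogis rbinom runif rnorm rbeta rexp quantile sd
#'   var cor lm glm binomial coef vcov pnorm pchisq t.test complete.cases
#'   as.formula setNames
#' @importFrom utils read.delim read.table write.table head
NULL

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for a synthetic nested case-control cohort
#'
#' Holds every knob of the cohort generator: panel size and allele-frequency
#' spectrum, per-individual inbreeding distribution, population structure
#' (number of subpopulations and Fst divergence), the planted disease effect
#' per 2000 heterozygous loci, the discrete-time incidence model, the
#' matching design, and missingness. Identical configuration plus identical
#' seed yields bit-identical cohorts.
#'
#' @slot nIndividuals cohort size (individuals at risk at baseline).
#' @slot nSnps number of autosomal SNPs; X-chromosome SNPs are added on top
#'   as `round(xFraction * nSnps)`.
#' @slot mafLow,mafHigh bounds of the uniform ancestral allele-frequency
#'   spectrum, in (0, 0.5].
#' @slot fMean,fSd mean and spread of the per-individual inbreeding
#'   coefficient F (Beta distributed, truncated to \[0, 1)). Variance in F
#'   ("identity disequilibrium") is what makes multilocus heterozygosity an
#'   informative proxy for inbreeding.
#' @slot nSubpops,fst number of subpopulations and Balding-Nichols
#'   divergence; subpopulation frequencies have variance `fst * p * (1 - p)`
#'   around the ancestral frequency `p`.
#' @slot subpopFMean optional per-subpopulation mean inbreeding (length
#'   `nSubpops`); when set it overrides `fMean` per subpopulation and induces
#'   systematic heterozygosity differences between subpopulations.
#' @slot betaPer2000 planted log-odds of disease per 2000 additional
#'   heterozygous loci (0 = the null).
#' @slot baselinePrevalence per-period event probability at mean
#'   heterozygosity.
#' @slot nPeriods number of follow-up periods.
#' @slot subpopRiskLogOr log-odds shift in disease risk for subpopulations
#'   other than the first (population-stratification confounding when
#'   combined with `subpopFMean`).
#' @slot controlsPerCase matched controls sampled per case (risk-set
#'   sampling).
#' @slot missingRate per-genotype missingness probability (completely at
#'   random).
#' @slot xFraction X-chromosome SNPs as a fraction of `nSnps`.
#' @slot femaleFraction fraction of females in the cohort.
#' @slot genicFraction,nonsynFraction target fractions of autosomal SNPs
#'   inside flank-extended gene regions and flagged nonsynonymous.
#' @slot upstreamKb,downstreamKb flank sizes (kb) used when laying out gene
#'   regions.
#' @slot ageRange,ageBandYears baseline age range (uniform) and the band
#'   width used as a matching stratum.
#' @slot smokingPrevalence probability of being a smoker at baseline.
#' @slot seed integer seed controlling all randomness.
#'
#' @seealso [simConfig()] for the validated constructor.
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer", nSnps = "integer",
    mafLow = "numeric", mafHigh = "numeric",
    fMean = "numeric", fSd = "numeric",
    nSubpops = "integer", fst = "numeric", subpopFMean = "numeric",
    betaPer2000 = "numeric", baselinePrevalence = "numeric",
    nPeriods = "integer", subpopRiskLogOr = "numeric",
    controlsPerCase = "integer", missingRate = "numeric",
    xFraction = "numeric", femaleFraction = "numeric",
    genicFraction = "numeric", nonsynFraction = "numeric",
    upstreamKb = "numeric", downstreamKb = "numeric",
    ageRange = "numeric", ageBandYears = "numeric",
    smokingPrevalence = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@nIndividuals >= 2L, "nIndividuals must be >= 2")
  chk(object@nSnps >= 1L, "nSnps must be >= 1")
  chk(object@mafLow > 0 && object@mafLow <= object@mafHigh &&
        object@mafHigh <= 0.5,
      "need 0 < mafLow <= mafHigh <= 0.5")
  chk(object@fMean >= 0 && object@fMean < 1, "fMean must lie in [0, 1)")
  chk(object@fSd >= 0, "fSd must be >= 0")
  chk(object@fst >= 0 && object@fst < 1, "fst must lie in [0, 1)")
  chk(object@nSubpops >= 1L, "nSubpops must be >= 1")
  chk(length(object@subpopFMean) %in% c(0L, object@nSubpops),
      "subpopFMean must be empty or of length nSubpops")
  chk(all(object@subpopFMean >= 0 & object@subpopFMean < 1),
      "subpopFMean values must lie in [0, 1)")
  chk(object@baselinePrevalence > 0 && object@baselinePrevalence < 1,
      "baselinePrevalence must lie in (0, 1)")
  chk(object@nPeriods >= 1L, "nPeriods must be >= 1")
  chk(object@controlsPerCase >= 1L, "controlsPerCase must be >= 1")
  chk(object@missingRate >= 0 && object@missingRate < 1,
      "missingRate must lie in [0, 1)")
  chk(object@xFraction >= 0 && object@xFraction < 1,
      "xFraction must lie in [0, 1)")
  chk(object@femaleFraction >= 0 && object@femaleFraction <= 1,
      "femaleFraction must lie in [0, 1]")
  chk(object@genicFraction >= 0 && object@genicFraction <= 1,
      "genicFraction must lie in [0, 1]")
  chk(object@nonsynFraction >= 0 &&
        object@nonsynFraction <= object@genicFraction,
      "nonsynFraction must lie in [0, genicFraction]")
  chk(length(object@ageRange) == 2L && diff(object@ageRange) > 0,
      "ageRange must be an increasing pair")
  chk(object@ageBandYears > 0, "ageBandYears must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults reproduce the shape of a genotyped nested case-control study of
#' incident coronary disease: a ~693k autosomal SNP panel, per-individual
#' heterozygous-locus counts near 229k with SD on the order of 2,000, a
#' cohort of 2,500 followed for 14 periods yielding roughly 435 cases, and
#' 1:2 risk-set-sampled controls matched on 2-year age band and smoking.
#' Scaled-down panels for testing are obtained by lowering `nSnps` and
#' `nIndividuals` explicitly.
#'
#' @param nIndividuals,nSnps cohort size and autosomal panel size.
#' @param mafLow,mafHigh ancestral allele-frequency bounds in (0, 0.5].
#' @param fMean,fSd inbreeding-coefficient mean and SD.
#' @param nSubpops,fst,subpopFMean population structure; see
#'   [SimulationConfig-class].
#' @param betaPer2000 planted log-odds of disease per 2000 heterozygous loci.
#' @param baselinePrevalence per-period event probability at mean
#'   heterozygosity.
#' @param nPeriods follow-up periods.
#' @param subpopRiskLogOr log-odds risk shift for non-reference
#'   subpopulations.
#' @param controlsPerCase matched controls per case.
#' @param missingRate per-genotype missingness probability.
#' @param xFraction,femaleFraction X-SNP fraction and female fraction.
#' @param genicFraction,nonsynFraction target strata fractions.
#' @param upstreamKb,downstreamKb gene flank sizes in kb.
#' @param ageRange,ageBandYears baseline age range and matching band width.
#' @param smokingPrevalence smoking probability.
#' @param seed integer seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nIndividuals = 50, nSnps = 200, seed = 1)
#' cfg
#' @export
simConfig <- function(nIndividuals = 2500, nSnps = 692794,
                      mafLow = 0.001, mafHigh = 0.5,
                      fMean = 0.005, fSd = 0.009,
                      nSubpops = 1, fst = 0, subpopFMean = numeric(0),
                      betaPer2000 = 0, baselinePrevalence = 0.0133,
                      nPeriods = 14, subpopRiskLogOr = 0,
                      controlsPerCase = 2, missingRate = 0.005,
                      xFraction = 0.03, femaleFraction = 0.5,
                      genicFraction = 562289 / 692794,
                      nonsynFraction = 4760 / 692794,
                      upstreamKb = 70, downstreamKb = 20,
                      ageRange = c(45, 75), ageBandYears = 2,
                      smokingPrevalence = 0.25, seed = 1) {
  new("SimulationConfig",
      nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
      mafLow = as.numeric(mafLow), mafHigh = as.numeric(mafHigh),
      fMean = as.numeric(fMean), fSd = as.numeric(fSd),
      nSubpops = as.integer(nSubpops), fst = as.numeric(fst),
      subpopFMean = as.numeric(subpopFMean),
      betaPer2000 = as.numeric(betaPer2000),
      baselinePrevalence = as.numeric(baselinePrevalence),
      nPeriods = as.integer(nPeriods),
      subpopRiskLogOr = as.numeric(subpopRiskLogOr),
      controlsPerCase = as.integer(controlsPerCase),
      missingRate = as.numeric(missingRate),
      xFraction = as.numeric(xFraction),
      femaleFraction = as.numeric(femaleFraction),
      genicFraction = as.numeric(genicFraction),
      nonsynFraction = as.numeric(nonsynFraction),
      upstreamKb = as.numeric(upstreamKb),
      downstreamKb = as.numeric(downstreamKb),
      ageRange = as.numeric(ageRange),
      ageBandYears = as.numeric(ageBandYears),
      smokingPrevalence = as.numeric(smokingPrevalence),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohort: %d individuals, %d autosomal SNPs (+%.1f%% X)\n",
              object@nIndividuals, object@nSnps, 100 * object@xFraction))
  cat(sprintf("  inbreeding: F ~ Beta(mean=%.4g, sd=%.4g)\n",
              object@fMean, object@fSd))
  cat(sprintf("  structure: %d subpopulation(s), Fst=%.3g\n",
              object@nSubpops, object@fst))
  cat(sprintf("  disease: beta/2000 het = %.4g, baseline=%.4g x %d periods\n",
              object@betaPer2000, object@baselinePrevalence,
              object@nPeriods))
  cat(sprintf("  matching: 1 case : %d controls, %g-year age bands\n",
              object@controlsPerCase, object@ageBandYears))
  cat(sprintf("  seed: %d\n", object@seed))
})

## ---------------------------------------------------------------------------
## CohortTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated cohort
#'
#' Stores the latent quantities the generator drew so parameter-recovery
#' tests can compare estimates against them: per-individual inbreeding F,
#' subpopulation label and sex, the planted per-2000-loci effect, and the
#' ancestral and subpopulation-drifted allele frequencies.
#'
#' @slot f per-individual inbreeding coefficient in \[0, 1).
#' @slot subpop per-individual subpopulation label (1-based integer).
#' @slot sex per-individual sex, "F" or "M".
#' @slot betaPer2000 planted log-odds per 2000 heterozygous loci.
#' @slot ancestralFreq per-SNP ancestral allele frequency.
#' @slot subpopFreq SNPs x subpopulations matrix of drifted frequencies.
#' @export
setClass("CohortTruth",
  representation(
    f = "numeric", subpop = "integer", sex = "character",
    betaPer2000 = "numeric",
    ancestralFreq = "numeric", subpopFreq = "matrix"
  )
)

setValidity("CohortTruth", function(object) {
  n <- length(object@f)
  if (length(object@subpop) != n || length(object@sex) != n)
    return("f, subpop and sex must have equal length")
  if (any(object@f < 0 | object@f >= 1))
    return("f must lie in [0, 1)")
  if (any(object@subpop < 1L))
    return("subpop labels are 1-based positive integers")
  if (nrow(object@subpopFreq) != length(object@ancestralFreq))
    return("subpopFreq must have one row per SNP")
  if (any(object@subpopFreq < 0 | object@subpopFreq > 1))
    return("drifted frequencies must lie in [0, 1]")
  TRUE
})

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf(
    "CohortTruth: %d individuals, %d SNPs, %d subpopulation(s)\n",
    length(object@f), length(object@ancestralFreq),
    ncol(object@subpopFreq)))
  cat(sprintf("  mean F = %.4g, planted beta/2000 = %.4g\n",
              mean(object@f), object@betaPer2000))
})

## ---------------------------------------------------------------------------
## GenotypeData
## ---------------------------------------------------------------------------

#' Genotype matrix with SNP and sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `"genotype"`
#' assay: an integer matrix of non-reference allele counts (0, 1, 2, `NA`
#' for missing), SNPs as rows and individuals as columns. `rowData()`
#' carries the SNP annotation (chromosome, position, stratum flags,
#' platforms); `colData()` carries the sample table (age, smoking, sex,
#' case status, matched set, eigenvectors, biomarkers).
#'
#' Heterozygosity depends only on `code == 1`, so the polarity of the
#' reference allele is irrelevant to every downstream statistic.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is required")
  g <- SummarizedExperiment::assay(object, "genotype")
  if (!is.integer(g))
    return("genotype codes must be stored as integers")
  if (any(!is.na(g) & (g < 0L | g > 2L)))
    return("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(object)))
    return("SNP ids must be unique")
  if (anyDuplicated(colnames(object)))
    return("sample ids must be unique")
  TRUE
})

#' Construct a GenotypeData object
#'
#' @param genotypes integer matrix, SNPs x individuals, codes 0/1/2/`NA`
#'   counting non-reference alleles. Row and column names are used as SNP
#'   and sample ids; `snpInfo$id` / `sampleInfo$id` take precedence.
#' @param snpInfo `data.frame` (or `DataFrame`) of per-SNP metadata with at
#'   least `id`, `chrom`, `pos`; optional columns `isAutosomal`, `isGenic`,
#'   `isNonsynonymous`, `geneId`, `platforms`.
#' @param sampleInfo `data.frame` of per-individual metadata with at least
#'   `id`; further columns (age, smoking, caseStatus, ...) pass through.
#' @return A [GenotypeData-class] object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3,
#'             dimnames = list(paste0("snp", 1:3), c("s1", "s2")))
#' gd <- GenotypeData(g)
#' genotypes(gd)
#' @export
GenotypeData <- function(genotypes, snpInfo = NULL, sampleInfo = NULL) {
  storage.mode(genotypes) <- "integer"
  if (!is.null(snpInfo)) {
    snpInfo <- S4Vectors::DataFrame(snpInfo)
    if ("id" %in% colnames(snpInfo)) rownames(genotypes) <- snpInfo$id
  }
  if (!is.null(sampleInfo)) {
    sampleInfo <- S4Vectors::DataFrame(sampleInfo)
    if ("id" %in% colnames(sampleInfo)) colnames(genotypes) <- sampleInfo$id
  }
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("snp", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("ind", seq_len(ncol(genotypes)))
  if (is.null(snpInfo))
    snpInfo <- S4Vectors::DataFrame(id = rownames(genotypes))
  if (is.null(sampleInfo))
    sampleInfo <- S4Vectors::DataFrame(id = colnames(genotypes))
  rownames(snpInfo) <- rownames(genotypes)
  rownames(sampleInfo) <- colnames(genotypes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = genotypes),
    rowData = snpInfo, colData = sampleInfo)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData integer genotype matrix (SNPs x individuals).
#' @param x,object a `GenotypeData` object.
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "genotype")

#' @describeIn GenotypeData per-SNP annotation as a `DataFrame`.
#' @export
snpInfo <- function(x) SummarizedExperiment::rowData(x)

#' @describeIn GenotypeData per-sample table as a `DataFrame`.
#' @export
sampleInfo <- function(x) SummarizedExperiment::colData(x)

#' @describeIn GenotypeData replace the per-sample table.
#' @param value replacement `DataFrame`.
#' @export
`sampleInfo<-` <- function(x, value) {
  SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(value)
  x
}

setMethod("show", "GenotypeData", function(object) {
  g <- genotypes(object)
  cat(sprintf("GenotypeData: %d SNPs x %d individuals\n",
              nrow(object), ncol(object)))
  miss <- mean(is.na(g))
  cat(sprintf("  missing genotypes: %.3f%%\n", 100 * miss))
  sn <- snpInfo(object)
  if ("isAutosomal" %in% colnames(sn))
    cat(sprintf("  autosomal SNPs: %d\n", sum(sn$isAutosomal)))
  cs <- sampleInfo(object)$caseStatus
  if (!is.null(cs))
    cat(sprintf("  cases: %d, controls: %d (unsampled: %d)\n",
                sum(cs == "case", na.rm = TRUE),
                sum(cs == "control", na.rm = TRUE), sum(is.na(cs))))
})

## ---------------------------------------------------------------------------
## StratumDefinition
## ---------------------------------------------------------------------------

#' A named SNP stratum with its reporting unit
#'
#' Binds a set of SNP ids (e.g. all autosomal SNPs, SNPs inside
#' flank-extended genes, nonsynonymous SNPs) to the number of SNPs per
#' reporting unit used to standardize effect sizes (2000 for the dense
#' strata, 25 for nonsynonymous SNPs; both chosen to be about one standard
#' deviation of the respective heterozygous-locus count).
#'
#' @slot name stratum label.
#' @slot snpIds SNP identifiers belonging to the stratum.
#' @slot scaleUnit SNPs per reporting unit (> 0).
#' @export
setClass("StratumDefinition",
  representation(name = "character", snpIds = "character",
                 scaleUnit = "numeric"))

setValidity("StratumDefinition", function(object) {
  if (object@scaleUnit <= 0) return("scaleUnit must be > 0")
  if (anyDuplicated(object@snpIds)) return("snpIds must be unique")
  TRUE
})

#' @rdname StratumDefinition-class
#' @param name,snpIds,scaleUnit see slots.
#' @export
StratumDefinition <- function(name, snpIds, scaleUnit = 2000) {
  new("StratumDefinition", name = as.character(name),
      snpIds = as.character(snpIds), scaleUnit = as.numeric(scaleUnit))
}

setMethod("show", "StratumDefinition", function(object) {
  cat(sprintf("StratumDefinition '%s': %d SNPs, unit = %g SNPs\n",
              object@name, length(object@snpIds), object@scaleUnit))
})

## ---------------------------------------------------------------------------
## HetProfile
## ---------------------------------------------------------------------------

#' Per-individual multilocus heterozygosity over SNP strata
#'
#' For each individual and stratum: the number of heterozygous genotypes,
#' the number of non-missing genotypes, and their ratio. Missing genotypes
#' contribute to neither numerator nor denominator, so each individual has
#' their own denominator.
#'
#' @slot sampleIds individual identifiers.
#' @slot counts individuals x strata matrix of heterozygous-locus counts.
#' @slot nonmissing individuals x strata matrix of non-missing counts.
#' @slot units named numeric: SNPs per reporting unit for each stratum.
#' @export
setClass("HetProfile",
  representation(sampleIds = "character", counts = "matrix",
                 nonmissing = "matrix", units = "numeric"))

setValidity("HetProfile", function(object) {
  if (!identical(dim(object@counts), dim(object@nonmissing)))
    return("counts and nonmissing must have identical shape")
  if (nrow(object@counts) != length(object@sampleIds))
    return("one row per individual required")
  if (any(object@counts < 0 | object@counts > object@nonmissing))
    return("need 0 <= n_het <= n_nonmissing")
  TRUE
})

#' @describeIn HetProfile heterozygous-locus counts (individuals x strata).
#' @param x a `HetProfile`.
#' @export
hetCounts <- function(x) x@counts

#' @describeIn HetProfile proportion heterozygous among non-missing loci.
#' @export
hetProportions <- function(x) {
  p <- x@counts / x@nonmissing
  p[x@nonmissing == 0] <- NA_real_
  p
}

#' @describeIn HetProfile stratum names.
#' @export
strataNames <- function(x) colnames(x@counts)

setMethod("show", "HetProfile", function(object) {
  cat(sprintf("HetProfile: %d individuals x %d strata\n",
              nrow(object@counts), ncol(object@counts)))
  for (s in colnames(object@counts)) {
    cat(sprintf("  %-16s mean n_het = %.1f (SD %.1f), unit = %g\n", s,
                mean(object@counts[, s]), sd(object@counts[, s]),
                object@units[[s]]))
  }
})

## ---------------------------------------------------------------------------
## QcReport
## ---------------------------------------------------------------------------

#' Genotyping quality-control report
#'
#' Book-keeping for the fixed-order QC pipeline (sample call rate, sex
#' consistency, cross-platform SNP intersection, Hardy-Weinberg in
#' controls). Each excluded sample or SNP carries exactly one primary
#' reason: the first rule in the fixed order that it violates.
#'
#' @slot excludedSamples `data.frame` with columns `id`, `reason`
#'   (`low_call_rate` or `sex_mismatch`).
#' @slot excludedSnps `data.frame` with columns `id`, `reason`
#'   (`platform_mismatch` or `hwe_fail`).
#' @slot thresholds named list of the thresholds applied.
#' @slot nSamplesBefore,nSamplesAfter,nSnpsBefore,nSnpsAfter counts.
#' @slot log character vector of human-readable messages.
#' @export
setClass("QcReport",
  representation(excludedSamples = "data.frame", excludedSnps = "data.frame",
                 thresholds = "list",
                 nSamplesBefore = "integer", nSamplesAfter = "integer",
                 nSnpsBefore = "integer", nSnpsAfter = "integer",
                 log = "character"))

setValidity("QcReport", function(object) {
  if (!all(c("id", "reason") %in% colnames(object@excludedSamples)))
    return("excludedSamples needs columns id, reason")
  if (!all(c("id", "reason") %in% colnames(object@excludedSnps)))
    return("excludedSnps needs columns id, reason")
  if (anyDuplicated(object@excludedSamples$id))
    return("a sample may be excluded for one primary reason only")
  if (anyDuplicated(object@excludedSnps$id))
    return("a SNP may be excluded for one primary reason only")
  if (object@nSamplesAfter !=
        object@nSamplesBefore - nrow(object@excludedSamples))
    return("sample counts do not reconcile with exclusions")
  if (object@nSnpsAfter != object@nSnpsBefore - nrow(object@excludedSnps))
    return("SNP counts do not reconcile with exclusions")
  TRUE
})

#' @describeIn QcReport excluded samples with reasons.
#' @param x a `QcReport`.
#' @export
excludedSamples <- function(x) x@excludedSamples

#' @describeIn QcReport excluded SNPs with reasons.
#' @export
excludedSnps <- function(x) x@excludedSnps

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n")
  cat(sprintf("  samples: %d -> %d (%d excluded)\n", object@nSamplesBefore,
              object@nSamplesAfter, nrow(object@excludedSamples)))
  if (nrow(object@excludedSamples))
    print(table(object@excludedSamples$reason))
  cat(sprintf("  SNPs: %d -> %d (%d excluded)\n", object@nSnpsBefore,
              object@nSnpsAfter, nrow(object@excludedSnps)))
  if (nrow(object@excludedSnps))
    print(table(object@excludedSnps$reason))
  for (l in object@log) cat("  ", l, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EigenvectorSet
## ---------------------------------------------------------------------------

#' Principal-component covariates for population stratification
#'
#' Top-k eigenvectors of the individual-by-individual covariance of
#' centered, binomially scaled genotypes, with a fixed sign convention
#' (the entry of largest magnitude is positive) so results are
#' reproducible.
#'
#' @slot sampleIds individual identifiers.
#' @slot vectors individuals x k matrix of coordinates (columns EV1..EVk).
#' @slot values the corresponding eigenvalues.
#' @slot varianceExplained eigenvalues as fractions of the total positive
#'   spectrum.
#' @export
setClass("EigenvectorSet",
  representation(sampleIds = "character", vectors = "matrix",
                 values = "numeric", varianceExplained = "numeric"))

setValidity("EigenvectorSet", function(object) {
  if (nrow(object@vectors) != length(object@sampleIds))
    return("one row per individual required")
  if (ncol(object@vectors) != length(object@values))
    return("one eigenvalue per component required")
  TRUE
})

#' @describeIn EigenvectorSet coordinates matrix (columns EV1..EVk).
#' @param x an `EigenvectorSet`.
#' @export
eigenvectors <- function(x) x@vectors

#' @describeIn EigenvectorSet per-component variance explained.
#' @export
varianceExplained <- function(x) x@varianceExplained

setMethod("show", "EigenvectorSet", function(object) {
  cat(sprintf("EigenvectorSet: %d individuals x %d components\n",
              nrow(object@vectors), ncol(object@vectors)))
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * object@varianceExplained),
            collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## AssociationResult
## ---------------------------------------------------------------------------

#' Result of a disease-heterozygosity association fit
#'
#' Effect of multilocus heterozygosity on disease odds, expressed per
#' reporting unit of SNPs, with Wald standard error, odds ratio, 95%
#' confidence interval and two-sided p-value.
#'
#' @slot stratum stratum name.
#' @slot unit SNPs per reporting unit.
#' @slot exposure `"count"` or `"proportion"`.
#' @slot beta,se log-odds per unit and its standard error.
#' @slot or,ciLow,ciHigh odds ratio per unit with Wald 95% CI.
#' @slot p two-sided Wald p-value.
#' @slot nCases,nControls sample sizes entering the fit.
#' @slot covariates adjustment covariates used.
#' @slot converged did the iteratively reweighted fit converge.
#' @export
setClass("AssociationResult",
  representation(stratum = "character", unit = "numeric",
                 exposure = "character",
                 beta = "numeric", se = "numeric",
                 or = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 p = "numeric", nCases = "integer", nControls = "integer",
                 covariates = "character", converged = "logical"))

setValidity("AssociationResult", function(object) {
  if (is.finite(object@or) &&
      (object@or < object@ciLow || object@or > object@ciHigh))
    return("the confidence interval must contain the odds ratio")
  TRUE
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult [%s, per %g SNPs, exposure=%s]\n",
              object@stratum, object@unit, object@exposure))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              object@or, object@ciLow, object@ciHigh, object@p))
  cat(sprintf("  beta = %.4g (SE %.4g); %d cases / %d controls\n",
              object@beta, object@se, object@nCases, object@nControls))
  cat(sprintf("  adjusted for: %s\n",
              if (length(object@covariates))
                paste(object@covariates, collapse = ", ") else "(none)"))
  if (!object@converged) cat("  WARNING: fit did not converge\n")
})

#' @describeIn AssociationResult coerce to a one-row data.frame.
#' @param x an `AssociationResult`.
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.AssociationResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(stratum = x@stratum, unit = x@unit, exposure = x@exposure,
             beta = x@beta, se = x@se, or = x@or,
             ciLow = x@ciLow, ciHigh = x@ciHigh, p = x@p,
             nCases = x@nCases, nControls = x@nControls,
             converged = x@converged, stringsAsFactors = FALSE)
}
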