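## Genotyping quality control: sample call rate, sex consistency,
## cross-platform SNP intersection, Hardy-Weinberg in controls.
## The filter order is fixed (call rate -> sex -> platform -> HWE) and each
## excluded sample/SNP gets the first violated rule as its primary reason.

#' Filter samples by genotyping call rate
#'
#' Excludes individuals whose fraction of non-missing genotypes is strictly
#' below `minRate` (an individual exactly at the threshold is retained).
#'
#' @param geno a [GenotypeData-class] or integer genotype matrix.
#' @param minRate minimum call rate in (0, 1]; default 0.97.
#' @return `data.frame` of excluded samples (id, reason, callRate).
#' @export
filterSampleCallRate <- function(geno, minRate = 0.97) {
  stopifnot(minRate > 0, minRate <= 1)
  g <- if (is(geno, "GenotypeData")) genotypes(geno) else geno
  if (nrow(g) == 0 || ncol(g) == 0)
    stop("empty genotype matrix")
  ids <- colnames(g)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(g)))
  rate <- colMeans(!is.na(g))
  bad <- rate < minRate
  data.frame(id = ids[bad], reason = rep("low_call_rate", sum(bad)),
             callRate = unname(rate[bad]), stringsAsFactors = FALSE)
}

#' Check reported against genetically inferred sex
#'
#' Infers sex from the X-chromosome heterozygosity rate: at or below `lo`
#' the individual is inferred male (hemizygous X), at or above `hi` female,
#' in between indeterminate. Individuals whose inferred sex contradicts the
#' reported sex are flagged; indeterminate individuals are retained. With
#' fewer than `minXSnps` X-labeled SNPs the check is skipped with a
#' warning.
#'
#' @param geno a [GenotypeData-class] or genotype matrix.
#' @param xSnpIds ids of X-labeled SNPs (taken from `rowData$isAutosomal`
#'   when `geno` is a [GenotypeData-class] and `xSnpIds` is `NULL`).
#' @param reportedSex per-sample "F"/"M" (taken from `colData$sex` when
#'   available).
#' @param lo,hi X-heterozygosity thresholds (defaults 0.02 and 0.20).
#' @param minXSnps minimum X SNPs required to run the check (default 50).
#' @return `data.frame` of excluded samples (id, reason, xHetRate), with
#'   attribute `skipped = TRUE` when the check could not run.
#' @export
checkSexConsistency <- function(geno, xSnpIds = NULL, reportedSex = NULL,
                                lo = 0.02, hi = 0.20, minXSnps = 50) {
  if (is(geno, "GenotypeData")) {
    if (is.null(xSnpIds) && "isAutosomal" %in% colnames(snpInfo(geno)))
      xSnpIds <- rownames(geno)[!snpInfo(geno)$isAutosomal]
    if (is.null(reportedSex) && "sex" %in% colnames(sampleInfo(geno)))
      reportedSex <- sampleInfo(geno)$sex
    g <- genotypes(geno)
  } else {
    g <- geno
  }
  empty <- data.frame(id = character(), reason = character(),
                      xHetRate = numeric(), stringsAsFactors = FALSE)
  xSnpIds <- intersect(xSnpIds, rownames(g))
  if (length(xSnpIds) < minXSnps || is.null(reportedSex)) {
    warning("sex-consistency check skipped: fewer than ", minXSnps,
            " X-labeled SNPs (or no reported sex) available")
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  x <- g[xSnpIds, , drop = FALSE]
  rate <- colSums(x == 1L, na.rm = TRUE) / pmax(colSums(!is.na(x)), 1L)
  inferred <- ifelse(rate >= hi, "F", ifelse(rate <= lo, "M", NA))
  bad <- !is.na(inferred) & !is.na(reportedSex) & inferred != reportedSex
  out <- data.frame(id = colnames(g)[bad],
                    reason = rep("sex_mismatch", sum(bad)),
                    xHetRate = unname(rate[bad]), stringsAsFactors = FALSE)
  attr(out, "skipped") <- FALSE
  out
}

#' Restrict the panel to SNPs shared by all genotyping platforms
#'
#' @param snpIds full SNP id vector under analysis.
#' @param platformSets named list (>= 2 entries) of SNP-id vectors, one per
#'   platform.
#' @return `data.frame` of excluded SNPs (id, reason = platform_mismatch).
#' @examples
#' intersectPlatforms(c("a", "b", "c", "d"),
#'                    list(P1 = c("a", "b", "c"), P2 = c("b", "c", "d")))
#' @export
intersectPlatforms <- function(snpIds, platformSets) {
  stopifnot(is.list(platformSets), length(platformSets) >= 2)
  shared <- Reduce(intersect, platformSets)
  keep <- intersect(snpIds, shared)
  if (length(keep) == 0)
    stop("platform intersection is empty")
  bad <- setdiff(snpIds, keep)
  data.frame(id = bad, reason = rep("platform_mismatch", length(bad)),
             stringsAsFactors = FALSE)
}

#' Filter SNPs violating Hardy-Weinberg equilibrium in controls
#'
#' Genotype counts are tallied over control individuals only and tested
#' with [hweExactTest()]; SNPs with exact `p < alpha` are excluded for all
#' individuals, cases included. X-labeled SNPs are tested in female
#' controls only (males are hemizygous on X). SNPs monomorphic in controls
#' have p = 1 and are retained.
#'
#' @param geno a [GenotypeData-class] or genotype matrix.
#' @param controlIds ids of control individuals (default: samples with
#'   `caseStatus == "control"` in `colData`).
#' @param alpha exclusion threshold on the exact p-value (default 1e-4).
#' @param xSnpIds optional ids of X-labeled SNPs; `NULL` derives them from
#'   `rowData$isAutosomal` when available.
#' @param femaleIds ids of female individuals, used for X SNPs.
#' @return `data.frame` of excluded SNPs (id, reason = hwe_fail, p).
#' @export
filterHweInControls <- function(geno, controlIds = NULL, alpha = 1e-4,
                                xSnpIds = NULL, femaleIds = NULL) {
  if (is(geno, "GenotypeData")) {
    si <- sampleInfo(geno)
    if (is.null(controlIds) && "caseStatus" %in% colnames(si))
      controlIds <- rownames(si)[!is.na(si$caseStatus) &
                                   si$caseStatus == "control"]
    if (is.null(femaleIds) && "sex" %in% colnames(si))
      femaleIds <- rownames(si)[si$sex == "F"]
    if (is.null(xSnpIds) && "isAutosomal" %in% colnames(snpInfo(geno)))
      xSnpIds <- rownames(geno)[!snpInfo(geno)$isAutosomal]
    g <- genotypes(geno)
  } else {
    g <- geno
  }
  controlIds <- intersect(controlIds, colnames(g))
  if (length(controlIds) == 0)
    stop("no control individuals available for the HWE filter")
  isX <- rownames(g) %in% xSnpIds
  useCols <- function(rows, cols) {
    sub <- g[rows, cols, drop = FALSE]
    cbind(nAA = rowSums(sub == 2L, na.rm = TRUE),
          nAa = rowSums(sub == 1L, na.rm = TRUE),
          naa = rowSums(sub == 0L, na.rm = TRUE))
  }
  p <- rep(NA_real_, nrow(g))
  names(p) <- rownames(g)
  if (any(!isX)) {
    cnt <- useCols(which(!isX), controlIds)
    ok <- rowSums(cnt) >= 1
    p[!isX][ok] <- hweExactTest(cnt[ok, "nAA"], cnt[ok, "nAa"],
                                cnt[ok, "naa"])
  }
  if (any(isX)) {
    fem <- intersect(controlIds, femaleIds)
    if (length(fem) > 0) {
      cnt <- useCols(which(isX), fem)
      ok <- rowSums(cnt) >= 1
      p[isX][ok] <- hweExactTest(cnt[ok, "nAA"], cnt[ok, "nAa"],
                                 cnt[ok, "naa"])
    }
  }
  bad <- !is.na(p) & p < alpha
  data.frame(id = rownames(g)[bad], reason = rep("hwe_fail", sum(bad)),
             p = unname(p[bad]), stringsAsFactors = FALSE)
}

#' Run the full quality-control pipeline
#'
#' Applies, in fixed order: sample call-rate filter (strict `< minRate`),
#' sex-consistency check, cross-platform SNP intersection, and the
#' control-only Hardy-Weinberg filter (on the samples surviving the first
#' two steps). Each exclusion carries the first violated rule as its
#' primary reason; re-running on the filtered output is a no-op.
#'
#' @param geno a [GenotypeData-class].
#' @param minCallRate sample call-rate threshold (default 0.97).
#' @param hweAlpha Hardy-Weinberg exclusion threshold (default 1e-4).
#' @param sexCheck run the sex-consistency check (default `TRUE`).
#' @param platformSets optional named list of per-platform SNP-id sets;
#'   `NULL` skips the intersection step.
#' @param sexLo,sexHi X-heterozygosity thresholds for sex inference.
#' @return list with `geno` (the filtered [GenotypeData-class]) and
#'   `report` (a [QcReport-class]).
#' @export
runQc <- function(geno, minCallRate = 0.97, hweAlpha = 1e-4,
                  sexCheck = TRUE, platformSets = NULL,
                  sexLo = 0.02, sexHi = 0.20) {
  stopifnot(is(geno, "GenotypeData"))
  logLines <- character()
  nS0 <- ncol(geno)
  nV0 <- nrow(geno)

  exS <- filterSampleCallRate(geno, minCallRate)[, c("id", "reason")]
  logLines <- c(logLines, sprintf(
    "call-rate filter (< %.4g): %d sample(s) excluded", minCallRate,
    nrow(exS)))

  if (sexCheck) {
    sx <- withCallingHandlers(
      checkSexConsistency(geno, lo = sexLo, hi = sexHi),
      warning = function(w) {
        logLines <<- c(logLines, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    sx <- sx[!sx$id %in% exS$id, , drop = FALSE]
    exS <- rbind(exS, sx[, c("id", "reason")])
    logLines <- c(logLines, sprintf(
      "sex-consistency check: %d sample(s) excluded", nrow(sx)))
  }
  keepSamples <- setdiff(colnames(geno), exS$id)

  exV <- data.frame(id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(platformSets)) {
    pf <- intersectPlatforms(rownames(geno), platformSets)
    exV <- rbind(exV, pf)
    logLines <- c(logLines, sprintf(
      "platform intersection: %d SNP(s) excluded", nrow(pf)))
  }
  genoTmp <- geno[setdiff(rownames(geno), exV$id), keepSamples]
  hw <- filterHweInControls(genoTmp, alpha = hweAlpha)
  exV <- rbind(exV, hw[, c("id", "reason")])
  logLines <- c(logLines, sprintf(
    "HWE-in-controls filter (p < %.3g): %d SNP(s) excluded", hweAlpha,
    nrow(hw)))

  keepSnps <- setdiff(rownames(geno), exV$id)
  report <- new("QcReport",
    excludedSamples = exS, excludedSnps = exV,
    thresholds = list(minCallRate = minCallRate, hweAlpha = hweAlpha,
                      sexLo = sexLo, sexHi = sexHi),
    nSamplesBefore = nS0, nSamplesAfter = length(keepSamples),
    nSnpsBefore = nV0, nSnpsAfter = length(keepSnps),
    log = logLines)
  list(geno = geno[keepSnps, keepSamples], report = report)
}
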