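## Synthetic nested case-control cohort generator.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a uniform ancestral allele-frequency spectrum, Balding-Nichols
## subpopulation drift, per-individual inbreeding F drawn from a Beta
## distribution (variance in F = identity disequilibrium), genotypes that are
## autozygous with probability F and Hardy-Weinberg otherwise, a discrete-time
## logistic hazard linear in centred heterozygous-locus count, risk-set
## sampled matched controls, and biomarkers linear in heterozygosity.
## SNPs are independent given F and subpopulation (no linkage).

#' Draw ancestral and subpopulation allele frequencies
#'
#' Ancestral frequencies are uniform on `[mafLow, mafHigh]`. With more than
#' one subpopulation, each subpopulation's frequency is drawn from the
#' Balding-Nichols distribution `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`,
#' which has mean `p` and variance `Fst * p * (1-p)`. With `fst = 0` the
#' subpopulation frequencies equal the ancestral ones.
#'
#' @param config a [SimulationConfig-class].
#' @param nSnps number of SNPs to draw; defaults to the autosomal panel plus
#'   the X SNPs implied by `config`.
#' @return list with `ancestral` (numeric vector) and `subpop`
#'   (SNPs x subpopulations matrix).
#' @examples
#' fr <- simulateAlleleFrequencies(simConfig(nSnps = 100, seed = 1))
#' range(fr$ancestral)
#' @export
simulateAlleleFrequencies <- function(config, nSnps = totalSnps(config)) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  p <- runif(nSnps, config@mafLow, config@mafHigh)
  k <- config@nSubpops
  if (k == 1L || config@fst == 0) {
    sub <- matrix(rep(p, k), ncol = k)
  } else {
    fst <- config@fst
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    sub <- matrix(rbeta(nSnps * k, rep(a, k), rep(b, k)), ncol = k)
  }
  colnames(sub) <- paste0("pop", seq_len(k))
  list(ancestral = p, subpop = sub)
}

## total SNPs = autosomal panel + X SNPs
totalSnps <- function(config) {
  config@nSnps + as.integer(round(config@xFraction * config@nSnps))
}

#' Draw the latent per-individual ground truth
#'
#' Inbreeding coefficients F come from a Beta distribution re-parameterized
#' by mean and SD (degenerate at the mean when `fSd = 0`), truncated to
#' `[0, 1)`; subpopulation labels are uniform; sex is Bernoulli with the
#' configured female fraction. When `subpopFMean` is set, each
#' subpopulation uses its own mean F.
#'
#' @param config a [SimulationConfig-class].
#' @param freqs output of [simulateAlleleFrequencies()].
#' @return A [CohortTruth-class] object.
#' @export
simulateTruth <- function(config, freqs) {
  n <- config@nIndividuals
  subpop <- sample.int(config@nSubpops, n, replace = TRUE)
  fm <- if (length(config@subpopFMean)) config@subpopFMean[subpop]
        else rep(config@fMean, n)
  f <- rbetaMeanSd(n, fm, config@fSd)
  sex <- ifelse(runif(n) < config@femaleFraction, "F", "M")
  new("CohortTruth", f = f, subpop = as.integer(subpop), sex = sex,
      betaPer2000 = config@betaPer2000,
      ancestralFreq = freqs$ancestral, subpopFreq = freqs$subpop)
}

## Beta draws parameterized by (mean, sd); mean may be a vector.
## sd = 0, or a mean of 0, degenerates to the mean itself; sd too large for
## the mean is clipped to the maximal valid Beta sd.
rbetaMeanSd <- function(n, m, s) {
  m <- rep_len(m, n)
  out <- m
  if (s > 0) {
    live <- m > 0 & m < 1
    if (any(live)) {
      ml <- m[live]
      smax <- sqrt(ml * (1 - ml)) * 0.999
      sl <- pmin(s, smax)
      nu <- ml * (1 - ml) / sl^2 - 1
      out[live] <- rbeta(sum(live), ml * nu, (1 - ml) * nu)
    }
  }
  pmin(out, 1 - 1e-12)
}

#' Simulate genotypes under inbreeding and population structure
#'
#' For individual `i` at a SNP with subpopulation frequency `p`, the
#' genotype is autozygous with probability `F_i` (two alleles identical by
#' descent: homozygous alt with probability `p`, homozygous ref otherwise)
#' and Hardy-Weinberg (`Binomial(2, p)`) with probability `1 - F_i`. The
#' expected heterozygote fraction is therefore `(1 - F_i) * 2p(1-p)`.
#' Males are hemizygous on X-labeled SNPs (codes 0/2 only, no
#' heterozygotes). Genotypes are then masked missing independently at
#' `missingRate`.
#'
#' @param freqs output of [simulateAlleleFrequencies()].
#' @param truth a [CohortTruth-class].
#' @param config a [SimulationConfig-class].
#' @param xSnps logical vector marking X-labeled SNPs (default: none).
#' @return integer matrix of genotype codes, SNPs x individuals.
#' @export
simulateGenotypes <- function(freqs, truth, config,
                              xSnps = logical(length(freqs$ancestral))) {
  nSnp <- length(freqs$ancestral)
  n <- length(truth@f)
  stopifnot(nrow(freqs$subpop) == nSnp, length(xSnps) == nSnp)
  g <- matrix(NA_integer_, nrow = nSnp, ncol = n)
  anyX <- any(xSnps)
  for (i in seq_len(n)) {
    p <- freqs$subpop[, truth@subpop[i]]
    gi <- rbinom(nSnp, 2L, p)
    if (truth@f[i] > 0) {
      az <- runif(nSnp) < truth@f[i]
      if (any(az)) gi[az] <- 2L * rbinom(sum(az), 1L, p[az])
    }
    if (anyX && truth@sex[i] == "M")
      gi[xSnps] <- 2L * rbinom(sum(xSnps), 1L, p[xSnps])
    if (config@missingRate > 0)
      gi[runif(nSnp) < config@missingRate] <- NA_integer_
    g[, i] <- gi
  }
  rownames(g) <- paste0("snp", seq_len(nSnp))
  colnames(g) <- paste0("ind", seq_len(n))
  g
}

#' Simulate a SNP annotation and gene table
#'
#' Places autosomal SNPs at increasing positions on 22 synthetic
#' chromosomes (plus an X chromosome when `xFraction > 0`), lays down
#' alternating intergenic gaps and gene regions so that the flank-extended
#' regions (upstream/downstream flanks oriented by a random strand) cover
#' about `genicFraction` of positions, and flags a `nonsynFraction`
#' subset of gene-body SNPs as nonsynonymous. Nonsynonymous SNPs always lie
#' inside a gene body and carry its `geneId`.
#'
#' The genic flag is computed from the emitted gene table with
#' [defineGenicStratum()], so annotation and stratum construction cannot
#' disagree.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `snps` (a `data.frame`: id, chrom, pos, isAutosomal,
#'   isGenic, isNonsynonymous, geneId, platforms) and `genes` (a
#'   `data.frame`: geneId, chrom, start, end, strand).
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  nAuto <- config@nSnps
  nX <- totalSnps(config) - nAuto
  spacing <- 4000                       # ~one SNP per 4 kb, genome-like
  chrW <- c(8.0, 7.8, 6.4, 6.2, 5.8, 5.5, 5.1, 4.7, 4.5, 4.3,
            4.3, 4.3, 3.7, 3.4, 3.3, 2.9, 2.6, 2.5, 1.9, 2.0, 1.5, 1.6)
  perChr <- floor(nAuto * chrW / sum(chrW))
  rem <- nAuto - sum(perChr)
  if (rem > 0) perChr[seq_len(rem)] <- perChr[seq_len(rem)] + 1L
  chrom <- rep(as.character(seq_along(perChr)), perChr)
  pos <- unlist(lapply(perChr, function(k) {
    len <- max(k * spacing, k + 1)
    sort(sample.int(len, k))
  }), use.names = FALSE)
  if (nX > 0) {
    chrom <- c(chrom, rep("X", nX))
    pos <- c(pos, sort(sample.int(max(nX * spacing, nX + 1), nX)))
  }
  snps <- data.frame(
    id = paste0("snp", seq_along(chrom)), chrom = chrom, pos = pos,
    isAutosomal = chrom != "X", stringsAsFactors = FALSE)

  genes <- simulateGeneTable(config, perChr, spacing)
  if (nrow(genes) > 0) {
    genic <- defineGenicStratum(snps, genes,
                                upstreamKb = config@upstreamKb,
                                downstreamKb = config@downstreamKb)
    snps$isGenic <- snps$id %in% genic@snpIds
  } else {
    snps$isGenic <- FALSE
  }

  ## nonsynonymous SNPs: a subset of SNPs inside gene bodies
  snps$geneId <- NA_character_
  snps$isNonsynonymous <- FALSE
  if (nrow(genes) > 0) {
    snpGr <- GenomicRanges::GRanges(snps$chrom,
                                    IRanges::IRanges(snps$pos, snps$pos))
    bodyGr <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
    hit <- IRanges::findOverlaps(snpGr, bodyGr, select = "first")
    inBody <- !is.na(hit)
    snps$geneId[inBody] <- genes$geneId[hit[inBody]]
    nNs <- min(round(config@nonsynFraction * nAuto), sum(inBody))
    if (nNs > 0) {
      ns <- sample(which(inBody), nNs)
      snps$isNonsynonymous[ns] <- TRUE
    }
  }
  snps$platforms <- "A;B"
  list(snps = snps, genes = genes)
}

## Alternating gap / gene-region layout per chromosome. Gene regions are
## drawn as flank-extended extents; the gene body is recovered by removing
## the strand-oriented flanks, so extended coverage hits genicFraction by
## construction.
simulateGeneTable <- function(config, perChr, spacing) {
  g <- config@genicFraction
  if (g <= 0) {
    return(data.frame(geneId = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  up <- config@upstreamKb * 1000
  down <- config@downstreamKb * 1000
  extMin <- max(150000, up + down + 20000)
  extMax <- extMin + 250000
  extMean <- (extMin + extMax) / 2
  gapMean <- max(extMean * (1 - g) / g, 1)
  out <- vector("list", length(perChr))
  idBase <- 0L
  for (ci in seq_along(perChr)) {
    len <- max(perChr[ci] * spacing, perChr[ci] + 1)
    pos <- 1
    starts <- ends <- integer(0)
    repeat {
      pos <- pos + rexp(1, 1 / gapMean)
      ext <- runif(1, extMin, extMax)
      if (pos + ext > len) break
      starts <- c(starts, round(pos))
      ends <- c(ends, round(pos + ext))
      pos <- pos + ext
    }
    if (!length(starts)) next
    strand <- sample(c("+", "-"), length(starts), replace = TRUE)
    bodyStart <- ifelse(strand == "+", starts + up, starts + down)
    bodyEnd <- ifelse(strand == "+", ends - down, ends - up)
    out[[ci]] <- data.frame(
      geneId = paste0("gene", idBase + seq_along(starts)),
      chrom = as.character(ci), start = as.integer(bodyStart),
      end = as.integer(bodyEnd), strand = strand,
      stringsAsFactors = FALSE)
    idBase <- idBase + length(starts)
  }
  keep <- out[!vapply(out, is.null, logical(1))]
  if (!length(keep)) {
    return(data.frame(geneId = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

#' Assign disease outcomes and sample matched controls by risk sets
#'
#' Each individual receives a baseline age (uniform over the configured
#' range, banded for matching), smoking status, and an event time from a
#' discrete-time logistic hazard whose per-period log-odds are
#' `logit(baselinePrevalence) + betaPer2000 * (hetCount - mean) / 2000`
#' (plus `subpopRiskLogOr` for non-reference subpopulations). Individuals
#' with an event inside follow-up are cases. Processing cases in event-time
#' order, each case is matched to `controlsPerCase` controls drawn from the
#' individuals still event-free at the case's event time in the same age
#' band and smoking stratum. A sampled control that later becomes a case is
#' retained once, as a case. Matched sets with no eligible control are
#' dropped and counted.
#'
#' @param hetCount per-individual heterozygous-locus count over the
#'   all-autosomal stratum (same order as `truth`).
#' @param truth a [CohortTruth-class].
#' @param config a [SimulationConfig-class].
#' @return `data.frame` with one row per cohort member: id, age, ageBand,
#'   smoking, sex, subpop, eventTime (`NA` if event-free), caseStatus
#'   ("case"/"control"/`NA` for unsampled), matchedSetId. The attribute
#'   `droppedSets` counts matching-exhausted sets.
#' @export
assignOutcomesAndMatch <- function(hetCount, truth, config) {
  n <- length(hetCount)
  stopifnot(n == length(truth@f))
  age <- runif(n, config@ageRange[1], config@ageRange[2])
  ageBand <- floor((age - config@ageRange[1]) / config@ageBandYears)
  smoking <- as.integer(runif(n) < config@smokingPrevalence)

  eta <- qlogis(config@baselinePrevalence) +
    config@betaPer2000 * (hetCount - mean(hetCount)) / 2000 +
    config@subpopRiskLogOr * (truth@subpop != 1L)
  h <- plogis(eta)
  ## geometric event time: first period with a success
  u <- runif(n)
  tEvent <- ceiling(log1p(-u) / log1p(-h))
  tEvent[tEvent < 1] <- 1
  eventTime <- ifelse(tEvent <= config@nPeriods, tEvent, NA_real_)

  caseStatus <- rep(NA_character_, n)
  caseSet <- ctrlSet <- rep(NA_integer_, n)
  caseIdx <- which(!is.na(eventTime))
  caseIdx <- caseIdx[order(eventTime[caseIdx], caseIdx)]
  caseStatus[caseIdx] <- "case"
  usedControl <- logical(n)
  dropped <- 0L
  setId <- 0L
  tAll <- ifelse(is.na(eventTime), Inf, eventTime)
  for (ci in caseIdx) {
    t0 <- eventTime[ci]
    elig <- which(tAll > t0 & ageBand == ageBand[ci] &
                    smoking == smoking[ci] & !usedControl)
    if (length(elig) < 1L) {
      dropped <- dropped + 1L
      next
    }
    setId <- setId + 1L
    caseSet[ci] <- setId
    nCtrl <- min(config@controlsPerCase, length(elig))
    pick <- if (length(elig) == 1L) elig else sample(elig, nCtrl)
    usedControl[pick] <- TRUE
    ctrlSet[pick] <- setId
    ## future cases keep their case status (converters counted once)
    caseStatus[pick][is.na(caseStatus[pick])] <- "control"
  }
  ## a converter sampled as an earlier case's control is reported once, as
  ## a case in its own matched set (NA if its own matching was exhausted)
  matchedSetId <- ifelse(!is.na(caseStatus) & caseStatus == "case",
                         caseSet, ctrlSet)
  out <- data.frame(
    id = paste0("ind", seq_len(n)), age = age, ageBand = ageBand,
    smoking = smoking, sex = truth@sex, subpop = truth@subpop,
    eventTime = eventTime, caseStatus = caseStatus,
    matchedSetId = matchedSetId, stringsAsFactors = FALSE)
  attr(out, "droppedSets") <- dropped
  out
}

#' Default biomarker panel
#'
#' Thirteen cardiovascular risk-factor traits (lipids, inflammatory
#' markers, adhesion molecules, homocysteine, adiponectin, BMI) with
#' realistic intercepts and noise SDs, a zero heterozygosity effect
#' (`gammaPer2000 = 0`, the null), and partial measurement subsets for the
#' traits assayed only in an initial subset of the cohort.
#'
#' @return `data.frame` with columns trait, intercept, noiseSd,
#'   gammaPer2000, ageCoef, smokingCoef, subsetFraction.
#' @export
defaultBiomarkerPanel <- function() {
  data.frame(
    trait = c("hdl", "ldl", "triglycerides", "crp", "il6", "fibrinogen",
              "homocysteine", "eselectin", "icam", "vcam",
              "adiponectin_total", "adiponectin_hmw", "bmi"),
    intercept = c(55, 130, 140, 0.3, 2.5, 350, 10, 45, 260, 700,
                  8500, 4200, 26),
    noiseSd = c(14, 33, 80, 0.5, 2.0, 70, 3, 20, 90, 240, 3500, 2400, 4.5),
    gammaPer2000 = 0,
    ageCoef = c(0.1, 0.3, 0.5, 0.002, 0.02, 1.0, 0.05, 0.1, 0.5, 2.0,
                10, 5, 0.02),
    smokingCoef = c(-3, 4, 10, 0.1, 0.4, 20, 0.8, 5, 15, 20, -300, -150,
                    -0.5),
    subsetFraction = c(1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Simulate biomarker levels linear in heterozygosity
#'
#' Each trait is `intercept + gammaPer2000 * hetCount/2000 +
#' ageCoef * (age - 60) + smokingCoef * smoking + Gaussian(0, noiseSd)`.
#' Traits with `subsetFraction < 1` are measured only in a random subset of
#' the sampled case-control individuals (the rest are `NA`), mimicking
#' assays run on an initial subset.
#'
#' @param samples sample table from [assignOutcomesAndMatch()].
#' @param hetCount per-individual heterozygous-locus count (cohort order).
#' @param panel biomarker panel `data.frame`; see [defaultBiomarkerPanel()].
#' @return `samples` with one numeric column appended per trait.
#' @export
simulateBiomarkers <- function(samples, hetCount,
                               panel = defaultBiomarkerPanel()) {
  n <- nrow(samples)
  stopifnot(length(hetCount) == n)
  sampled <- !is.na(samples$caseStatus)
  for (j in seq_len(nrow(panel))) {
    val <- panel$intercept[j] +
      panel$gammaPer2000[j] * hetCount / 2000 +
      panel$ageCoef[j] * (samples$age - 60) +
      panel$smokingCoef[j] * samples$smoking
    if (panel$noiseSd[j] > 0) val <- val + rnorm(n, 0, panel$noiseSd[j])
    if (panel$subsetFraction[j] < 1) {
      idx <- which(sampled)
      keepN <- round(panel$subsetFraction[j] * length(idx))
      keep <- if (keepN > 0) sample(idx, keepN) else integer(0)
      mask <- rep(TRUE, n)
      mask[keep] <- FALSE
      val[mask] <- NA_real_
    } else {
      val[!sampled] <- NA_real_
    }
    samples[[panel$trait[j]]] <- val
  }
  samples
}

#' Simulate a complete cohort
#'
#' Runs the full generator: allele frequencies, ground truth, annotation,
#' genotypes, heterozygosity, outcomes with matched sampling, and
#' biomarkers, assembled into a [GenotypeData-class] whose `colData` is the
#' sample table and whose `rowData` is the SNP annotation.
#'
#' @param config a [SimulationConfig-class]; `config@seed` seeds all
#'   randomness, so identical configs give bit-identical cohorts.
#' @param biomarkerPanel trait panel passed to [simulateBiomarkers()]; set
#'   `NULL` to skip biomarkers.
#' @return list with `geno` ([GenotypeData-class]), `truth`
#'   ([CohortTruth-class]), `genes` (gene table `data.frame`) and
#'   `droppedSets` (matching-exhausted set count).
#' @examples
#' sim <- simulateCohort(simConfig(nIndividuals = 60, nSnps = 300,
#'                                 baselinePrevalence = 0.02, seed = 7))
#' sim$geno
#' @export
simulateCohort <- function(config, biomarkerPanel = defaultBiomarkerPanel()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  ann <- simulateAnnotation(config)
  freqs <- simulateAlleleFrequencies(config, nSnps = nrow(ann$snps))
  truth <- simulateTruth(config, freqs)
  g <- simulateGenotypes(freqs, truth, config,
                         xSnps = !ann$snps$isAutosomal)
  rownames(g) <- ann$snps$id
  auto <- ann$snps$isAutosomal
  hetCount <- as.numeric(colSums(g[auto, , drop = FALSE] == 1L,
                                 na.rm = TRUE))
  samples <- assignOutcomesAndMatch(hetCount, truth, config)
  dropped <- attr(samples, "droppedSets")
  if (!is.null(biomarkerPanel))
    samples <- simulateBiomarkers(samples, hetCount, biomarkerPanel)
  colnames(g) <- samples$id
  geno <- GenotypeData(g, snpInfo = ann$snps, sampleInfo = samples)
  list(geno = geno, truth = truth, genes = ann$genes,
       droppedSets = dropped)
}
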