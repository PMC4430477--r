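# Synthetic-cohort generator.

test_that("allele frequencies honour bounds and zero divergence", {
  set.seed(1)
  cfg <- simConfig(nSnps = 500, mafLow = 0.3, mafHigh = 0.3,
                   nSubpops = 3, fst = 0, xFraction = 0)
  fr <- simulateAlleleFrequencies(cfg)
  expect_true(all(fr$ancestral == 0.3))
  expect_equal(ncol(fr$subpop), 3)
  for (j in 1:3) expect_identical(fr$subpop[, j], fr$ancestral)

  expect_error(simConfig(mafLow = 0.4, mafHigh = 0.2), "mafLow")
  expect_error(simConfig(fst = 1.2), "fst")
})

test_that("Balding-Nichols drift has variance fst * p * (1 - p)", {
  set.seed(2)
  cfg <- simConfig(nSnps = 10000, mafLow = 0.3, mafHigh = 0.3,
                   nSubpops = 2, fst = 0.1, xFraction = 0)
  fr <- simulateAlleleFrequencies(cfg)
  v <- var(fr$subpop[, 1])
  expect_equal(mean(fr$subpop[, 1]), 0.3, tolerance = 0.02)
  expect_lt(abs(v - 0.1 * 0.3 * 0.7), 0.002)   # 0.021 within MC error
})

test_that("genotype model reproduces autozygosity and HW heterozygosity", {
  cfg <- simConfig(nIndividuals = 4, nSnps = 100000, missingRate = 0,
                   xFraction = 0, mafLow = 0.5, mafHigh = 0.5)
  fr <- list(ancestral = rep(0.5, 100000),
             subpop = matrix(0.5, 100000, 1))
  mkTruth <- function(f) new("CohortTruth", f = rep(f, 4),
                             subpop = rep(1L, 4), sex = rep("F", 4),
                             betaPer2000 = 0, ancestralFreq = fr$ancestral,
                             subpopFreq = fr$subpop)
  set.seed(3)
  gFull <- simulateGenotypes(fr, mkTruth(1 - 1e-12), cfg)
  expect_equal(sum(gFull == 1L), 0)            # full autozygosity: no hets

  set.seed(4)
  g0 <- simulateGenotypes(fr, mkTruth(0), cfg)
  hetFrac <- mean(g0 == 1L)
  se <- sqrt(0.5 * 0.5 / length(g0))
  expect_lt(abs(hetFrac - 0.5), 3 * se)        # 2p(1-p) at p = 0.5

  fr3 <- list(ancestral = rep(0.3, 100000), subpop = matrix(0.3, 100000, 1))
  set.seed(5)
  g2 <- simulateGenotypes(fr3, new("CohortTruth", f = rep(0.2, 4),
                                   subpop = rep(1L, 4), sex = rep("F", 4),
                                   betaPer2000 = 0,
                                   ancestralFreq = fr3$ancestral,
                                   subpopFreq = fr3$subpop), cfg)
  expected <- (1 - 0.2) * 2 * 0.3 * 0.7        # 0.336
  se2 <- sqrt(expected * (1 - expected) / length(g2))
  expect_lt(abs(mean(g2 == 1L) - expected), 3 * se2)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- quickConfig(seed = 11, nIndividuals = 80, nSnps = 400)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(genotypes(a$geno), genotypes(b$geno))
  expect_identical(as.data.frame(sampleInfo(a$geno)),
                   as.data.frame(sampleInfo(b$geno)))
  expect_identical(a$truth@f, b$truth@f)
})

test_that("annotation reproduces the strata proportions of a ~693k panel", {
  set.seed(12)
  cfg <- simConfig(nSnps = 692794, xFraction = 0)
  ann <- simulateAnnotation(cfg)
  nGenic <- sum(ann$snps$isGenic)
  expect_lt(abs(nGenic - 562289) / 562289, 0.01)
  nNs <- sum(ann$snps$isNonsynonymous)
  expect_lt(abs(nNs - 4760) / 4760, 0.05)
  # nonsynonymous SNPs lie inside gene bodies, hence are genic
  ns <- ann$snps[ann$snps$isNonsynonymous, ]
  expect_true(all(!is.na(ns$geneId)))
  expect_true(all(ns$isGenic))
  gidx <- match(ns$geneId, ann$genes$geneId)
  expect_true(all(ns$pos >= ann$genes$start[gidx] &
                    ns$pos <= ann$genes$end[gidx]))
  # positions increase within chromosomes
  byChr <- split(ann$snps$pos, ann$snps$chrom)
  expect_true(all(vapply(byChr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("zero genic fraction empties the genic stratum", {
  set.seed(13)
  ann <- simulateAnnotation(simConfig(nSnps = 5000, genicFraction = 0,
                                      nonsynFraction = 0, xFraction = 0))
  expect_false(any(ann$snps$isGenic))
  expect_false(any(ann$snps$isNonsynonymous))
})

test_that("matched sets respect the risk-set sampling design", {
  cfg <- quickConfig(seed = 21, nIndividuals = 500, nSnps = 1000)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  tab <- as.data.frame(sampleInfo(sim$geno))
  cases <- tab[!is.na(tab$caseStatus) & tab$caseStatus == "case", ]
  ctrls <- tab[!is.na(tab$caseStatus) & tab$caseStatus == "control", ]
  expect_gt(nrow(cases), 20)
  # each sampled individual appears exactly once (converters as cases)
  expect_false(anyDuplicated(c(cases$id, ctrls$id)) > 0)
  # per-set structure: exactly 1 case, at most controlsPerCase controls
  sets <- split(tab[!is.na(tab$matchedSetId), ],
                tab$matchedSetId[!is.na(tab$matchedSetId)])
  for (s in sets) {
    expect_lte(sum(s$caseStatus == "control"), 2)
  }
  nCasePerSet <- table(cases$matchedSetId)
  expect_true(all(nCasePerSet == 1))
  # controls share the case's age band and smoking stratum, and their
  # event time (if any) is strictly later
  for (s in sets) {
    cs <- s[s$caseStatus == "case", ]
    if (nrow(cs) != 1) next
    ct <- s[s$caseStatus == "control", ]
    expect_true(all(ct$ageBand == cs$ageBand))
    expect_true(all(ct$smoking == cs$smoking))
    expect_true(all(is.na(ct$eventTime) | ct$eventTime > cs$eventTime))
  }
})

test_that("without a planted effect, case and control heterozygosity agree", {
  sig <- 0L
  for (seed in 1:20) {
    cfg <- quickConfig(seed = seed, nIndividuals = 350, nSnps = 1200)
    sim <- simulateCohort(cfg, biomarkerPanel = NULL)
    tab <- as.data.frame(sampleInfo(sim$geno))
    hp <- hetProfile(sim$geno)
    x <- hetCounts(hp)[, "all_autosomal"]
    isCase <- !is.na(tab$caseStatus) & tab$caseStatus == "case"
    isCtrl <- !is.na(tab$caseStatus) & tab$caseStatus == "control"
    if (t.test(x[isCase], x[isCtrl])$p.value < 0.01) sig <- sig + 1L
  }
  expect_lte(sig, 2L)                      # alpha = 0.01 over 20 seeds
})

test_that("biomarkers are exactly linear in heterozygosity when noiseless", {
  cfg <- quickConfig(seed = 31, nIndividuals = 200, nSnps = 500)
  panel <- data.frame(trait = "t1", intercept = 5, noiseSd = 0,
                      gammaPer2000 = 1, ageCoef = 0.2, smokingCoef = -1,
                      subsetFraction = 1, stringsAsFactors = FALSE)
  sim <- simulateCohort(cfg, biomarkerPanel = panel)
  tab <- as.data.frame(sampleInfo(sim$geno))
  hp <- hetProfile(sim$geno)
  het <- hetCounts(hp)[match(tab$id, rownames(hetCounts(hp))),
                       "all_autosomal"]
  sampled <- !is.na(tab$caseStatus)
  resid <- tab$t1[sampled] - 0.2 * (tab$age[sampled] - 60) +
    1 * tab$smoking[sampled] - 5
  expect_equal(resid, unname(het[sampled]) / 2000, tolerance = 1e-10)

  # measurement subsets: exactly the configured count is non-missing
  panel$subsetFraction <- 0.5
  sim2 <- simulateCohort(cfg, biomarkerPanel = panel)
  tab2 <- as.data.frame(sampleInfo(sim2$geno))
  nSampled <- sum(!is.na(tab2$caseStatus))
  expect_equal(sum(!is.na(tab2$t1)), round(0.5 * nSampled))
})
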