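# Heterozygosity strata and standardized effects.

test_that("genic boundaries are strand-aware, inclusive and clamped", {
  snps <- data.frame(id = paste0("v", 1:6), chrom = "1",
                     pos = c(29999, 30000, 30001, 140000, 140001, 190000))
  plus <- data.frame(geneId = "g1", chrom = "1", start = 100000,
                     end = 120000, strand = "+")
  s <- defineGenicStratum(snps, plus)
  # [100000 - 70000, 120000 + 20000] = [30000, 140000]
  expect_setequal(s@snpIds, c("v2", "v3", "v4"))

  minus <- plus
  minus$strand <- "-"
  s2 <- defineGenicStratum(snps, minus)
  # [100000 - 20000, 120000 + 70000] = [80000, 190000] inclusive
  expect_true("v6" %in% s2@snpIds)
  expect_false("v1" %in% s2@snpIds)

  # clamping at position 1
  early <- data.frame(geneId = "g2", chrom = "1", start = 5000, end = 6000,
                      strand = "+")
  s3 <- defineGenicStratum(data.frame(id = "v0", chrom = "1", pos = 1),
                           early)
  expect_identical(s3@snpIds, "v0")

  bad <- data.frame(geneId = "gX", chrom = "1", start = 10, end = 5,
                    strand = "+")
  expect_error(defineGenicStratum(snps, bad), "gX")
})

test_that("genic membership equals the brute-force interval oracle", {
  set.seed(7)
  snps <- data.frame(id = paste0("v", 1:2000),
                     chrom = as.character(sample(1:3, 2000, replace = TRUE)),
                     pos = sample.int(5e6, 2000))
  genes <- data.frame(geneId = paste0("g", 1:50),
                      chrom = as.character(sample(1:3, 50, replace = TRUE)),
                      start = sample.int(45e5, 50),
                      strand = sample(c("+", "-"), 50, replace = TRUE))
  genes$end <- genes$start + sample.int(2e5, 50)
  s <- defineGenicStratum(snps, genes)
  expect_setequal(s@snpIds, snps$id[genicOracle(snps, genes)])
})

test_that("heterozygote counting matches hand tallies and skips missing", {
  g <- matrix(c(0L, 1L, 2L, 1L, NA,
                0L, 0L, 2L, 2L, 0L), ncol = 2,
              dimnames = list(paste0("v", 1:5), c("a", "b")))
  s <- StratumDefinition("all", rownames(g), 1)
  cc <- countHeterozygous(g, s)
  expect_equal(cc$nHet, c(2L, 0L))
  expect_equal(cc$nNonmissing, c(4L, 5L))
  expect_equal(cc$proportion, c(0.5, 0))
  expect_error(countHeterozygous(g, StratumDefinition("none", "zz", 1)),
               "empty")
})

test_that("heterozygosity is invariant to allele-polarity flips", {
  cfg <- quickConfig(seed = 8, nIndividuals = 60, nSnps = 400)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  hp1 <- hetProfile(sim$geno)
  g <- genotypes(sim$geno)
  set.seed(9)
  flip <- sample(nrow(g), 150)
  g[flip, ] <- 2L - g[flip, ]
  gd2 <- GenotypeData(g, snpInfo = as.data.frame(snpInfo(sim$geno)),
                      sampleInfo = as.data.frame(sampleInfo(sim$geno)))
  hp2 <- hetProfile(gd2)
  expect_identical(hetCounts(hp1), hetCounts(hp2))
})

test_that("summing het counts over individuals equals summing over SNPs", {
  cfg <- quickConfig(seed = 10, nIndividuals = 50, nSnps = 300,
                     missingRate = 0.05)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  g <- genotypes(sim$geno)
  auto <- snpInfo(sim$geno)$isAutosomal
  hp <- hetProfile(sim$geno)
  expect_equal(sum(hetCounts(hp)[, "all_autosomal"]),
               sum(rowSums(g[auto, ] == 1L, na.rm = TRUE)))
})

test_that("mean het proportion matches 2p(1-p) and the -mean(2p(1-p)) slope", {
  # known per-individual F with spread; proportion ~ (1 - F) * hbar
  set.seed(11)
  cfg <- simConfig(nIndividuals = 200, nSnps = 20000, missingRate = 0,
                   xFraction = 0, fMean = 0.05, fSd = 0.03,
                   mafLow = 0.05, mafHigh = 0.5)
  fr <- simulateAlleleFrequencies(cfg)
  truth <- simulateTruth(cfg, fr)
  g <- simulateGenotypes(fr, truth, cfg)
  prop <- colMeans(g == 1L)
  hbar <- mean(2 * fr$ancestral * (1 - fr$ancestral))
  fit <- lm(prop ~ truth@f)
  slope <- coef(fit)[2]
  se <- sqrt(vcov(fit)[2, 2])
  expect_lt(abs(slope - (-hbar)), 4 * se)
  expect_equal(mean(prop), (1 - mean(truth@f)) * hbar, tolerance = 0.01)
})

test_that("rescaling effects is exact and matches refitting", {
  r <- rescaleEffect(1e-4, 2e-5, 2000)
  expect_equal(r$or, exp(0.2))
  expect_equal(rescaleEffect(0, 1e-5, 2000)$or, 1)

  cfg <- quickConfig(seed = 12, nIndividuals = 400, nSnps = 800)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  tab <- as.data.frame(sampleInfo(sim$geno))
  hp <- hetProfile(sim$geno)
  fPerSnp <- fitChdModel(tab, hp, unit = 1, covariates = c("age", "smoking"))
  f2000 <- fitChdModel(tab, hp, unit = 2000,
                       covariates = c("age", "smoking"))
  r2 <- rescaleEffect(fPerSnp@beta, fPerSnp@se, 2000)
  expect_equal(f2000@beta, r2$betaPerUnit, tolerance = 1e-8)
  expect_equal(f2000@se, r2$sePerUnit, tolerance = 1e-6)
  expect_equal(f2000@or, r2$or, tolerance = 1e-6)
})
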