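# Association models and report tables.

test_that("the saturated 2x2 model reproduces the cross-product ratio", {
  # cases: 30 exposed / 20 unexposed; controls: 20 exposed / 30 unexposed
  status <- c(rep("case", 50), rep("control", 50))
  exposed <- c(rep(1L, 30), rep(0L, 20), rep(1L, 20), rep(0L, 30))
  ids <- paste0("s", seq_along(status))
  tab <- data.frame(id = ids, caseStatus = status,
                    stringsAsFactors = FALSE)
  hp <- manualHetProfile(exposed, nonmissing = rep(1L, 100), unit = 1,
                         ids = ids)
  r <- fitChdModel(tab, hp, unit = 1, covariates = character(0))
  expect_equal(r@or, (30 * 30) / (20 * 20), tolerance = 1e-6)
  expect_true(r@converged)
  expect_equal(r@nCases, 50L)
  # invariants: CI contains OR and matches exp(beta +/- 1.96 se)
  expect_true(r@ciLow <= r@or && r@or <= r@ciHigh)
  expect_equal(r@ciLow, exp(r@beta - 1.96 * r@se))
  expect_equal(r@p, 2 * pnorm(-abs(r@beta / r@se)))
})

test_that("all-case or all-control input is rejected", {
  ids <- paste0("s", 1:20)
  tab <- data.frame(id = ids, caseStatus = rep("case", 20))
  hp <- manualHetProfile(rep(c(0L, 1L), 10), ids = ids)
  expect_error(fitChdModel(tab, hp, unit = 1, covariates = character(0)),
               "cases and controls")
})

test_that("count and proportion exposures give identical z with no missing", {
  cfg <- quickConfig(seed = 21, nIndividuals = 400, nSnps = 1000,
                     missingRate = 0)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  tab <- as.data.frame(sampleInfo(sim$geno))
  hp <- hetProfile(sim$geno)
  rc <- fitChdModel(tab, hp, exposure = "count", unit = "sd",
                    covariates = c("age", "smoking"))
  rp <- fitChdModel(tab, hp, exposure = "proportion", unit = "sd",
                    covariates = c("age", "smoking"))
  expect_equal(rc@beta / rc@se, rp@beta / rp@se, tolerance = 1e-8)
  expect_equal(rc@p, rp@p, tolerance = 1e-8)
})

test_that("noiseless biomarker fits recover the planted slope exactly", {
  cfg <- quickConfig(seed = 22, nIndividuals = 300, nSnps = 600)
  panel <- data.frame(trait = "t1", intercept = 2, noiseSd = 0,
                      gammaPer2000 = 1, ageCoef = 0.3, smokingCoef = 2,
                      subsetFraction = 1, stringsAsFactors = FALSE)
  sim <- simulateCohort(cfg, biomarkerPanel = panel)
  tab <- as.data.frame(sampleInfo(sim$geno))
  hp <- hetProfile(sim$geno)
  # lm warns about the perfect fit; that is the point of the check
  b <- suppressWarnings(
    fitBiomarkerModel(tab, hp, "t1", unit = 2000,
                      covariates = c("age", "smoking", "caseStatus")))
  expect_equal(b$beta, 1, tolerance = 1e-6)
})

test_that("random-intercept and fixed-only fits agree without set variance", {
  set.seed(23)
  n <- 120
  ids <- paste0("s", 1:n)
  het <- rpois(n, 50)
  tab <- data.frame(id = ids, age = runif(n, 45, 75),
                    smoking = rbinom(n, 1, 0.3),
                    caseStatus = rep(c("case", "control"), n / 2),
                    matchedSetId = rep(1:(n / 3), each = 3),
                    stringsAsFactors = FALSE)
  hp <- manualHetProfile(het, nonmissing = rep(200L, n), unit = 25,
                         ids = ids)
  tab$trait <- 3 + 0.5 * het / 25 + 0.1 * tab$age + rnorm(n, 0, 0.5)
  bFix <- fitBiomarkerModel(tab, hp, "trait", unit = 25)
  bMix <- suppressWarnings(suppressMessages(
    fitBiomarkerModel(tab, hp, "trait", unit = 25, randomIntercept = TRUE)))
  expect_equal(bMix$beta, bFix$beta, tolerance = 1e-3)
  expect_identical(bMix$model, "random-intercept-by-set")
  expect_error(fitBiomarkerModel(within(tab, trait <- 1), hp, "trait"),
               "constant")
})

test_that("subgroup filtering is strict and preserves model fits", {
  tab <- data.frame(id = c("a", "b", "c"), age = c(60, 65, 70))
  expect_identical(subgroupFilter(tab, "age_lt_65")$id, "a")
  expect_identical(subgroupFilter(tab, function(d) rep(TRUE, nrow(d))), tab)
  expect_error(subgroupFilter(tab, function(d) rep(FALSE, nrow(d))),
               "empty")

  cfg <- quickConfig(seed = 24, nIndividuals = 500, nSnps = 800)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  full <- as.data.frame(sampleInfo(sim$geno))
  hp <- hetProfile(sim$geno)
  young <- subgroupFilter(full, "age_lt_65")
  r1 <- fitChdModel(young, hp, covariates = c("age", "smoking"))
  # materializing the subgroup first gives the identical fit
  pre <- full[full$age < 65, ]
  r2 <- fitChdModel(pre, hp, covariates = c("age", "smoking"))
  expect_equal(r1@beta, r2@beta)
  expect_equal(r1@se, r2@se)
})

test_that("report tables agree with direct recomputation", {
  cfg <- quickConfig(seed = 25, nIndividuals = 400, nSnps = 900)
  sim <- simulateCohort(cfg)
  tab <- as.data.frame(sampleInfo(sim$geno))
  hp <- hetProfile(sim$geno)
  r <- fitChdModel(tab, hp, covariates = c("age", "smoking"))
  bio <- rbind(fitBiomarkerModel(tab, hp, "hdl"),
               fitBiomarkerModel(tab, hp, "bmi"))
  rep <- buildReports(tab, hp, list(r), biomarkerResults = bio)
  d <- rep$disease
  expect_equal(nrow(d), 1)
  expect_identical(d$unit, 2000)
  isCase <- !is.na(tab$caseStatus) & tab$caseStatus == "case"
  x <- hetCounts(hp)[match(tab$id, rownames(hetCounts(hp))),
                     "all_autosomal"]
  expect_equal(d$caseMean, mean(x[isCase]))
  expect_equal(d$caseSd, sd(x[isCase]))
  expect_equal(d$or, r@or)
  expect_true(all(c("hdl", "bmi") %in% rownames(rep$biomarkers)))
  expect_true(any(grepl("^\\| Stratum", rep$markdown)))
})
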