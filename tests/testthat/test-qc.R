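# Quality control: HWE exact test, call rate, sex check, platforms.

test_that("HWE exact test matches hand-derived values", {
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)
  expect_equal(hweExactTest(0, 0, 25), 1)      # monomorphic
  expect_equal(hweExactTest(25, 0, 0), 1)
  expect_error(hweExactTest(-1, 0, 1), "non-negative")
  expect_error(hweExactTest(0, 0, 0), "at least one")
  # mid-p is strictly smaller than the standard p
  expect_lt(hweExactTest(10, 5, 10, midP = TRUE), hweExactTest(10, 5, 10))
})

test_that("HWE exact test agrees with the enumeration oracle", {
  set.seed(1)
  for (i in 1:200) {
    tot <- sample(1:50, 1)
    nAa <- sample(0:tot, 1)
    nAA <- sample(0:(tot - nAa), 1)
    naa <- tot - nAa - nAA
    ora <- hweOracle(nAA, nAa, naa)
    expect_equal(hweExactTest(nAA, nAa, naa), ora$p, tolerance = 1e-12)
    expect_equal(ora$total, 1, tolerance = 1e-9)   # normalization
  }
})

test_that("call-rate filter uses a strict < threshold", {
  g <- matrix(0L, nrow = 100, ncol = 3,
              dimnames = list(paste0("v", 1:100), c("a", "b", "c")))
  g[1:4, 1] <- NA                          # 96/100: below threshold
  g[1:3, 2] <- NA                          # 97/100: exactly at threshold
  ex <- filterSampleCallRate(g, minRate = 0.97)
  expect_identical(ex$id, "a")
  expect_identical(ex$reason, "low_call_rate")
  expect_error(filterSampleCallRate(g[0, , drop = FALSE]), "empty")
  # no missingness, no exclusions
  expect_equal(nrow(filterSampleCallRate(matrix(1L, 10, 2))), 0)
})

test_that("HWE filter in controls is conservative at its alpha", {
  set.seed(2)
  nCtrl <- 60
  nSnp <- 10000
  p <- runif(nSnp, 0.1, 0.5)
  g <- matrix(rbinom(nSnp * nCtrl, 2L, rep(p, nCtrl)), nrow = nSnp,
              dimnames = list(paste0("v", seq_len(nSnp)),
                              paste0("s", seq_len(nCtrl))))
  alpha <- 0.01
  ex <- filterHweInControls(g, controlIds = colnames(g), alpha = alpha)
  frac <- nrow(ex) / nSnp
  se <- sqrt(alpha * (1 - alpha) / nSnp)
  expect_lte(frac, alpha + 3 * se)         # exact test: type I <= alpha
  # a SNP with every control heterozygous is grossly off-equilibrium
  g2 <- rbind(g, allhet = rep(1L, nCtrl))
  ex2 <- filterHweInControls(g2, controlIds = colnames(g2), alpha = 1e-4)
  expect_true("allhet" %in% ex2$id)
  expect_error(filterHweInControls(g, controlIds = character(0)),
               "no control")
})

test_that("sex check compares X heterozygosity against reported sex", {
  set.seed(3)
  nX <- 80
  mkInd <- function(hetRate) {
    v <- rep(0L, nX)
    v[seq_len(round(hetRate * nX))] <- 1L
    v
  }
  g <- cbind(maleOk = mkInd(0), maleBad = mkInd(0.30), female = mkInd(0.28),
             ambiguous = mkInd(0.10))
  rownames(g) <- paste0("x", seq_len(nX))
  ex <- checkSexConsistency(g, xSnpIds = rownames(g),
                            reportedSex = c("M", "M", "F", "M"))
  expect_identical(ex$id, "maleBad")
  expect_identical(ex$reason, "sex_mismatch")
  # indeterminate rates and matching sexes are retained
  expect_false("ambiguous" %in% ex$id)
  expect_false("female" %in% ex$id)
  # all-autosomal panel: skipped with a warning, zero exclusions
  expect_warning(
    ex2 <- checkSexConsistency(g[1:10, ], xSnpIds = rownames(g)[1:10],
                               reportedSex = c("M", "M", "F", "M")),
    "skipped")
  expect_equal(nrow(ex2), 0)
  expect_true(attr(ex2, "skipped"))
})

test_that("platform intersection removes exactly the non-shared SNPs", {
  ids <- c("a", "b", "c", "d")
  ex <- intersectPlatforms(ids, list(P1 = c("a", "b", "c"),
                                     P2 = c("b", "c", "d")))
  expect_setequal(ex$id, c("a", "d"))
  expect_equal(nrow(intersectPlatforms(ids, list(P1 = ids, P2 = ids))), 0)
  expect_error(intersectPlatforms(ids, list(P1 = "a", P2 = "z")), "empty")
})

test_that("the QC pipeline is idempotent and reconciles its counts", {
  cfg <- quickConfig(seed = 5, nIndividuals = 120, nSnps = 600,
                     missingRate = 0.02)
  sim <- simulateCohort(cfg, biomarkerPanel = NULL)
  qc1 <- runQc(sim$geno)
  rep1 <- qc1$report
  expect_equal(rep1@nSamplesAfter,
               rep1@nSamplesBefore - nrow(excludedSamples(rep1)))
  expect_equal(rep1@nSnpsAfter, rep1@nSnpsBefore - nrow(excludedSnps(rep1)))
  qc2 <- runQc(qc1$geno)
  expect_equal(nrow(excludedSamples(qc2$report)), 0)
  expect_equal(nrow(excludedSnps(qc2$report)), 0)
  expect_identical(dim(qc2$geno), dim(qc1$geno))
})
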