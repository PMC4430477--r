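## Association models: unconditional logistic regression of disease on
## standardized multilocus heterozygosity, and linear / mixed models of
## biomarkers on heterozygosity adjusting for case-control status.

#' Fit the disease-heterozygosity logistic model
#'
#' Unconditional logistic regression of case status on the per-individual
#' heterozygous-locus count (or proportion) divided by the reporting unit,
#' with adjustment for the matching factors and any further covariates.
#' The effect is reported as an odds ratio per `unit` SNPs with a Wald 95%
#' confidence interval and two-sided p-value.
#'
#' @param samples per-individual table (`data.frame` or `DataFrame`) with
#'   `id`, `caseStatus` ("case"/"control"; other rows are dropped) and the
#'   adjustment covariates.
#' @param het a [HetProfile-class] covering the sampled individuals.
#' @param stratum stratum name present in `het` (default
#'   `"all_autosomal"`).
#' @param unit SNPs per reporting unit; `NULL` uses the stratum's stored
#'   unit, `"sd"` uses the observed SD of the exposure (the auto-unit
#'   rationale: one reporting unit = about one SD).
#' @param exposure `"count"` (heterozygous-locus count) or `"proportion"`.
#'   For proportions the unit is interpreted as a proportion increment of
#'   `unit / nNonmissing` equivalents only when `unit = "sd"`; otherwise
#'   the raw proportion divided by `unit` is used.
#' @param covariates covariate column names to adjust for; defaults to
#'   age, smoking and every `EV*` column present.
#' @return An [AssociationResult-class]. A separation or non-convergence
#'   is reported through the `converged` flag, never silently.
#' @export
fitChdModel <- function(samples, het, stratum = "all_autosomal",
                        unit = NULL, exposure = c("count", "proportion"),
                        covariates = NULL) {
  exposure <- match.arg(exposure)
  samples <- as.data.frame(samples)
  stopifnot("caseStatus" %in% colnames(samples), "id" %in% colnames(samples))
  stopifnot(is(het, "HetProfile"), stratum %in% strataNames(het))
  if (is.null(covariates))
    covariates <- intersect(c("age", "smoking",
                              grep("^EV[0-9]+$", colnames(samples),
                                   value = TRUE)),
                            colnames(samples))

  idx <- match(samples$id, het@sampleIds)
  x <- if (exposure == "count") het@counts[idx, stratum]
       else hetProportions(het)[idx, stratum]
  if (is.null(unit)) unit <- het@units[[stratum]]
  if (identical(unit, "sd")) unit <- sd(x, na.rm = TRUE)
  stopifnot(is.numeric(unit), unit > 0)

  df <- samples[, c("id", "caseStatus", covariates), drop = FALSE]
  df$.het <- x / unit
  df <- df[!is.na(df$caseStatus) & df$caseStatus %in% c("case", "control"), ]
  df <- df[complete.cases(df), ]
  df$.y <- as.integer(df$caseStatus == "case")
  nCases <- sum(df$.y == 1L)
  nControls <- sum(df$.y == 0L)
  if (nCases == 0 || nControls == 0)
    stop("both cases and controls are required")

  form <- as.formula(paste(".y ~ .het",
                           if (length(covariates))
                             paste("+", paste(covariates, collapse = " + "))
                           else ""))
  fit <- glm(form, family = binomial(), data = df)
  b <- coef(fit)[".het"]
  se <- sqrt(vcov(fit)[".het", ".het"])
  converged <- isTRUE(fit$converged) && is.finite(b) && is.finite(se) &&
    abs(b) < 1e3
  p <- 2 * pnorm(-abs(b / se))
  new("AssociationResult", stratum = stratum, unit = unname(unit),
      exposure = exposure,
      beta = unname(b), se = unname(se), or = unname(exp(b)),
      ciLow = unname(exp(b - 1.96 * se)),
      ciHigh = unname(exp(b + 1.96 * se)), p = unname(p),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      covariates = covariates, converged = converged)
}

#' Fit a biomarker-heterozygosity linear model
#'
#' Linear model of a continuous trait on the standardized heterozygous-
#' locus count, adjusting for age, smoking, eigenvectors and case-control
#' status, over both cases and controls. With `randomIntercept = TRUE` a
#' per-matched-set random intercept is added and the model is fit by
#' restricted maximum likelihood (`lme4::lmer`).
#'
#' @param samples per-individual table with `id`, the trait, `caseStatus`
#'   and the covariates; `matchedSetId` is required for the random
#'   intercept.
#' @param het a [HetProfile-class].
#' @param trait trait column name.
#' @param stratum stratum name in `het`.
#' @param unit SNPs per reporting unit (`NULL` = the stratum's unit).
#' @param covariates adjustment covariates; defaults to age, smoking,
#'   `EV*` columns and case status.
#' @param randomIntercept add a per-matched-set random intercept.
#' @return one-row `data.frame`: trait, stratum, unit, beta, se, p, n,
#'   model.
#' @export
fitBiomarkerModel <- function(samples, het, trait,
                              stratum = "all_autosomal", unit = NULL,
                              covariates = NULL, randomIntercept = FALSE) {
  samples <- as.data.frame(samples)
  stopifnot(trait %in% colnames(samples),
            is(het, "HetProfile"), stratum %in% strataNames(het))
  if (is.null(covariates))
    covariates <- intersect(c("age", "smoking",
                              grep("^EV[0-9]+$", colnames(samples),
                                   value = TRUE), "caseStatus"),
                            colnames(samples))
  idx <- match(samples$id, het@sampleIds)
  if (is.null(unit)) unit <- het@units[[stratum]]
  keepCols <- unique(c("id", trait, covariates,
                       if (randomIntercept) "matchedSetId"))
  df <- samples[, keepCols, drop = FALSE]
  df$.het <- het@counts[idx, stratum] / unit
  df <- df[complete.cases(df), ]
  if (nrow(df) < 10)
    stop("trait '", trait, "' has fewer than 10 complete observations")
  if (sd(df[[trait]]) == 0)
    stop("trait '", trait, "' is constant")
  rhs <- paste(c(".het", covariates), collapse = " + ")
  if (randomIntercept) {
    form <- as.formula(paste(trait, "~", rhs, "+ (1 | matchedSetId)"))
    fit <- lme4::lmer(form, data = df, REML = TRUE)
    cc <- lme4::fixef(fit)[".het"]
    se <- sqrt(as.matrix(vcov(fit))[".het", ".het"])
    model <- "random-intercept-by-set"
  } else {
    form <- as.formula(paste(trait, "~", rhs))
    fit <- lm(form, data = df)
    cc <- coef(fit)[".het"]
    se <- sqrt(vcov(fit)[".het", ".het"])
    model <- "fixed-only"
  }
  z <- cc / se
  data.frame(trait = trait, stratum = stratum, unit = unname(unit),
             beta = unname(cc), se = unname(se),
             p = unname(2 * pnorm(-abs(z))), n = nrow(df), model = model,
             stringsAsFactors = FALSE)
}

#' Restrict a sample table to a subgroup
#'
#' Keeps every individual passing the predicate regardless of matched-set
#' integrity: the analysis model is unconditional with matching factors as
#' covariates, so broken sets do not bias the fit.
#'
#' @param samples per-individual table.
#' @param predicate `"age_lt_65"` (baseline age strictly below 65) or a
#'   one-argument function returning a logical vector over rows.
#' @return the filtered table.
#' @examples
#' tab <- data.frame(id = 1:3, age = c(60, 65, 70))
#' subgroupFilter(tab, "age_lt_65")$age
#' @export
subgroupFilter <- function(samples, predicate = "age_lt_65") {
  samples <- as.data.frame(samples)
  keep <- if (is.function(predicate)) {
    predicate(samples)
  } else if (identical(predicate, "age_lt_65")) {
    stopifnot("age" %in% colnames(samples))
    samples$age < 65
  } else {
    stop("unknown predicate: ", predicate)
  }
  keep[is.na(keep)] <- FALSE
  out <- samples[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("subgroup is empty")
  out
}

#' Build report tables of heterozygosity by case status
#'
#' The disease table gives, per stratum, the case and control mean (+/- SD)
#' heterozygous-locus counts, a two-sided Welch two-sample t-test p-value
#' for the mean difference, and the adjusted odds ratio per reporting unit
#' from the supplied association results. The biomarker table lays out
#' beta +/- SE per trait and stratum.
#'
#' @param samples per-individual table with `id` and `caseStatus`.
#' @param het a [HetProfile-class].
#' @param assocResults list of [AssociationResult-class], one per stratum.
#' @param biomarkerResults optional `data.frame` of rows from
#'   [fitBiomarkerModel()].
#' @return list with `disease` (a `data.frame`), optional `biomarkers`
#'   (trait x stratum `data.frame` of "beta +/- se"), and `markdown`
#'   (character vector of a Markdown rendering).
#' @export
buildReports <- function(samples, het, assocResults,
                         biomarkerResults = NULL) {
  samples <- as.data.frame(samples)
  stopifnot(length(assocResults) >= 1)
  idx <- match(samples$id, het@sampleIds)
  isCase <- !is.na(samples$caseStatus) & samples$caseStatus == "case"
  isCtrl <- !is.na(samples$caseStatus) & samples$caseStatus == "control"
  rows <- lapply(assocResults, function(r) {
    stopifnot(is(r, "AssociationResult"))
    x <- het@counts[idx, r@stratum]
    tt <- t.test(x[isCase], x[isCtrl])   # Welch, unequal variances
    data.frame(
      stratum = r@stratum,
      caseMean = mean(x[isCase]), caseSd = sd(x[isCase]),
      controlMean = mean(x[isCtrl]), controlSd = sd(x[isCtrl]),
      pDiff = tt$p.value, unit = r@unit, or = r@or,
      ciLow = r@ciLow, ciHigh = r@ciHigh, orP = r@p,
      stringsAsFactors = FALSE)
  })
  disease <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  md <- c(paste("| Stratum | Cases mean ± SD | Controls mean ± SD |",
                "p (diff) | OR per unit (95% CI) |"),
          "|---|---|---|---|---|",
          sprintf("| %s | %.0f ± %.0f | %.0f ± %.0f | %.2g | %.2f (%.2f–%.2f) per %g |",
                  disease$stratum, disease$caseMean, disease$caseSd,
                  disease$controlMean, disease$controlSd, disease$pDiff,
                  disease$or, disease$ciLow, disease$ciHigh, disease$unit))

  out <- list(disease = disease, markdown = md)
  if (!is.null(biomarkerResults) && nrow(biomarkerResults) > 0) {
    traits <- unique(biomarkerResults$trait)
    strata <- unique(biomarkerResults$stratum)
    tab <- matrix("", length(traits), length(strata),
                  dimnames = list(traits, strata))
    for (i in seq_len(nrow(biomarkerResults))) {
      r <- biomarkerResults[i, ]
      tab[r$trait, r$stratum] <- sprintf("%.3g ± %.2g", r$beta, r$se)
    }
    out$biomarkers <- as.data.frame(tab, stringsAsFactors = FALSE)
    out$markdown <- c(out$markdown, "",
      paste0("| Trait | ", paste(strata, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(strata) + 1), collapse = "|"),
             "|"),
      vapply(traits, function(tr) {
        paste0("| ", tr, " | ", paste(tab[tr, ], collapse = " | "), " |")
      }, character(1)))
  }
  out
}
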