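## Population-stratification covariates: principal components of the
## genotype matrix and ancestry-outlier flagging.

#' Compute principal-component covariates from genotypes
#'
#' Genotypes are centered per SNP at twice the observed allele frequency
#' and scaled by the binomial SD `sqrt(2 p (1 - p))`; monomorphic SNPs are
#' dropped and missing genotypes are mean-imputed (zero after centering).
#' The top `k` eigenvectors of the individual-by-individual covariance are
#' returned with a fixed sign convention: within each component the entry
#' of largest magnitude is positive, so results are deterministic given the
#' input. Only autosomal SNPs are used when the annotation carries an
#' `isAutosomal` flag, and by default every `snpStep`-th SNP enters the
#' decomposition (the stratification signal is dense, and the subset keeps
#' the covariance computation light).
#'
#' @param geno a [GenotypeData-class] or integer genotype matrix.
#' @param k number of components (default 3).
#' @param snpStep use every `snpStep`-th SNP (default 10; set 1 for all).
#' @return An [EigenvectorSet-class].
#' @export
computeEigenvectors <- function(geno, k = 3, snpStep = 10) {
  if (is(geno, "GenotypeData")) {
    g <- genotypes(geno)
    info <- snpInfo(geno)
    if ("isAutosomal" %in% colnames(info))
      g <- g[info$isAutosomal, , drop = FALSE]
  } else {
    g <- geno
  }
  n <- ncol(g)
  if (n < k + 1) stop("need at least k + 1 individuals")
  g <- g[seq(1, nrow(g), by = snpStep), , drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  if (nrow(g) < k) stop("fewer polymorphic SNPs than components requested")
  x <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  covMat <- crossprod(x) / nrow(x)
  ev <- eigen(covMat, symmetric = TRUE)
  if (k > sum(ev$values > 1e-12))
    stop("k exceeds the rank of the genotype covariance")
  vec <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(vec[, j]))
    if (vec[top, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("EV", seq_len(k))
  rownames(vec) <- colnames(g)
  pos <- pmax(ev$values, 0)
  new("EigenvectorSet", sampleIds = colnames(g), vectors = vec,
      values = ev$values[seq_len(k)],
      varianceExplained = ev$values[seq_len(k)] / sum(pos))
}

#' Flag ancestry outliers on the top components
#'
#' Lists individuals lying more than `sdMultiple` standard deviations from
#' the mean on any component. Flagging is informational; exclusion is the
#' caller's decision.
#'
#' @param eig an [EigenvectorSet-class].
#' @param sdMultiple threshold in SDs (default 6; `Inf` flags nobody).
#' @return character vector of outlier sample ids.
#' @export
flagAncestryOutliers <- function(eig, sdMultiple = 6) {
  stopifnot(is(eig, "EigenvectorSet"))
  v <- eig@vectors
  out <- rep(FALSE, nrow(v))
  for (j in seq_len(ncol(v))) {
    s <- sd(v[, j])
    if (s > 0)
      out <- out | abs(v[, j] - mean(v[, j])) > sdMultiple * s
  }
  eig@sampleIds[out]
}

#' Merge eigenvector covariates into a sample table
#'
#' @param samples per-individual table with an `id` column (or a
#'   [GenotypeData-class], whose `colData` is updated).
#' @param eig an [EigenvectorSet-class].
#' @return the sample table (or [GenotypeData-class]) with EV columns
#'   appended; individuals absent from `eig` get `NA`.
#' @export
addEigenvectors <- function(samples, eig) {
  stopifnot(is(eig, "EigenvectorSet"))
  addTo <- function(tab) {
    idx <- match(tab$id, eig@sampleIds)
    for (j in seq_len(ncol(eig@vectors)))
      tab[[colnames(eig@vectors)[j]]] <- eig@vectors[idx, j]
    tab
  }
  if (is(samples, "GenotypeData")) {
    sampleInfo(samples) <- addTo(as.data.frame(sampleInfo(samples)))
    samples
  } else {
    addTo(samples)
  }
}
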