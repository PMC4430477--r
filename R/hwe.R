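## Exact test of Hardy-Weinberg equilibrium.
##
## Conditional on the observed allele counts, the heterozygote count n_Aa
## has probability proportional to
##   n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa,
## supported on heterozygote counts of the same parity as the minor-allele
## count. The two-sided exact p-value sums the probabilities of all
## attainable configurations no more probable than the observed one.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact p-value for genotype counts at a biallelic locus, using
#' the conditional distribution of the heterozygote count given the allele
#' counts. Configurations with probability less than or equal to the
#' observed one (up to a 1e-9 relative rounding guard) contribute to the
#' p-value, so `p` lies in (0, 1] and a monomorphic locus gives exactly 1.
#' An optional mid-p variant halves the observed configuration's
#' contribution.
#'
#' @param nAA,nAa,naa genotype counts (non-negative, total >= 1). Vectors
#'   are accepted and recycled to a common length.
#' @param midP use the mid-p correction (default off).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' hweExactTest(1, 0, 1)        # 1/3
#' hweExactTest(0, 0, 25)       # monomorphic: 1
#' @export
hweExactTest <- function(nAA, nAa, naa, midP = FALSE) {
  n <- max(length(nAA), length(nAa), length(naa))
  nAA <- rep_len(as.integer(nAA), n)
  nAa <- rep_len(as.integer(nAa), n)
  naa <- rep_len(as.integer(naa), n)
  if (any(nAA < 0 | nAa < 0 | naa < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative")
  if (any(nAA + nAa + naa < 1, na.rm = TRUE))
    stop("at least one genotype must be observed")
  vapply(seq_len(n), function(i) {
    if (is.na(nAA[i]) || is.na(nAa[i]) || is.na(naa[i])) return(NA_real_)
    hweExactOne(nAA[i], nAa[i], naa[i], midP)
  }, numeric(1))
}

hweExactOne <- function(nAA, nAa, naa, midP = FALSE) {
  nTot <- nAA + nAa + naa
  nA <- 2L * nAA + nAa                  # copies of allele A
  na <- 2L * naa + nAa
  nMinor <- min(nA, na)
  ## attainable heterozygote counts share the parity of the minor count
  k <- seq.int(nMinor %% 2L, nMinor, by = 2L)
  logw <- k * log(2) - lfactorial((nA - k) / 2) - lfactorial(k) -
    lfactorial((na - k) / 2)
  logw <- logw - max(logw)
  w <- exp(logw)
  pr <- w / sum(w)
  obs <- pr[match(nAa, k)]
  inTail <- pr <= obs * (1 + 1e-9)
  p <- sum(pr[inTail])
  if (midP) p <- p - obs / 2
  min(p, 1)
}
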