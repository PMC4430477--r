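# Independent oracles used across tests.

# Exact HWE p-value by direct enumeration with closed-form conditional
# probabilities P(nAa = k | allele counts) =
#   n! 2^k / (((nA-k)/2)! k! ((na-k)/2)!) / choose(2n, nA).
# No self-normalization: the probabilities must sum to 1 on their own.
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  nMinor <- min(nA, na)
  k <- seq(nMinor %% 2, nMinor, by = 2)
  logp <- lfactorial(n) + k * log(2) -
    lfactorial((nA - k) / 2) - lfactorial(k) - lfactorial((na - k) / 2) -
    (lfactorial(2 * n) - lfactorial(nA) - lfactorial(na))
  pr <- exp(logp)
  obs <- pr[match(nAa, k)]
  list(p = min(sum(pr[pr <= obs * (1 + 1e-9)]), 1), total = sum(pr))
}

# Brute-force genic membership: per-SNP scan over every gene interval.
genicOracle <- function(snps, genes, upKb = 70, downKb = 20) {
  up <- upKb * 1000
  down <- downKb * 1000
  vapply(seq_len(nrow(snps)), function(i) {
    ch <- snps$chrom[i]
    p <- snps$pos[i]
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != ch) next
      if (genes$strand[j] == "-") {
        lo <- max(genes$start[j] - down, 1)
        hi <- genes$end[j] + up
      } else {
        lo <- max(genes$start[j] - up, 1)
        hi <- genes$end[j] + down
      }
      if (p >= lo && p <= hi) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# Small cohort configuration for quick pipeline tests.
quickConfig <- function(seed, nIndividuals = 300, nSnps = 2000, ...) {
  simConfig(nIndividuals = nIndividuals, nSnps = nSnps,
            baselinePrevalence = 0.02, seed = seed, ...)
}

# Hand-built HetProfile over one stratum named all_autosomal.
manualHetProfile <- function(counts, nonmissing = NULL, unit = 1,
                             ids = paste0("s", seq_along(counts))) {
  m <- matrix(as.integer(counts), ncol = 1,
              dimnames = list(ids, "all_autosomal"))
  nm <- if (is.null(nonmissing)) matrix(max(counts) + 0L, length(counts), 1,
                                        dimnames = dimnames(m))
        else matrix(as.integer(nonmissing), ncol = 1, dimnames = dimnames(m))
  nm[] <- pmax(nm, m)
  new("HetProfile", sampleIds = ids, counts = m, nonmissing = nm,
      units = c(all_autosomal = unit))
}
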