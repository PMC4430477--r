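## Multilocus heterozygosity over SNP strata.

#' Define the genic SNP stratum from a gene table
#'
#' A SNP belongs to the genic stratum iff its position lies inside some
#' gene body extended by an upstream and a downstream flank oriented by the
#' gene's strand: a plus-strand gene `[start, end]` covers
#' `[start - up, end + down]`; a minus-strand gene covers
#' `[start - down, end + up]`. Extended intervals are clamped at position 1
#' and overlapping intervals are merged, so each SNP is counted once (set
#' semantics).
#'
#' @param snps per-SNP table (`data.frame` or `DataFrame`) with columns
#'   `id`, `chrom`, `pos`; if an `isAutosomal` column is present the
#'   stratum is restricted to autosomal SNPs.
#' @param genes gene table with columns `geneId`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` ("+" or "-").
#' @param upstreamKb,downstreamKb flank sizes in kb (defaults 70 and 20).
#' @param scaleUnit SNPs per reporting unit for the resulting stratum.
#' @return A [StratumDefinition-class] named `"genic"`.
#' @examples
#' snps <- data.frame(id = c("a", "b"), chrom = "1", pos = c(29999, 30001))
#' genes <- data.frame(geneId = "g1", chrom = "1", start = 100000,
#'                     end = 120000, strand = "+")
#' defineGenicStratum(snps, genes)@snpIds   # "b" only
#' @export
defineGenicStratum <- function(snps, genes, upstreamKb = 70,
                               downstreamKb = 20, scaleUnit = 2000) {
  snps <- as.data.frame(snps)
  genes <- as.data.frame(genes)
  stopifnot(all(c("id", "chrom", "pos") %in% colnames(snps)),
            all(c("chrom", "start", "end", "strand") %in% colnames(genes)))
  bad <- genes$start > genes$end
  if (any(bad)) {
    nm <- if ("geneId" %in% colnames(genes)) genes$geneId[bad][1]
          else which(bad)[1]
    stop("gene table has start > end for gene: ", nm)
  }
  if (nrow(genes) == 0)
    return(StratumDefinition("genic", character(0), scaleUnit))
  up <- upstreamKb * 1000
  down <- downstreamKb * 1000
  plus <- genes$strand != "-"
  extStart <- ifelse(plus, genes$start - up, genes$start - down)
  extEnd <- ifelse(plus, genes$end + down, genes$end + up)
  extStart <- pmax(extStart, 1)
  ext <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(extStart, extEnd)))
  snpGr <- GenomicRanges::GRanges(as.character(snps$chrom),
                                  IRanges::IRanges(snps$pos, snps$pos))
  hit <- IRanges::overlapsAny(snpGr, ext)
  if ("isAutosomal" %in% colnames(snps)) hit <- hit & snps$isAutosomal
  StratumDefinition("genic", snps$id[hit], scaleUnit)
}

#' Count heterozygous loci per individual over a stratum
#'
#' `n_het` is the number of genotypes with code 1 over the stratum's SNPs;
#' `n_nonmissing` the number of non-missing genotypes. Missing genotypes
#' contribute to neither, so proportions use each individual's own
#' denominator.
#'
#' @param geno a [GenotypeData-class] or integer genotype matrix
#'   (SNPs x individuals, with row names).
#' @param stratum a [StratumDefinition-class]; its SNP ids must be a
#'   non-empty subset of the genotype rows.
#' @return `data.frame` with columns id, stratum, nHet, nNonmissing,
#'   proportion.
#' @export
countHeterozygous <- function(geno, stratum) {
  g <- if (is(geno, "GenotypeData")) genotypes(geno) else geno
  stopifnot(is(stratum, "StratumDefinition"))
  ids <- intersect(stratum@snpIds, rownames(g))
  if (length(ids) == 0)
    stop("stratum '", stratum@name, "' is empty on this genotype matrix")
  sub <- g[ids, , drop = FALSE]
  nHet <- colSums(sub == 1L, na.rm = TRUE)
  nNon <- colSums(!is.na(sub))
  data.frame(id = colnames(g), stratum = stratum@name,
             nHet = as.integer(nHet), nNonmissing = as.integer(nNon),
             proportion = ifelse(nNon > 0, nHet / nNon, NA_real_),
             stringsAsFactors = FALSE)
}

#' Per-individual heterozygosity profile over the three standard strata
#'
#' Computes heterozygous-locus counts and proportions over all autosomal
#' SNPs, the genic stratum, and nonsynonymous SNPs. Strata come from the
#' `rowData` flags (`isAutosomal`, `isGenic`, `isNonsynonymous`) unless an
#' explicit genic [StratumDefinition-class] is supplied.
#'
#' @param geno a [GenotypeData-class] with annotated `rowData`.
#' @param genicStratum optional [StratumDefinition-class] overriding the
#'   `isGenic` flag (e.g. from [defineGenicStratum()] on a real gene
#'   table).
#' @param units named numeric of SNPs per reporting unit; defaults to 2000
#'   for the dense strata and 25 for nonsynonymous SNPs (about one SD of
#'   each count).
#' @return A [HetProfile-class].
#' @export
hetProfile <- function(geno, genicStratum = NULL,
                       units = c(all_autosomal = 2000, genic = 2000,
                                 nonsynonymous = 25)) {
  stopifnot(is(geno, "GenotypeData"))
  info <- snpInfo(geno)
  stopifnot("isAutosomal" %in% colnames(info))
  strata <- list(
    all_autosomal = StratumDefinition(
      "all_autosomal", rownames(geno)[info$isAutosomal],
      units[["all_autosomal"]]))
  if (!is.null(genicStratum)) {
    strata$genic <- StratumDefinition(
      "genic", intersect(genicStratum@snpIds, rownames(geno)),
      units[["genic"]])
  } else if ("isGenic" %in% colnames(info) && any(info$isGenic)) {
    strata$genic <- StratumDefinition(
      "genic", rownames(geno)[info$isGenic & info$isAutosomal],
      units[["genic"]])
  }
  if ("isNonsynonymous" %in% colnames(info) && any(info$isNonsynonymous)) {
    strata$nonsynonymous <- StratumDefinition(
      "nonsynonymous",
      rownames(geno)[info$isNonsynonymous & info$isAutosomal],
      units[["nonsynonymous"]])
  }
  counts <- nonmiss <- matrix(0L, ncol(geno), length(strata),
                              dimnames = list(colnames(geno),
                                              names(strata)))
  for (s in names(strata)) {
    cc <- countHeterozygous(geno, strata[[s]])
    counts[, s] <- cc$nHet
    nonmiss[, s] <- cc$nNonmissing
  }
  new("HetProfile", sampleIds = colnames(geno), counts = counts,
      nonmissing = nonmiss,
      units = vapply(strata, function(s) s@scaleUnit, numeric(1)))
}

#' Rescale a per-SNP log-odds effect to a reporting unit
#'
#' Multiplies a per-heterozygous-SNP log-odds and its standard error by the
#' unit (e.g. 2000 SNPs), and returns the implied odds ratio with a Wald
#' 95% confidence interval. The transformation is exact: fitting the model
#' with `hetCount / unit` as the regressor gives the same result.
#'
#' @param betaPerSnp log-odds per heterozygous SNP.
#' @param sePerSnp its standard error.
#' @param scaleUnit SNPs per reporting unit.
#' @return list with betaPerUnit, sePerUnit, or, ciLow, ciHigh.
#' @examples
#' rescaleEffect(1e-4, 2e-5, 2000)$or   # exp(0.2)
#' @export
rescaleEffect <- function(betaPerSnp, sePerSnp, scaleUnit) {
  stopifnot(is.finite(betaPerSnp), is.finite(sePerSnp), scaleUnit > 0)
  b <- betaPerSnp * scaleUnit
  s <- sePerSnp * scaleUnit
  list(betaPerUnit = b, sePerUnit = s, or = exp(b),
       ciLow = exp(b - 1.96 * s), ciHigh = exp(b + 1.96 * s))
}
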