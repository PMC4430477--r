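## Genotype and table input/output.
##
## Genotype codes count non-reference alleles (0/1/2, NA missing).
## VCF reading goes through VariantAnnotation; VCF writing emits a minimal
## VCFv4.2 with GT only. PLINK bed/bim/fam uses the standard SNP-major
## 2-bit packing (no installed R package reads .bed, so the codec lives
## here). Positions are 1-based inclusive throughout.

#' Read genotypes from VCF or PLINK files
#'
#' VCF genotypes are mapped to allele-count codes (0/0 -> 0, 0/1 or 1/0 ->
#' 1, 1/1 -> 2, ./. -> missing; phased separators accepted). Non-biallelic
#' records and half-calls are dropped (and counted in the `dropped`
#' attributes) unless `strict = TRUE`, in which case they raise an error
#' naming the record. Round-trips with [writeGenotypes()] preserve codes,
#' ids and order.
#'
#' @param path VCF file path, or the PLINK prefix (the three files
#'   `<prefix>.bed/.bim/.fam` are read).
#' @param format `"vcf"` or `"plink"`.
#' @param strict error on non-biallelic sites and half-calls instead of
#'   dropping them.
#' @return A [GenotypeData-class]; `rowData` carries chrom and pos, and for
#'   VCF input the attribute `dropped` holds the dropped-record count.
#' @export
readGenotypes <- function(path, format = c("vcf", "plink"),
                          strict = FALSE) {
  format <- match.arg(format)
  if (format == "vcf") readGenotypesVcf(path, strict)
  else readGenotypesPlink(path)
}

#' Write genotypes to VCF or PLINK files
#'
#' @param geno a [GenotypeData-class].
#' @param path output VCF path, or PLINK prefix.
#' @param format `"vcf"` or `"plink"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(geno, path, format = c("vcf", "plink")) {
  format <- match.arg(format)
  if (format == "vcf") writeGenotypesVcf(geno, path)
  else writeGenotypesPlink(geno, path)
  invisible(path)
}

snpCoords <- function(geno) {
  info <- as.data.frame(snpInfo(geno))
  chrom <- if ("chrom" %in% colnames(info)) as.character(info$chrom)
           else rep("1", nrow(geno))
  pos <- if ("pos" %in% colnames(info)) as.integer(info$pos)
         else seq_len(nrow(geno))
  list(chrom = chrom, pos = pos)
}

writeGenotypesVcf <- function(geno, path) {
  g <- genotypes(geno)
  co <- snpCoords(geno)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  body <- paste(co$chrom, co$pos, rownames(g), "A", "G", ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hetchd",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  writeLines(c(hdr, body), path)
}

readGenotypesVcf <- function(path, strict = FALSE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1L
  if (any(multi)) {
    if (strict)
      stop("non-biallelic VCF record under strict mode: ",
           rownames(vcf)[multi][1])
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm %in% c("0/0")] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% c("1/1")] <- 2L
  half <- grepl("\\.", norm) & norm != "./." & norm != "."
  if (any(half) && strict)
    stop("half-call genotype under strict mode at record ",
         rownames(gt)[which(half, arr.ind = TRUE)[1, 1]])
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- data.frame(id = rownames(gt),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     stringsAsFactors = FALSE)
  info$isAutosomal <- !info$chrom %in% c("X", "Y", "MT", "chrX", "chrY")
  out <- GenotypeData(code, snpInfo = info)
  attr(out, "dropped") <- sum(multi)
  attr(out, "halfCalls") <- sum(half)
  out
}

## PLINK .bed 2-bit codes (SNP-major): 00 = hom A1, 01 = missing,
## 10 = het, 11 = hom A2. A1 is written as the non-reference allele, so
## our code 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01.
writeGenotypesPlink <- function(geno, prefix) {
  g <- genotypes(geno)
  co <- snpCoords(geno)
  n <- ncol(g)
  nBytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * nBytes - n
  shift <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(nrow(g))) {
    v <- c(3L, 2L, 0L)[g[j, ] + 1L]
    v[is.na(v)] <- 1L
    if (pad > 0) v <- c(v, integer(pad))
    m <- matrix(v, nrow = 4)
    writeBin(as.raw(colSums(m * shift)), con)
  }
  si <- as.data.frame(sampleInfo(geno))
  sexCode <- if ("sex" %in% colnames(si))
    ifelse(si$sex == "M", 1L, ifelse(si$sex == "F", 2L, 0L)) else 0L
  fam <- data.frame(fid = colnames(g), iid = colnames(g), pat = 0L,
                    mat = 0L, sex = sexCode, pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = co$chrom, id = rownames(g), cm = 0L,
                    pos = co$pos, a1 = "G", a2 = "A")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

readGenotypesPlink <- function(prefix) {
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  colnames(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  nBytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  raw <- readBin(con, "raw", m * nBytes)
  ints <- as.integer(raw)
  ## unpack 4 two-bit fields per byte
  q <- cbind(ints %% 4L, (ints %/% 4L) %% 4L, (ints %/% 16L) %% 4L,
             ints %/% 64L)
  v <- as.vector(t(q))                  # per SNP: 4*nBytes entries
  v <- matrix(v, nrow = 4 * nBytes)[seq_len(n), , drop = FALSE]
  code <- matrix(NA_integer_, nrow = n, ncol = m)
  code[v == 3L] <- 0L
  code[v == 2L] <- 1L
  code[v == 0L] <- 2L
  g <- t(code)
  rownames(g) <- bim$id
  colnames(g) <- fam[[2]]
  info <- data.frame(id = bim$id, chrom = as.character(bim$chrom),
                     pos = bim$pos, stringsAsFactors = FALSE)
  info$isAutosomal <- !info$chrom %in% c("X", "Y", "23", "24", "25", "26")
  si <- data.frame(id = fam[[2]],
                   sex = c(NA, "M", "F")[fam[[5]] + 1L],
                   stringsAsFactors = FALSE)
  GenotypeData(g, snpInfo = info, sampleInfo = si)
}

#' Read a per-individual covariate/outcome table
#'
#' Tab-separated with a header. Missing values are empty fields or "NA".
#' Columns beyond the recognized schema are preserved untouched (typically
#' biomarkers). Individuals with missing mandatory covariates are kept in
#' the table; adjusted models drop them at fit time.
#'
#' @param path TSV file path.
#' @param required column names that must be present (default `"id"`).
#' @return `data.frame`.
#' @export
readCovariates <- function(path, required = "id") {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required, colnames(tab))
  if (length(missing))
    stop("covariate table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' Write a per-individual covariate/outcome table
#'
#' @param samples `data.frame` (or `DataFrame`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCovariates <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-SNP annotation table
#'
#' @param path TSV file path; must contain `id`, `chrom`, `pos`.
#' @return `data.frame` with positions coerced to integer.
#' @export
readAnnotation <- function(path) {
  tab <- readCovariates(path, required = c("id", "chrom", "pos"))
  tab$pos <- as.integer(tab$pos)
  tab$chrom <- as.character(tab$chrom)
  if (any(tab$pos <= 0, na.rm = TRUE))
    stop("annotation positions must be positive (1-based)")
  tab
}

#' @rdname readAnnotation
#' @param snps annotation `data.frame`.
#' @param path output TSV path.
#' @export
writeAnnotation <- function(snps, path) writeCovariates(snps, path)
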