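#' Read per-cell allele depths from a multi-sample VCF
#'
#' Consumes a VCF 4.x whose sample columns are cell barcodes and whose
#' FORMAT includes \code{AD} (ref,alt read depths).  GT/GQ fields are
#' ignored; genotypes are re-derived internally by
#' \code{\link{callGenotypes}}.  Multi-allelic records are split into one
#' column per ALT allele, each taking that ALT's AD entry as alt depth and
#' the shared REF AD entry as ref depth; a missing AD (".") yields ref and
#' alt depth 0 for that cell.
#'
#' @param vcfPath path to a VCF (plain or bgzipped).
#' @param genes optional named character vector mapping \code{"chrom:pos"}
#'   (or plain chrom) to gene symbols; unknown loci get gene "NA".
#' @return A \linkS4class{CellAlleleCounts}.
#' @export
readVcfAlleleDepths <- function(vcfPath, genes = NULL) {
  if (!file.exists(vcfPath))
    stopf("cannot read VCF: file not found: %s", vcfPath)
  vcf <- VariantAnnotation::readVcf(vcfPath)
  hdr <- VariantAnnotation::header(vcf)
  if (!"AD" %in% rownames(VariantAnnotation::geno(hdr)))
    stopf("unsupported input: VCF lacks a FORMAT/AD field")
  if (ncol(vcf) == 0L)
    stopf("VCF contains zero sample columns")
  ad <- VariantAnnotation::geno(vcf)$AD
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  barcodes <- colnames(vcf)
  nS <- length(barcodes)

  ids <- character(0); gene <- character(0)
  refM <- NULL; altM <- NULL
  refRows <- list(); altRows <- list()
  for (i in seq_len(nrow(vcf))) {
    altAll <- as.character(alts[[i]])
    for (j in seq_along(altAll)) {
      rd <- integer(nS); adx <- integer(nS)
      for (s in seq_len(nS)) {
        v <- if (is.matrix(ad)) ad[i, s][[1]] else ad[[i, s]]
        if (is.null(v) || all(is.na(v)) || length(v) < j + 1L) {
          rd[s] <- 0L; adx[s] <- 0L
        } else {
          rd[s] <- ifelse(is.na(v[1L]), 0L, v[1L])
          adx[s] <- ifelse(is.na(v[j + 1L]), 0L, v[j + 1L])
        }
      }
      id <- sprintf("%s:%d:%s/%s", chrom[i], pos[i], refs[i], altAll[j])
      ids <- c(ids, id)
      g <- NA_character_
      if (!is.null(genes)) {
        key <- sprintf("%s:%d", chrom[i], pos[i])
        g <- if (key %in% names(genes)) genes[[key]]
             else if (chrom[i] %in% names(genes)) genes[[chrom[i]]]
             else NA_character_
      }
      gene <- c(gene, g)
      refRows[[length(refRows) + 1L]] <- rd
      altRows[[length(altRows) + 1L]] <- adx
    }
  }
  if (anyDuplicated(ids))
    stopf("duplicate variant after multi-allelic split: %s",
          ids[duplicated(ids)][1L])
  refM <- do.call(rbind, refRows)
  altM <- do.call(rbind, altRows)
  variants <- variantTable(ids, ifelse(is.na(gene), "NA", gene))
  CellAlleleCounts(refM, altM, variants, barcodes = barcodes)
}
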