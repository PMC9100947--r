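#' Parse variant identifiers of the form "chrom:pos:ref/alt"
#'
#' Variant identifiers follow the compact panel notation
#' \code{"chrom:pos:ref/alt"} with a 1-based position.  For pure insertions
#' (including internal tandem duplications, ITDs) the reference allele may
#' be empty, e.g. \code{"chr13:28608262:/CTGAAATCAACGTAGAAG"}.
#'
#' @param variant_id character vector of identifiers.
#' @return A data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}.
#' @examples
#' parseVariantId("chr15:90631934:C/T")
#' @export
parseVariantId <- function(variant_id) {
  if (!is.character(variant_id) || length(variant_id) == 0)
    stopf("variant_id must be a non-empty character vector")
  parts <- regmatches(variant_id,
                      regexec("^([^:]+):([0-9]+):([ACGTN]*)/([ACGTN]+)$",
                              variant_id))
  bad <- vapply(parts, length, 1L) != 5L
  if (any(bad))
    stopf("malformed variant_id: %s", paste(variant_id[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  pos <- as.integer(m[, 3L])
  if (any(pos < 1L))
    stopf("variant position must be >= 1")
  data.frame(variant_id = variant_id, chrom = m[, 2L], pos = pos,
             ref = m[, 4L], alt = m[, 5L], stringsAsFactors = FALSE)
}

#' Build a validated variant annotation table
#'
#' @param variant_id identifiers in \code{"chrom:pos:ref/alt"} notation.
#' @param gene gene symbol per variant.
#' @param protein_change optional protein-level annotation (e.g. "p.R140H").
#' @param class variant class, one of \code{"SNV"}, \code{"INDEL"},
#'   \code{"ITD"}; inferred from the alleles when \code{NULL} (an ITD is
#'   never inferred, it must be declared).
#' @return data.frame usable as \code{rowData} of a
#'   \linkS4class{CellAlleleCounts} object.
#' @examples
#' variantTable("chr15:90631934:C/T", "IDH2", "p.R140H")
#' @export
variantTable <- function(variant_id, gene, protein_change = NA_character_,
                         class = NULL) {
  p <- parseVariantId(variant_id)
  if (anyDuplicated(variant_id))
    stopf("duplicate variant_id within panel")
  if (length(gene) != nrow(p))
    gene <- rep_len(gene, nrow(p))
  protein_change <- rep_len(as.character(protein_change), nrow(p))
  inferred <- ifelse(nchar(p$ref) == 1L & nchar(p$alt) == 1L, "SNV", "INDEL")
  if (is.null(class)) class <- inferred
  class <- rep_len(class, nrow(p))
  if (!all(class %in% c("SNV", "INDEL", "ITD")))
    stopf("variant class must be SNV, INDEL or ITD")
  if (any(p$ref == p$alt))
    stopf("ref and alt allele must differ")
  itd <- class == "ITD"
  if (any(itd & (nchar(p$ref[itd]) > 0L | nchar(p$alt[itd]) < 3L)))
    stopf("ITD class requires an empty ref allele and alt length >= 3")
  if (any(!itd & nchar(p$ref[!itd]) == 0L & nchar(p$alt[!itd]) >= 3L))
    class[!itd & nchar(p$ref) == 0L & nchar(p$alt) >= 3L] <- "INDEL"
  data.frame(variant_id = p$variant_id, gene = gene,
             protein_change = protein_change, class = class,
             chrom = p$chrom, pos = p$pos, ref = p$ref, alt = p$alt,
             stringsAsFactors = FALSE)
}

#' Build a validated amplicon annotation table
#'
#' @param amplicon_id unique amplicon identifiers.
#' @param gene gene symbol (exactly one gene per amplicon).
#' @param start,end 1-based inclusive genomic coordinates.
#' @param chrom chromosome per amplicon.
#' @return data.frame usable as \code{rowData} of an
#'   \linkS4class{AmpliconCounts} object.
#' @export
ampliconTable <- function(amplicon_id, gene, chrom, start, end) {
  n <- length(amplicon_id)
  if (anyDuplicated(amplicon_id))
    stopf("duplicate amplicon_id")
  start <- as.integer(start); end <- as.integer(end)
  gene <- rep_len(gene, n)
  if (length(start) != n || length(end) != n)
    stopf("amplicon fields must have equal length")
  if (any(start > end) || any(start < 1L))
    stopf("amplicon coordinates must satisfy 1 <= start <= end")
  data.frame(amplicon_id = amplicon_id, gene = gene,
             chrom = rep_len(chrom, n), start = start, end = end,
             is_artifact = FALSE, stringsAsFactors = FALSE)
}

## Map each variant onto the amplicon containing it (1-based inclusive
## coordinate containment).  A variant covered by no amplicon is a
## configuration error, never silently zero-covered.
variantAmpliconIndex <- function(variants, amplicons) {
  idx <- integer(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    hit <- which(amplicons$chrom == variants$chrom[i] &
                 amplicons$start <= variants$pos[i] &
                 amplicons$end >= variants$pos[i])
    if (length(hit) == 0L)
      stopf("variant %s is not covered by any amplicon",
            variants$variant_id[i])
    idx[i] <- hit[1L]
  }
  idx
}
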