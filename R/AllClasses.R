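#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<-
NULL

## ---------------------------------------------------------------------------
## Count containers: SummarizedExperiment with rows = features, cols = cells
## (the on-disk interchange orientation is cells x features; IO transposes).
## ---------------------------------------------------------------------------

#' Per-cell, per-variant allele depths
#'
#' A \linkS4class{SummarizedExperiment} with rows = variants and columns =
#' cells, carrying integer assays \code{refDepth} and \code{altDepth} and a
#' variant annotation table (see \code{\link{variantTable}}) as
#' \code{rowData}.  This is the genotyper's sole input.
#'
#' @aliases CellAlleleCounts-class
#' @export
setClass("CellAlleleCounts", contains = "SummarizedExperiment")

#' Per-cell, per-amplicon read counts
#'
#' A \linkS4class{SummarizedExperiment} with rows = amplicons and columns =
#' cells, carrying one integer assay \code{counts} and an amplicon
#' annotation table (see \code{\link{ampliconTable}}) as \code{rowData}.
#' This is the copy-number pipeline's sole input.
#'
#' @aliases AmpliconCounts-class
#' @export
setClass("AmpliconCounts", contains = "SummarizedExperiment")

checkCountAssay <- function(m, nm) {
  if (!is.matrix(m)) return(sprintf("assay '%s' must be a matrix", nm))
  if (any(is.na(m))) return(sprintf("assay '%s' contains NA", nm))
  if (any(m < 0)) return(sprintf("assay '%s' has negative entries", nm))
  if (any(m != round(m))) return(sprintf("assay '%s' must be integer", nm))
  NULL
}

setValidity("CellAlleleCounts", function(object) {
  msg <- character()
  if (!all(c("refDepth", "altDepth") %in% names(assays(object))))
    return("assays 'refDepth' and 'altDepth' are required")
  for (nm in c("refDepth", "altDepth")) {
    e <- checkCountAssay(assay(object, nm), nm)
    if (!is.null(e)) msg <- c(msg, e)
  }
  cb <- colnames(object)
  if (is.null(cb) || anyDuplicated(cb))
    msg <- c(msg, "cell barcodes (colnames) must be present and unique")
  need <- c("variant_id", "gene", "protein_change", "class",
            "chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must carry the variantTable() columns")
  else if (anyDuplicated(rowData(object)$variant_id))
    msg <- c(msg, "variant_id must be unique")
  if (length(msg)) msg else TRUE
})

setValidity("AmpliconCounts", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  e <- checkCountAssay(assay(object, "counts"), "counts")
  if (!is.null(e)) msg <- c(msg, e)
  cb <- colnames(object)
  if (is.null(cb) || anyDuplicated(cb))
    msg <- c(msg, "cell barcodes (colnames) must be present and unique")
  need <- c("amplicon_id", "gene", "chrom", "start", "end", "is_artifact")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must carry the ampliconTable() columns")
  else {
    rd <- rowData(object)
    if (anyDuplicated(rd$amplicon_id))
      msg <- c(msg, "amplicon_id must be unique")
    if (any(rd$start > rd$end))
      msg <- c(msg, "amplicon start must be <= end")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellAlleleCounts object
#'
#' @param refDepth,altDepth cells-in-columns integer matrices
#'   (variants x cells); a cells x variants matrix is accepted when row
#'   names match \code{barcodes} and is transposed.
#' @param variants a \code{\link{variantTable}} data.frame (one row per
#'   variant, in row order of the matrices).
#' @param barcodes cell barcodes; defaults to the matrix column names.
#' @return A \linkS4class{CellAlleleCounts} object.
#' @export
CellAlleleCounts <- function(refDepth, altDepth, variants,
                             barcodes = colnames(refDepth)) {
  refDepth <- as.matrix(refDepth); altDepth <- as.matrix(altDepth)
  if (!identical(dim(refDepth), dim(altDepth)))
    stopf("refDepth and altDepth dimensions differ")
  if (nrow(refDepth) != nrow(variants)) {
    if (ncol(refDepth) == nrow(variants)) {   # cells x variants orientation
      refDepth <- t(refDepth); altDepth <- t(altDepth)
      if (is.null(barcodes)) barcodes <- colnames(refDepth)
    } else {
      stopf("dimension mismatch: %d matrix rows for %d variants",
            nrow(refDepth), nrow(variants))
    }
  }
  if (is.null(barcodes))
    stopf("cell barcodes are required")
  if (length(barcodes) != ncol(refDepth))
    stopf("dimension mismatch: %d columns for %d barcodes",
          ncol(refDepth), length(barcodes))
  dimnames(refDepth) <- dimnames(altDepth) <-
    list(variants$variant_id, barcodes)
  new("CellAlleleCounts", SummarizedExperiment(
    assays = list(refDepth = asIntegerMatrix(refDepth),
                  altDepth = asIntegerMatrix(altDepth)),
    rowData = DataFrame(variants, row.names = variants$variant_id)))
}

#' Construct an AmpliconCounts object
#'
#' @param counts amplicons x cells integer matrix (cells x amplicons is
#'   accepted and transposed).
#' @param amplicons an \code{\link{ampliconTable}} data.frame.
#' @param barcodes cell barcodes; defaults to matrix column names.
#' @return An \linkS4class{AmpliconCounts} object.
#' @export
AmpliconCounts <- function(counts, amplicons, barcodes = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(amplicons)) {
    if (ncol(counts) == nrow(amplicons)) {
      counts <- t(counts)
      if (is.null(barcodes)) barcodes <- colnames(counts)
    } else {
      stopf("dimension mismatch: %d matrix rows for %d amplicons",
            nrow(counts), nrow(amplicons))
    }
  }
  if (is.null(barcodes))
    stopf("cell barcodes are required")
  if (length(barcodes) != ncol(counts))
    stopf("dimension mismatch: %d columns for %d barcodes",
          ncol(counts), length(barcodes))
  dimnames(counts) <- list(amplicons$amplicon_id, barcodes)
  new("AmpliconCounts", SummarizedExperiment(
    assays = list(counts = asIntegerMatrix(counts)),
    rowData = DataFrame(amplicons, row.names = amplicons$amplicon_id)))
}

## ---------------------------------------------------------------------------
## Time-point sample and longitudinal dataset
## ---------------------------------------------------------------------------

#' One bone-marrow draw: allele depths plus optional amplicon counts
#'
#' @slot label sample label, unique within a dataset.
#' @slot months months from diagnosis (non-negative).
#' @slot alleleCounts a \linkS4class{CellAlleleCounts}.
#' @slot ampliconCounts an \linkS4class{AmpliconCounts} or \code{NULL};
#'   when present its cell barcode set must equal the allele-count set.
#' @aliases TimePointSample-class
#' @export
setClass("TimePointSample", representation(
  label = "character", months = "numeric",
  alleleCounts = "CellAlleleCounts", ampliconCounts = "ANY"))

setValidity("TimePointSample", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a single non-empty string")
  if (length(object@months) != 1L || is.na(object@months) ||
      object@months < 0)
    msg <- c(msg, "months must be a single non-negative number")
  amp <- object@ampliconCounts
  if (!is.null(amp)) {
    if (!is(amp, "AmpliconCounts"))
      msg <- c(msg, "ampliconCounts must be an AmpliconCounts or NULL")
    else if (!setequal(colnames(amp), colnames(object@alleleCounts)))
      msg <- c(msg, sprintf(
        "sample '%s': allele-count and amplicon-count barcode sets differ",
        object@label))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TimePointSample-class
#' @param label,months,alleleCounts,ampliconCounts see slots.
#' @export
TimePointSample <- function(label, months, alleleCounts,
                            ampliconCounts = NULL) {
  new("TimePointSample", label = as.character(label),
      months = as.numeric(months), alleleCounts = alleleCounts,
      ampliconCounts = ampliconCounts)
}

#' A serial single-cell amplicon dataset
#'
#' Ordered collection of \linkS4class{TimePointSample} objects (one per
#' bone-marrow draw) plus the panel gene list.  Cells at different time
#' points are independent draws and need not share barcodes.
#'
#' @slot panelGenes character vector of panel gene symbols.
#' @slot samples list of \linkS4class{TimePointSample}, ordered by
#'   \code{months}.
#' @aliases ScAmpliconDataset-class
#' @export
setClass("ScAmpliconDataset", representation(
  panelGenes = "character", samples = "list"))

setValidity("ScAmpliconDataset", function(object) {
  msg <- character()
  if (length(object@samples) == 0L)
    msg <- c(msg, "dataset must contain at least one sample")
  ok <- vapply(object@samples, is, TRUE, class2 = "TimePointSample")
  if (!all(ok))
    return("samples must all be TimePointSample objects")
  labs <- vapply(object@samples, function(s) s@label, "")
  if (anyDuplicated(labs))
    msg <- c(msg, "sample labels must be unique")
  mo <- vapply(object@samples, function(s) s@months, 0)
  if (is.unsorted(mo))
    msg <- c(msg, "samples must be ordered by non-decreasing months")
  if (length(msg)) msg else TRUE
})

#' @rdname ScAmpliconDataset-class
#' @param samples list of \linkS4class{TimePointSample}; sorted by months.
#' @param panelGenes panel gene symbols; default: union of genes seen in
#'   the samples' annotation tables.
#' @export
ScAmpliconDataset <- function(samples, panelGenes = NULL) {
  if (length(samples) == 0L)
    stopf("dataset must contain at least one sample")
  mo <- vapply(samples, function(s) s@months, 0)
  samples <- samples[order(mo)]
  if (is.null(panelGenes)) {
    panelGenes <- unique(unlist(lapply(samples, function(s) {
      g <- rowData(s@alleleCounts)$gene
      if (!is.null(s@ampliconCounts))
        g <- c(g, rowData(s@ampliconCounts)$gene)
      g
    })))
  }
  new("ScAmpliconDataset", panelGenes = as.character(panelGenes),
      samples = samples)
}

## ---------------------------------------------------------------------------
## Genotype calls
## ---------------------------------------------------------------------------

#' Per-cell genotype calls with quality
#'
#' A \linkS4class{SummarizedExperiment} (rows = variants, cols = cells)
#' with assays \code{zygosity} ("WT"/"HET"/"HOM"/"MISSING"), \code{vaf}
#' (NA when MISSING or depth 0), \code{gq} (phred-scaled, capped at 99,
#' NA when MISSING) and \code{depth}.  Model parameters are recorded in
#' \code{metadata()} and are immutable after construction.
#'
#' @aliases GenotypeCalls-class
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  need <- c("zygosity", "vaf", "gq", "depth")
  if (!all(need %in% names(assays(object))))
    return("assays zygosity, vaf, gq, depth are required")
  z <- assay(object, "zygosity")
  if (!all(z %in% c("WT", "HET", "HOM", "MISSING")))
    return("zygosity entries must be WT/HET/HOM/MISSING")
  p <- metadata(object)$params
  if (is.null(p) || !all(c("eps", "minDepth", "priors") %in% names(p)))
    return("metadata()$params must record eps, minDepth and priors")
  TRUE
})

## ---------------------------------------------------------------------------
## Clone assignment and fish table
## ---------------------------------------------------------------------------

#' Per-cell clone assignment over a driver variant set
#'
#' Each assigned cell carries a clone key: its zygosity tuple over the
#' driver set, encoded \code{"HET/WT"} in driver order.  Cells with any
#' MISSING or low-GQ driver call are unassigned (\code{NA} key).
#'
#' @slot barcodes cell barcodes.
#' @slot keys per-cell clone key, \code{NA} = unassigned.
#' @slot driverSet driver variant_ids (order defines the key encoding).
#' @slot driverGenes gene symbol per driver (for display labels).
#' @slot gqMin GQ threshold used.
#' @slot counts named integer vector of raw per-key cell counts.
#' @aliases CloneAssignment-class
#' @export
setClass("CloneAssignment", representation(
  barcodes = "character", keys = "character", driverSet = "character",
  driverGenes = "character", gqMin = "numeric", counts = "integer"))

setValidity("CloneAssignment", function(object) {
  msg <- character()
  if (length(object@keys) != length(object@barcodes))
    msg <- c(msg, "one key per barcode required")
  if (sum(object@counts) + sum(is.na(object@keys)) != length(object@keys))
    msg <- c(msg, "per-clone counts plus unassigned must equal cell count")
  if (length(object@driverGenes) != length(object@driverSet))
    msg <- c(msg, "one gene per driver variant required")
  if (length(msg)) msg else TRUE
})

#' Longitudinal clone-fraction (fish) table
#'
#' Clone fractions per time point over the union of clone keys, with
#' subset-based parent relations for fish-plot rendering.  Fractions are
#' the ADO-corrected maximum-likelihood estimates (see
#' \code{\link{estimateCloneFractions}}); the raw assigned-cell fractions
#' are retained alongside.
#'
#' @slot driverSet driver variant_ids.
#' @slot cloneKeys clone keys (columns of \code{fractions}).
#' @slot cloneLabels human-readable labels, e.g. "IDH2:HET+FLT3:HET".
#' @slot parents parent key per clone (\code{NA} for the root).
#' @slot fractions time point x clone matrix; rows sum to 1.
#' @slot rawFractions uncorrected assigned-cell fractions.
#' @slot months time in months per row.
#' @slot adoRate fitted allele-dropout rate used for the correction.
#' @aliases FishTable-class
#' @export
setClass("FishTable", representation(
  driverSet = "character", cloneKeys = "character",
  cloneLabels = "character", parents = "character", fractions = "matrix",
  rawFractions = "matrix", months = "numeric", adoRate = "numeric"))

setValidity("FishTable", function(object) {
  msg <- character()
  fr <- object@fractions
  if (ncol(fr) != length(object@cloneKeys))
    msg <- c(msg, "fractions columns must match cloneKeys")
  if (nrow(fr) > 0 && any(abs(rowSums(fr) - 1) > 1e-9))
    msg <- c(msg, "fraction rows must sum to 1 (tolerance 1e-9)")
  ## parent's non-WT variant set must be a strict subset of the child's
  nonWt <- lapply(object@cloneKeys, keyNonWtVariants,
                  driverSet = object@driverSet)
  names(nonWt) <- object@cloneKeys
  for (i in seq_along(object@cloneKeys)) {
    p <- object@parents[i]
    if (is.na(p)) next
    if (!p %in% object@cloneKeys) {
      msg <- c(msg, sprintf("parent '%s' is not a clone", p)); next
    }
    ps <- nonWt[[p]]; cs <- nonWt[[object@cloneKeys[i]]]
    if (!(all(ps %in% cs) && length(ps) < length(cs)))
      msg <- c(msg, sprintf(
        "parent of '%s' violates the strict-subset law",
        object@cloneKeys[i]))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Allelic burden and ploidy
## ---------------------------------------------------------------------------

#' Pooled per-cell allelic-burden (VAF) matrix
#'
#' @slot burden cells x variants matrix of per-cell VAFs in [0,1]
#'   (missing entries imputed per \code{missingPolicy}).
#' @slot timePoint time-point label per row.
#' @slot droppedVariants variants removed for excess missingness.
#' @slot missingPolicy record of the imputation rule applied.
#' @aliases AlleleBurdenMatrix-class
#' @export
setClass("AlleleBurdenMatrix", representation(
  burden = "matrix", timePoint = "character",
  droppedVariants = "character", missingPolicy = "character"))

setValidity("AlleleBurdenMatrix", function(object) {
  msg <- character()
  if (nrow(object@burden) != length(object@timePoint))
    msg <- c(msg, "one time-point label per cell row required")
  b <- object@burden
  if (any(is.na(b)) || any(b < 0) || any(b > 1))
    msg <- c(msg, "burden entries must lie in [0,1] after imputation")
  if (length(msg)) msg else TRUE
})

#' Normalized per-cell, per-amplicon ploidy estimates
#'
#' A \linkS4class{SummarizedExperiment} (rows = amplicons, cols = cells)
#' with assay \code{ploidy}, where 2 = diploid by construction: reference
#' cells have per-amplicon median ploidy exactly 2.  \code{metadata()}
#' records the reference cell set, excluded artifact amplicons and cells
#' dropped for low total counts.
#'
#' @aliases PloidyMatrix-class
#' @export
setClass("PloidyMatrix", contains = "SummarizedExperiment")

setValidity("PloidyMatrix", function(object) {
  if (!"ploidy" %in% names(assays(object)))
    return("assay 'ploidy' is required")
  md <- metadata(object)
  if (is.null(md$referenceCells))
    return("metadata()$referenceCells is required")
  pl <- assay(object, "ploidy")
  art <- md$artifactAmplicons
  keep <- !(rownames(pl) %in% art)
  if (any(pl[keep, ] < 0, na.rm = TRUE))
    return("ploidy entries must be non-negative")
  ref <- intersect(md$referenceCells, colnames(pl))
  if (length(ref)) {
    med <- apply(pl[keep, ref, drop = FALSE], 1L, median)
    if (any(abs(med - 2) > 1e-6))
      return("reference cells' per-amplicon median ploidy must be 2")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Simulation truth
## ---------------------------------------------------------------------------

#' Full generative ground truth for the synthetic-data generator
#'
#' @slot clones list of clone specifications (see \code{\link{cloneSpec}}).
#' @slot variants \code{\link{variantTable}} of panel variants.
#' @slot amplicons \code{\link{ampliconTable}} of panel amplicons.
#' @slot fractions time point x clone matrix of clone fractions; each row
#'   sums to 1 (tolerance 1e-9).
#' @slot labels,months time-point labels and months from diagnosis.
#' @slot ampliconEfficiency per-amplicon positive depth multiplier.
#' @slot meanDepth mean reads per cell per amplicon for a diploid gene at
#'   efficiency 1.
#' @slot depthDispersion negative-binomial size (overdispersion) parameter.
#' @slot pAdo allele-dropout probability per allele copy, in [0,1).
#' @slot seqError per-read miscall probability, in [0,0.5).
#' @slot doubletRate doublet probability per cell, in [0,0.5).
#' @slot nCells cells per time point.
#' @slot seed integer seed governing all sampling.
#' @aliases SimulationTruth-class
#' @export
setClass("SimulationTruth", representation(
  clones = "list", variants = "data.frame", amplicons = "data.frame",
  fractions = "matrix", labels = "character", months = "numeric",
  ampliconEfficiency = "numeric", meanDepth = "numeric",
  depthDispersion = "numeric", pAdo = "numeric", seqError = "numeric",
  doubletRate = "numeric", nCells = "integer", seed = "integer"))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  K <- length(object@clones)
  if (K == 0L) msg <- c(msg, "at least one clone required")
  ids <- vapply(object@clones, `[[`, "", "clone_id")
  if (anyDuplicated(ids)) msg <- c(msg, "clone ids must be unique")
  fr <- object@fractions
  if (ncol(fr) != K)
    msg <- c(msg, "fractions must have one column per clone")
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9))
    msg <- c(msg, "each fractions row must sum to 1 (tolerance 1e-9)")
  if (nrow(fr) != length(object@labels) ||
      nrow(fr) != length(object@months) ||
      nrow(fr) != length(object@nCells))
    msg <- c(msg, "labels, months and nCells must match fraction rows")
  nWt <- sum(vapply(object@clones,
                    function(cl) length(cl$genotypes) == 0L, TRUE))
  if (nWt > 1L)
    msg <- c(msg, "at most one clone may be fully wild type")
  for (cl in object@clones) {
    if (length(cl$copyNumber) &&
        (any(cl$copyNumber < 0L) || any(cl$copyNumber > 4L)))
      msg <- c(msg, sprintf("clone %s: copy numbers must lie in 0..4",
                            cl$clone_id))
    if (length(cl$genotypes) &&
        !all(names(cl$genotypes) %in% object@variants$variant_id))
      msg <- c(msg, sprintf("clone %s: genotype at unknown variant",
                            cl$clone_id))
    if (!is.na(cl$parent_id)) {
      pp <- object@clones[match(cl$parent_id, ids)][[1]]
      if (is.null(pp))
        msg <- c(msg, sprintf("clone %s: unknown parent", cl$clone_id))
      else if (!all(names(pp$genotypes)[pp$genotypes != "WT"] %in%
                    names(cl$genotypes)[cl$genotypes != "WT"]))
        msg <- c(msg, sprintf(
          "clone %s: parent's mutant variants are not a subset",
          cl$clone_id))
    }
  }
  if (length(object@ampliconEfficiency) != nrow(object@amplicons))
    msg <- c(msg, "one efficiency per amplicon required")
  if (any(object@ampliconEfficiency <= 0))
    msg <- c(msg, "amplicon efficiencies must be positive")
  if (object@pAdo < 0 || object@pAdo >= 1)
    msg <- c(msg, "pAdo must lie in [0,1)")
  if (object@seqError < 0 || object@seqError >= 0.5)
    msg <- c(msg, "seqError must lie in [0,0.5)")
  if (object@doubletRate < 0 || object@doubletRate >= 0.5)
    msg <- c(msg, "doubletRate must lie in [0,0.5)")
  if (any(object@nCells < 1L))
    msg <- c(msg, "nCells must be positive")
  if (length(msg)) msg else TRUE
})
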