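## On-disk interchange: a YAML manifest listing, per time point, the
## allele-depth and amplicon-count files.  Count matrices are MatrixMarket
## (row = cell, column = variant/amplicon) with TSV sidecars, or a wide-TSV
## fallback for small fixtures.  Integer counts round-trip bit-identically.

#' @importFrom Matrix readMM writeMM Matrix
NULL

readMatrixFile <- function(path, format, what) {
  if (!file.exists(path))
    stopf("cannot read %s: file not found: %s", what, path)
  if (format == "mtx") {
    asIntegerMatrix(as.matrix(Matrix::readMM(path)))
  } else {
    df <- readTsv(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    asIntegerMatrix(m)
  }
}

writeMatrixFile <- function(m, path, format, colIds) {
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  } else {
    df <- data.frame(barcode = rownames(m), m, check.names = FALSE)
    colnames(df) <- c("barcode", colIds)
    writeTsv(df, path)
  }
  invisible(path)
}

readBarcodes <- function(path) {
  if (!file.exists(path))
    stopf("cannot read barcodes: file not found: %s", path)
  bc <- readTsv(path)$barcode
  if (anyDuplicated(bc))
    stopf("duplicate barcode in %s", path)
  bc
}

#' Read a serial single-cell amplicon dataset from a manifest
#'
#' The manifest is a YAML file listing, per time point, the allele-depth
#' matrices (ref/alt), the optional amplicon-count matrix and the barcode /
#' variant / amplicon sidecar TSVs.  All container invariants are checked;
#' see \code{\link{writeDataset}} for the writer that produces this layout.
#'
#' @param manifestPath path to \code{manifest.yaml}.
#' @return A validated \linkS4class{ScAmpliconDataset}.
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stopf("cannot read manifest: file not found: %s", manifestPath)
  man <- yaml::read_yaml(manifestPath)
  base <- dirname(manifestPath)
  if (is.null(man$samples) || length(man$samples) == 0L)
    stopf("manifest lists no samples")
  samples <- lapply(man$samples, function(sm) {
    lab <- sm$label
    ac <- sm$allele_counts
    if (is.null(ac))
      stopf("sample '%s': allele_counts section missing", lab)
    fmt <- if (is.null(ac$format)) "mtx" else ac$format
    bc <- readBarcodes(file.path(base, ac$barcodes))
    vt <- readTsv(file.path(base, ac$variants))
    variants <- variantTable(vt$variant_id, vt$gene, vt$protein_change,
                             vt$class)
    ref <- readMatrixFile(file.path(base, ac$ref), fmt, "ref_depth")
    alt <- readMatrixFile(file.path(base, ac$alt), fmt, "alt_depth")
    if (nrow(ref) != length(bc) || nrow(alt) != length(bc))
      stopf("sample '%s': dimension mismatch on the cell axis (%d rows for %d barcodes)",
            lab, nrow(alt), length(bc))
    if (ncol(ref) != nrow(variants) || ncol(alt) != nrow(variants))
      stopf("sample '%s': dimension mismatch on the variant axis (%d columns for %d variants)",
            lab, ncol(alt), nrow(variants))
    amp <- NULL
    if (!is.null(sm$amplicon_counts)) {
      am <- sm$amplicon_counts
      afmt <- if (is.null(am$format)) "mtx" else am$format
      at <- readTsv(file.path(base, am$amplicons))
      amplicons <- ampliconTable(at$amplicon_id, at$gene, at$chrom,
                                 at$start, at$end)
      if (!is.null(at$is_artifact)) amplicons$is_artifact <- at$is_artifact
      abc <- readBarcodes(file.path(base, am$barcodes))
      cm <- readMatrixFile(file.path(base, am$counts), afmt,
                           "amplicon_counts")
      if (nrow(cm) != length(abc))
        stopf("sample '%s': dimension mismatch on the cell axis (%d rows for %d barcodes)",
              lab, nrow(cm), length(abc))
      if (ncol(cm) != nrow(amplicons))
        stopf("sample '%s': dimension mismatch on the amplicon axis (%d columns for %d amplicons)",
              lab, ncol(cm), nrow(amplicons))
      amp <- AmpliconCounts(t(cm), amplicons, barcodes = abc)
    }
    TimePointSample(lab, sm$months,
                    CellAlleleCounts(t(ref), t(alt), variants,
                                     barcodes = bc), amp)
  })
  ds <- ScAmpliconDataset(samples, panelGenes = unlist(man$panel_genes))
  validObject(ds)
  for (s in ds@samples) {
    validObject(s); validObject(s@alleleCounts)
    if (!is.null(s@ampliconCounts)) validObject(s@ampliconCounts)
  }
  ds
}

#' Write a dataset to an interchange directory
#'
#' Emits one sub-directory per time point (MatrixMarket count matrices plus
#' barcode/variant/amplicon TSV sidecars) and a \code{manifest.yaml}, such
#' that \code{readDataset(writeDataset(d, dir))} reproduces \code{d}
#' exactly (integer matrices bit-identical).
#'
#' @param dataset a \linkS4class{ScAmpliconDataset}.
#' @param outDir output directory (created if absent).
#' @param format \code{"mtx"} (default) or \code{"tsv"} for small fixtures.
#' @return The manifest path, invisibly.
#' @export
writeDataset <- function(dataset, outDir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(dataset, "ScAmpliconDataset"))
  validObject(dataset)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir))
    stopf("cannot write dataset: directory not writable: %s", outDir)
  ext <- if (format == "mtx") "mtx" else "tsv"
  entries <- lapply(dataset@samples, function(s) {
    lab <- s@label
    sdir <- file.path(outDir, lab)
    dir.create(sdir, showWarnings = FALSE)
    ac <- s@alleleCounts
    vi <- variantInfo(ac)
    writeTsv(data.frame(barcode = colnames(ac)),
             file.path(sdir, "barcodes.tsv"))
    writeTsv(vi[, c("variant_id", "gene", "protein_change", "class")],
             file.path(sdir, "variants.tsv"))
    writeMatrixFile(t(refDepth(ac)),
                    file.path(sdir, paste0("ref_depth.", ext)),
                    format, vi$variant_id)
    writeMatrixFile(t(altDepth(ac)),
                    file.path(sdir, paste0("alt_depth.", ext)),
                    format, vi$variant_id)
    entry <- list(label = lab, months = s@months,
                  allele_counts = list(
                    format = format,
                    ref = file.path(lab, paste0("ref_depth.", ext)),
                    alt = file.path(lab, paste0("alt_depth.", ext)),
                    barcodes = file.path(lab, "barcodes.tsv"),
                    variants = file.path(lab, "variants.tsv")))
    if (!is.null(s@ampliconCounts)) {
      am <- s@ampliconCounts
      ai <- ampliconInfo(am)
      writeTsv(ai[, c("amplicon_id", "gene", "chrom", "start", "end",
                      "is_artifact")],
               file.path(sdir, "amplicons.tsv"))
      writeTsv(data.frame(barcode = colnames(am)),
               file.path(sdir, "amp_barcodes.tsv"))
      writeMatrixFile(t(counts(am)),
                      file.path(sdir, paste0("amplicon_counts.", ext)),
                      format, ai$amplicon_id)
      entry$amplicon_counts <- list(
        format = format,
        counts = file.path(lab, paste0("amplicon_counts.", ext)),
        barcodes = file.path(lab, "amp_barcodes.tsv"),
        amplicons = file.path(lab, "amplicons.tsv"))
    }
    entry
  })
  man <- list(panel_genes = as.list(dataset@panelGenes),
              samples = entries)
  manifestPath <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(man, manifestPath)
  invisible(manifestPath)
}
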