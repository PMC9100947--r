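#' @importFrom BiocGenerics counts
NULL

#' Accessors for ampliClone containers
#'
#' Small accessor layer so user code never touches slots or assay names
#' directly.
#'
#' @param x an ampliClone object (see individual methods).
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refDepth", function(x, ...) standardGeneric("refDepth"))
#' @rdname accessors
#' @export
setGeneric("altDepth", function(x, ...) standardGeneric("altDepth"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x, ...) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("ampliconInfo", function(x, ...) standardGeneric("ampliconInfo"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x, ...) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleMonths", function(x, ...) standardGeneric("sampleMonths"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x, ...) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("ampliconCounts",
           function(x, ...) standardGeneric("ampliconCounts"))
#' @rdname accessors
#' @export
setGeneric("zygosity", function(x, ...) standardGeneric("zygosity"))
#' @rdname accessors
#' @export
setGeneric("vaf", function(x, ...) standardGeneric("vaf"))
#' @rdname accessors
#' @export
setGeneric("gq", function(x, ...) standardGeneric("gq"))
#' @rdname accessors
#' @export
setGeneric("callDepth", function(x, ...) standardGeneric("callDepth"))
#' @rdname accessors
#' @export
setGeneric("cloneKeys", function(x, ...) standardGeneric("cloneKeys"))
#' @rdname accessors
#' @export
setGeneric("cloneCounts", function(x, ...) standardGeneric("cloneCounts"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x, ...) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("ploidy", function(x, ...) standardGeneric("ploidy"))
#' @rdname accessors
#' @export
setGeneric("artifactAmplicons",
           function(x, ...) standardGeneric("artifactAmplicons"))
#' @rdname accessors
#' @export
setGeneric("referenceCells",
           function(x, ...) standardGeneric("referenceCells"))
#' @rdname accessors
#' @export
setGeneric("burden", function(x, ...) standardGeneric("burden"))

#' @rdname accessors
#' @export
setMethod("refDepth", "CellAlleleCounts",
          function(x, ...) assay(x, "refDepth"))
#' @rdname accessors
#' @export
setMethod("altDepth", "CellAlleleCounts",
          function(x, ...) assay(x, "altDepth"))
#' @rdname accessors
#' @export
setMethod("variantInfo", "CellAlleleCounts",
          function(x, ...) as.data.frame(rowData(x)))
#' @rdname accessors
#' @export
setMethod("counts", "AmpliconCounts", function(object) {
  assay(object, "counts")
})
#' @rdname accessors
#' @export
setMethod("ampliconInfo", "AmpliconCounts",
          function(x, ...) as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "ScAmpliconDataset",
          function(x, ...) vapply(x@samples, function(s) s@label, ""))
#' @rdname accessors
#' @export
setMethod("sampleMonths", "ScAmpliconDataset",
          function(x, ...) vapply(x@samples, function(s) s@months, 0))
#' @rdname accessors
#' @export
setMethod("alleleCounts", "TimePointSample",
          function(x, ...) x@alleleCounts)
#' @rdname accessors
#' @export
setMethod("ampliconCounts", "TimePointSample",
          function(x, ...) x@ampliconCounts)

#' Extract one time-point sample from a dataset
#'
#' @param x a \linkS4class{ScAmpliconDataset}.
#' @param which sample index or label.
#' @return A \linkS4class{TimePointSample}.
#' @export
getSample <- function(x, which) {
  stopifnot(is(x, "ScAmpliconDataset"))
  if (is.character(which)) {
    i <- match(which, sampleLabels(x))
    if (is.na(i)) stopf("unknown sample label '%s'", which)
  } else i <- which
  x@samples[[i]]
}

#' Number of time points in a dataset
#' @param x a \linkS4class{ScAmpliconDataset}.
#' @export
nSamples <- function(x) length(x@samples)

#' @rdname accessors
#' @export
setMethod("zygosity", "GenotypeCalls", function(x, ...) assay(x, "zygosity"))
#' @rdname accessors
#' @export
setMethod("vaf", "GenotypeCalls", function(x, ...) assay(x, "vaf"))
#' @rdname accessors
#' @export
setMethod("gq", "GenotypeCalls", function(x, ...) assay(x, "gq"))
#' @rdname accessors
#' @export
setMethod("callDepth", "GenotypeCalls", function(x, ...) assay(x, "depth"))

#' @rdname accessors
#' @export
setMethod("cloneKeys", "CloneAssignment", function(x, ...) x@keys)
#' @rdname accessors
#' @export
setMethod("cloneCounts", "CloneAssignment", function(x, ...) x@counts)
#' @rdname accessors
#' @export
setMethod("cloneKeys", "FishTable", function(x, ...) x@cloneKeys)

#' @rdname accessors
#' @param corrected return the ADO-corrected fractions (default) or the raw
#'   assigned-cell fractions.
#' @export
setMethod("fractions", "FishTable", function(x, corrected = TRUE, ...) {
  if (corrected) x@fractions else x@rawFractions
})
#' @rdname accessors
#' @export
setMethod("fractions", "CloneAssignment", function(x, ...) {
  n <- sum(x@counts)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  x@counts / n
})

#' @rdname accessors
#' @export
setMethod("ploidy", "PloidyMatrix", function(x, ...) assay(x, "ploidy"))
#' @rdname accessors
#' @export
setMethod("artifactAmplicons", "PloidyMatrix",
          function(x, ...) metadata(x)$artifactAmplicons)
#' @rdname accessors
#' @export
setMethod("referenceCells", "PloidyMatrix",
          function(x, ...) metadata(x)$referenceCells)

#' @rdname accessors
#' @export
setMethod("burden", "AlleleBurdenMatrix", function(x, ...) x@burden)

## -- show methods -----------------------------------------------------------

setMethod("show", "TimePointSample", function(object) {
  cat(sprintf("TimePointSample '%s' (%.4g months): %d cells, %d variants%s\n",
              object@label, object@months, ncol(object@alleleCounts),
              nrow(object@alleleCounts),
              if (is.null(object@ampliconCounts)) ""
              else sprintf(", %d amplicons",
                           nrow(object@ampliconCounts))))
})

setMethod("show", "ScAmpliconDataset", function(object) {
  cat(sprintf("ScAmpliconDataset: %d time points, %d panel genes\n",
              length(object@samples), length(object@panelGenes)))
  for (s in object@samples) show(s)
})

setMethod("show", "CloneAssignment", function(object) {
  n <- length(object@keys)
  cat(sprintf(
    "CloneAssignment over %d drivers (gqMin=%g): %d cells, %d assigned, %d clones\n",
    length(object@driverSet), object@gqMin, n, sum(!is.na(object@keys)),
    length(object@counts)))
})

setMethod("show", "FishTable", function(object) {
  cat(sprintf("FishTable: %d clones x %d time points (fitted ADO rate %.3f)\n",
              length(object@cloneKeys), nrow(object@fractions),
              object@adoRate))
  m <- round(object@fractions, 3)
  colnames(m) <- object@cloneLabels
  print(m)
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "SimulationTruth: %d clones, %d variants, %d amplicons/%d genes, %d time points\n",
    length(object@clones), nrow(object@variants), nrow(object@amplicons),
    length(unique(object@amplicons$gene)), nrow(object@fractions)))
  cat(sprintf(
    "  meanDepth=%g, dispersion=%g, pAdo=%g, seqError=%g, doubletRate=%g, seed=%d\n",
    object@meanDepth, object@depthDispersion, object@pAdo,
    object@seqError, object@doubletRate, object@seed))
})

setMethod("show", "AlleleBurdenMatrix", function(object) {
  cat(sprintf(
    "AlleleBurdenMatrix: %d cells x %d variants (%d dropped; policy: %s)\n",
    nrow(object@burden), ncol(object@burden),
    length(object@droppedVariants), object@missingPolicy))
})
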