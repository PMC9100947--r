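## Copy-number inference from amplicon read counts.  Two-step
## normalization: per cell by the cell's total count over non-artifact
## amplicons (library size), then per amplicon by the median of step-1
## values over reference cells, times 2 — so reference cells sit at
## ploidy 2 by construction.  Medians, not means, for robustness to the
## heavy-tailed per-amplicon depth spread of amplicon panels.

#' Flag low-efficiency (dropout-prone) artifact amplicons
#'
#' An amplicon is flagged when its zero-count cell fraction exceeds
#' \code{zeroFracMax} or its mean per-cell count falls below
#' \code{relDepthMin} times the panel-wide median of per-amplicon mean
#' counts.  Flagged amplicons are the apparent whole-gene-loss artifacts
#' caused by poor PCR efficiency and are excluded from every downstream
#' copy-number call.
#'
#' @param x an \linkS4class{AmpliconCounts}, or a list of them (pooled
#'   over time points).
#' @param zeroFracMax zero-fraction threshold (default 0.5).
#' @param relDepthMin relative mean-depth threshold (default 0.2).
#' @return Character vector of artifact amplicon_ids.
#' @export
flagDropoutAmplicons <- function(x, zeroFracMax = 0.5,
                                 relDepthMin = 0.2) {
  cnt <- poolAmpliconCounts(x)
  if (ncol(cnt) == 0L || nrow(cnt) == 0L)
    stopf("empty amplicon count matrix")
  if (ncol(cnt) < 100L)
    warning(sprintf(
      "artifact flagging on only %d cells; >= 100 recommended",
      ncol(cnt)), call. = FALSE)
  zeroFrac <- rowMeans(cnt == 0L)
  meanCnt <- rowMeans(cnt)
  flagged <- zeroFrac > zeroFracMax |
    meanCnt < relDepthMin * median(meanCnt)
  rownames(cnt)[flagged]
}

## cbind a list of AmpliconCounts / GenotypeCalls-compatible matrices,
## prefixing barcodes with the sample label to keep them unique.
poolAmpliconCounts <- function(x, labels = NULL) {
  if (is(x, "AmpliconCounts")) return(counts(x))
  stopifnot(is.list(x), length(x) >= 1L)
  if (is.null(labels)) labels <- sprintf("t%d", seq_along(x))
  mats <- lapply(seq_along(x), function(i) {
    m <- counts(x[[i]])
    colnames(m) <- paste(labels[i], colnames(m), sep = ":")
    m
  })
  ids <- rownames(mats[[1]])
  for (m in mats)
    if (!identical(rownames(m), ids))
      stopf("time points carry different amplicon panels")
  do.call(cbind, mats)
}

#' Select diploid reference cells (neutral-polymorphism cells)
#'
#' Reference cells are those somatically wild type at every driver
#' variant with confident calls: no MISSING driver call and GQ at or
#' above the threshold.  They anchor the copy-number normalization at
#' ploidy 2.
#'
#' @param gt a \linkS4class{GenotypeCalls} (or list, pooled with
#'   label-prefixed barcodes).
#' @param driverSet driver variant_ids.
#' @param gqMin GQ threshold (default 30).
#' @param minRefCells fail below this many reference cells (default 50).
#' @param labels labels used for prefixing when \code{gt} is a list.
#' @return Character vector of reference cell barcodes.
#' @export
selectReferenceCells <- function(gt, driverSet, gqMin = 30,
                                 minRefCells = 50, labels = NULL) {
  if (is.list(gt) && !is(gt, "GenotypeCalls")) {
    if (is.null(labels)) labels <- sprintf("t%d", seq_along(gt))
    ref <- unlist(lapply(seq_along(gt), function(i) {
      paste(labels[i],
            selectReferenceCells(gt[[i]], driverSet, gqMin,
                                 minRefCells = 0), sep = ":")
    }))
  } else {
    stopifnot(is(gt, "GenotypeCalls"))
    missing <- setdiff(driverSet, rownames(gt))
    if (length(missing))
      stopf("driver variant(s) not in panel: %s",
            paste(missing, collapse = ", "))
    z <- zygosity(gt)[driverSet, , drop = FALSE]
    q <- gq(gt)[driverSet, , drop = FALSE]
    ok <- colSums(z != "WT" | is.na(q) | q < gqMin) == 0L
    ref <- colnames(gt)[ok]
  }
  if (length(ref) < minRefCells)
    stopf("too few reference cells: %d found, %d required",
          length(ref), minRefCells)
  ref
}

#' Normalize amplicon counts to per-cell, per-amplicon ploidy
#'
#' Two-step normalization: (1) per cell, each amplicon count is divided
#' by that cell's total count over non-artifact amplicons; (2) per
#' amplicon, step-1 values are divided by their median over the
#' reference cells and multiplied by 2.  Cells whose non-artifact total
#' is below \code{minCellReads} are dropped and recorded in the result's
#' metadata.
#'
#' @param x an \linkS4class{AmpliconCounts} or list of them (pooled,
#'   barcodes prefixed by time-point label).
#' @param reference reference cell barcodes (after pooling prefixes).
#' @param artifacts artifact amplicon_ids to exclude.
#' @param minCellReads per-cell total-count floor (default 500).
#' @param labels pooling labels when \code{x} is a list.
#' @return A \linkS4class{PloidyMatrix}.
#' @export
normalizePloidy <- function(x, reference, artifacts = character(),
                            minCellReads = 500, labels = NULL) {
  cnt <- poolAmpliconCounts(x, labels = labels)
  unknown <- setdiff(artifacts, rownames(cnt))
  if (length(unknown))
    stopf("artifact id(s) not in panel: %s",
          paste(unknown, collapse = ", "))
  keep <- !(rownames(cnt) %in% artifacts)
  cellTot <- colSums(cnt[keep, , drop = FALSE])
  drop <- colnames(cnt)[cellTot < minCellReads]
  cnt2 <- cnt[, cellTot >= minCellReads, drop = FALSE]
  cellTot <- cellTot[cellTot >= minCellReads]
  reference <- intersect(reference, colnames(cnt2))
  if (length(reference) == 0L)
    stopf("no reference cell present after count filtering")
  s1 <- sweep(cnt2, 2L, cellTot, "/")
  refMed <- apply(s1[, reference, drop = FALSE], 1L, median)
  zero <- refMed == 0 & keep
  if (any(zero))
    stopf("reference median is 0 for non-artifact amplicon(s) %s; re-check artifact flagging",
          paste(rownames(cnt2)[zero], collapse = ", "))
  pl <- 2 * s1 / refMed
  pl[!keep, ] <- NA_real_  # artifact rows carry no ploidy estimate
  rd <- if (is(x, "AmpliconCounts")) rowData(x)
        else rowData(x[[1]])
  rd$is_artifact <- rownames(cnt2) %in% artifacts
  se <- SummarizedExperiment(assays = list(ploidy = pl), rowData = rd)
  metadata(se)$referenceCells <- reference
  metadata(se)$artifactAmplicons <- artifacts
  metadata(se)$droppedCells <- drop
  metadata(se)$minCellReads <- minCellReads
  new("PloidyMatrix", se)
}

## gene-level ploidy of a cell group: median over the group's cells of
## the per-cell median across the gene's non-artifact amplicons
groupGenePloidy <- function(pl, geneRows, cells) {
  sub <- pl[geneRows, cells, drop = FALSE]
  median(apply(sub, 2L, median))
}

#' Unbiased cell grouping by clustering the ploidy matrix
#'
#' k-means over a PCA reduction of the per-cell ploidy profiles, with k
#' chosen by mean silhouette width over \code{kRange}.  Used as the
#' "unbiased" grouping mode of \code{\link{detectCandidateCnvs}};
#' ploidy noise is continuous and the expected cluster count small,
#' which favours a centroid method over density clustering here.
#'
#' @param ploidyMat a \linkS4class{PloidyMatrix}.
#' @param kRange candidate cluster counts (default 2:8).
#' @param nComponents PCA components (default 10).
#' @param seed seed for k-means initialisation.
#' @param maxSilhouetteCells silhouette evaluated on at most this many
#'   cells (seeded subsample) to bound the distance matrix (default 2000).
#' @return Named integer cluster label per cell.
#' @export
cnvClusters <- function(ploidyMat, kRange = 2:8, nComponents = 10,
                        seed = 1L, maxSilhouetteCells = 2000L) {
  stopifnot(is(ploidyMat, "PloidyMatrix"))
  pl <- ploidy(ploidyMat)
  keep <- !(rownames(pl) %in% artifactAmplicons(ploidyMat))
  X <- t(pl[keep, , drop = FALSE])
  nc <- min(nComponents, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, rank. = nc, center = TRUE, scale. = FALSE)$x
  kRange <- kRange[kRange < nrow(pc)]
  if (length(kRange) == 0L)
    return(setNames(rep(1L, nrow(X)), rownames(X)))
  set.seed(stageSeed(seed, "cnv-kmeans"))
  sil <- if (nrow(pc) > maxSilhouetteCells)
    sort(sample.int(nrow(pc), maxSilhouetteCells)) else seq_len(nrow(pc))
  dSil <- dist(pc[sil, , drop = FALSE])
  best <- NULL; bestSil <- -Inf; bestK <- NA_integer_
  for (k in kRange) {
    km <- kmeans(pc, centers = k, nstart = 10L, iter.max = 200L,
                 algorithm = "Lloyd")
    sw <- mean(cluster::silhouette(km$cluster[sil], dSil)[, 3L])
    if (sw > bestSil) { bestSil <- sw; best <- km$cluster; bestK <- k }
  }
  setNames(as.integer(best), rownames(X))
}

#' Detect candidate copy-number variants per cell group and gene
#'
#' For each group of at least \code{minCells} cells and each gene, the
#' gene ploidy is the median over the group's cells of the per-cell
#' median across the gene's non-artifact amplicons.  A gene is a
#' candidate loss below \code{lossMax} and a candidate gain above
#' \code{gainMin} (midpoints between integer copy states).  Grouping is
#' either by clone key (\code{assignment}) or unbiased
#' (\code{\link{cnvClusters}}); both label sources flow through
#' identical candidate/confirmation logic.
#'
#' @param ploidyMat a \linkS4class{PloidyMatrix}.
#' @param groups named vector of per-cell group labels (names = cell
#'   barcodes as in the ploidy matrix); cells with \code{NA} group are
#'   excluded.  Alternatively supply \code{mode}.
#' @param mode "clone" (labels from \code{assignment}) or "unbiased"
#'   (labels from \code{\link{cnvClusters}}); ignored when \code{groups}
#'   is given.
#' @param assignment a \linkS4class{CloneAssignment} (for
#'   \code{mode = "clone"}); barcodes are matched to ploidy columns,
#'   allowing a "label:" pooling prefix.
#' @param lossMax candidate-loss threshold (default 1.5).
#' @param gainMin candidate-gain threshold (default 2.5).
#' @param minCells minimum group size (default 20).
#' @param seed seed for the unbiased clustering.
#' @return data.frame of candidate calls: gene, group, direction,
#'   ploidy, nAmplicons, status ("candidate").
#' @export
detectCandidateCnvs <- function(ploidyMat, groups = NULL,
                                mode = c("clone", "unbiased"),
                                assignment = NULL, lossMax = 1.5,
                                gainMin = 2.5, minCells = 20,
                                seed = 1L) {
  stopifnot(is(ploidyMat, "PloidyMatrix"))
  pl <- ploidy(ploidyMat)
  if (is.null(groups)) {
    mode <- match.arg(mode)
    groups <- if (mode == "unbiased")
      cnvClusters(ploidyMat, seed = seed)
    else cloneGroupsForPloidy(assignment, colnames(pl))
  }
  groups <- groups[!is.na(groups)]
  groups <- groups[names(groups) %in% colnames(pl)]
  rd <- as.data.frame(rowData(ploidyMat))
  keep <- !rd$amplicon_id %in% artifactAmplicons(ploidyMat)
  out <- list()
  tab <- table(groups)
  big <- names(tab)[tab >= minCells]
  if (length(big) == 0L) {
    warning("all groups fall below minCells; no candidate calls",
            call. = FALSE)
  }
  for (g in big) {
    cells <- names(groups)[groups == g]
    for (gene in unique(rd$gene)) {
      rows <- which(rd$gene == gene & keep)
      if (length(rows) == 0L) next
      gp <- groupGenePloidy(pl, rows, cells)
      dir <- if (gp < lossMax) "loss" else if (gp > gainMin) "gain"
             else NA_character_
      if (is.na(dir)) next
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, group = g, direction = dir, ploidy = gp,
        nAmplicons = length(rows), supportingFrac = NA_real_,
        status = "candidate", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), group = character(),
                      direction = character(), ploidy = numeric(),
                      nAmplicons = integer(), supportingFrac = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## clone keys -> per-ploidy-cell group labels, tolerating the "label:"
## prefix added by pooling
cloneGroupsForPloidy <- function(assignment, ploidyCells) {
  if (is(assignment, "CloneAssignment")) assignment <- list(assignment)
  stopifnot(length(assignment) >= 1L,
            all(vapply(assignment, is, TRUE, class2 = "CloneAssignment")))
  keys <- do.call(c, unname(lapply(assignment, function(a)
    setNames(a@keys, a@barcodes))))
  hit <- ploidyCells %in% names(keys)
  if (!all(hit)) {
    stripped <- sub("^[^:]+:", "", ploidyCells)
    if (all(stripped %in% names(keys)))
      return(setNames(unname(keys[stripped]), ploidyCells))
    stopf("assignment barcodes do not cover the ploidy matrix cells")
  }
  setNames(unname(keys[ploidyCells]), ploidyCells)
}

#' Confirm candidate CNVs by multi-amplicon consistency
#'
#' A candidate is confirmed when at least \code{confirmFrac} of the
#' gene's non-artifact amplicons are individually beyond the loss/gain
#' threshold (per-amplicon group median); otherwise its status is
#' "artifact" — a consistent drop across all of a gene's amplicons is
#' what separates a true copy loss from a single misbehaving amplicon.
#' Single-amplicon genes can be confirmed only on a non-flagged amplicon
#' and are marked as single-amplicon evidence.
#'
#' @param candidates candidate data.frame from
#'   \code{\link{detectCandidateCnvs}}.
#' @param ploidyMat the \linkS4class{PloidyMatrix} (built with the
#'   neutral-polymorphism reference cells).
#' @param groups the per-cell group labels used for the candidates (same
#'   semantics as in \code{\link{detectCandidateCnvs}}).
#' @param confirmFrac supporting-amplicon fraction required (default
#'   0.75).
#' @param lossMax,gainMin per-amplicon thresholds (defaults 1.5 / 2.5).
#' @return The candidates data.frame with \code{supportingFrac} filled
#'   and \code{status} set to "confirmed" or "artifact", plus a
#'   \code{singleAmplicon} logical column.
#' @export
confirmCnvs <- function(candidates, ploidyMat, groups,
                        confirmFrac = 0.75, lossMax = 1.5,
                        gainMin = 2.5) {
  stopifnot(is(ploidyMat, "PloidyMatrix"))
  if (nrow(candidates) == 0L) {
    candidates$singleAmplicon <- logical(0)
    return(candidates)
  }
  pl <- ploidy(ploidyMat)
  rd <- as.data.frame(rowData(ploidyMat))
  keep <- !rd$amplicon_id %in% artifactAmplicons(ploidyMat)
  groups <- groups[!is.na(groups)]
  candidates$singleAmplicon <- FALSE
  for (i in seq_len(nrow(candidates))) {
    gene <- candidates$gene[i]; g <- candidates$group[i]
    if (!gene %in% rd$gene)
      stopf("unknown gene '%s' in candidate list", gene)
    cells <- names(groups)[groups == g]
    if (length(cells) == 0L)
      stopf("unknown group '%s' in candidate list", g)
    rows <- which(rd$gene == gene & keep)
    ampMed <- apply(pl[rows, cells, drop = FALSE], 1L, median)
    support <- if (candidates$direction[i] == "loss")
      mean(ampMed < lossMax) else mean(ampMed > gainMin)
    candidates$supportingFrac[i] <- support
    candidates$singleAmplicon[i] <- length(rows) == 1L
    candidates$status[i] <- if (support >= confirmFrac)
      "confirmed" else "artifact"
  }
  candidates
}
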