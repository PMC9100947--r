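#' Pooled allelic-burden matrix across time points
#'
#' Collects per-cell VAFs for all panel variants, row-concatenating the
#' time points with labels preserved.  Variants whose VAF is missing in
#' more than \code{maxMissingFrac} of pooled cells are dropped; remaining
#' missing entries are imputed as 0 (the policy is recorded on the
#' object).  A VAF is missing when the cell's genotype at the variant is
#' MISSING or its depth is zero.
#'
#' @param gtList a \linkS4class{GenotypeCalls} or list of them (one per
#'   time point, same variant panel).
#' @param labels time-point label per element (default "t1", "t2", ...).
#' @param maxMissingFrac variant-dropping threshold (default 0.5).
#' @return An \linkS4class{AlleleBurdenMatrix}.
#' @export
alleleBurdenMatrix <- function(gtList, labels = NULL,
                               maxMissingFrac = 0.5) {
  if (is(gtList, "GenotypeCalls")) gtList <- list(gtList)
  stopifnot(length(gtList) >= 1L,
            all(vapply(gtList, is, TRUE, class2 = "GenotypeCalls")))
  if (is.null(labels)) labels <- sprintf("t%d", seq_along(gtList))
  vids <- rownames(gtList[[1]])
  for (g in gtList)
    if (!identical(rownames(g), vids))
      stopf("time points carry different variant panels")
  vafs <- do.call(rbind, lapply(gtList, function(g) t(vaf(g))))
  tp <- rep(labels, vapply(gtList, ncol, 0L))
  missFrac <- colMeans(is.na(vafs))
  drop <- colnames(vafs)[missFrac > maxMissingFrac]
  keep <- setdiff(colnames(vafs), drop)
  if (length(keep) == 0L)
    stopf("no variant survives the missingness filter")
  b <- vafs[, keep, drop = FALSE]
  b[is.na(b)] <- 0
  new("AlleleBurdenMatrix", burden = b, timePoint = tp,
      droppedVariants = drop,
      missingPolicy = sprintf(
        "VAF missing (MISSING call or zero depth) imputed as 0; variants with missing fraction > %g dropped",
        maxMissingFrac))
}

## ---------------------------------------------------------------------------
## DBSCAN (density-based spatial clustering with noise), Euclidean metric.
## Classic algorithm with blockwise neighbour search so the full distance
## matrix is never materialised.  Border points are attached to the
## cluster of their lowest-index core neighbour, which makes the result
## deterministic for a given input order.
## ---------------------------------------------------------------------------

epsNeighbours <- function(X, eps, block = 1024L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  eps2 <- eps^2 + 1e-12
  nbr <- vector("list", n)
  starts <- seq.int(1L, n, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1L, n)
    D2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(X[idx, , drop = FALSE], X)
    hits <- D2 <= eps2
    nbr[idx] <- lapply(seq_along(idx), function(r) which(hits[r, ]))
  }
  nbr
}

dbscanLabels <- function(X, eps, minPts) {
  n <- nrow(X)
  if (n == 0L) return(integer(0))
  nbr <- epsNeighbours(X, eps)
  core <- lengths(nbr) >= minPts
  labels <- integer(n)          # 0 = noise / unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      expand <- frontier[core[frontier]]
      if (!length(expand)) break
      nb <- unique(unlist(nbr[expand], use.names = FALSE))
      nb <- nb[labels[nb] == 0L]
      labels[nb] <- cl
      frontier <- nb
    }
  }
  labels
}

#' Density-based clustering of the allelic-burden matrix
#'
#' DBSCAN with Euclidean metric on the per-cell VAF matrix, the classic
#' pooled-time-point view of clonal heterogeneity.  Deterministic given
#' the input order; an all-noise result is legal.
#'
#' @param x an \linkS4class{AlleleBurdenMatrix} (or a plain numeric
#'   matrix, cells in rows).
#' @param eps neighbourhood radius in VAF units (default 0.3).
#' @param minSamples minimum neighbourhood size for a core cell
#'   (default 20).
#' @return Integer cluster label per cell; 0 is the designated noise
#'   label.
#' @export
clusterAlleleBurden <- function(x, eps = 0.3, minSamples = 20) {
  X <- if (is(x, "AlleleBurdenMatrix")) burden(x) else as.matrix(x)
  if (nrow(X) == 0L)
    stopf("empty burden matrix")
  labels <- dbscanLabels(X, eps, minSamples)
  names(labels) <- rownames(X)
  labels
}
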