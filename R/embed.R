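## Two-dimensional embedding of per-cell ploidy profiles: a linear PCA
## reduction followed by a spectral (Laplacian-eigenmap) manifold step on
## a kNN similarity graph.  Fully deterministic for a fixed seed: the
## only sampled quantity is the landmark subset used for large inputs,
## and eigenvector signs are fixed by convention.

knnGraphWeights <- function(S, k) {
  n <- nrow(S)
  D2 <- pmax(outer(rowSums(S^2), rowSums(S^2), "+") - 2 * tcrossprod(S), 0)
  diag(D2) <- Inf
  keepMask <- matrix(FALSE, n, n)
  kd <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(D2[i, ])[seq_len(k)]
    keepMask[i, o] <- TRUE
    kd[i] <- sqrt(D2[i, o[k]])
  }
  keepMask <- keepMask | t(keepMask)
  sigma <- median(kd)
  if (sigma == 0) sigma <- 1           # degenerate: coincident points
  W <- exp(-D2 / sigma^2)
  W[!keepMask] <- 0
  diag(W) <- 0
  W
}

spectralCoords <- function(S, k = 15L) {
  n <- nrow(S)
  if (n < 3L || all(abs(S) < 1e-12))
    return(matrix(0, n, 2L))
  W <- knnGraphWeights(S, min(k, n - 1L))
  deg <- rowSums(W)
  deg[deg == 0] <- 1e-12
  is <- 1 / sqrt(deg)
  L <- diag(n) - (is * W) * rep(is, each = n)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ## two smallest non-trivial eigenvalues; eigen() returns decreasing order
  idx <- rev(seq_len(n))[-1L][1:2]
  U <- ev$vectors[, idx, drop = FALSE] * is
  ## sign convention: largest-magnitude entry positive
  for (j in 1:2) {
    m <- which.max(abs(U[, j]))
    if (U[m, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Embed per-cell ploidy profiles into two dimensions
#'
#' Linear reduction to \code{nComponents} principal components followed
#' by a spectral manifold embedding of the cells' kNN graph; cells with
#' similar copy-number profiles land together, and planted group
#' structure becomes linearly separable.  For inputs above
#' \code{maxExactCells}, the spectral step runs on a seeded landmark
#' subset and the remaining cells are placed at the similarity-weighted
#' mean of their nearest landmarks.
#'
#' @param ploidyMat a \linkS4class{PloidyMatrix} (at least 10 cells).
#' @param nComponents PCA components (default 10); must not exceed the
#'   cell count.
#' @param seed integer seed (landmark selection).
#' @param maxExactCells dense-eigen size cap (default 2500).
#' @return data.frame with columns \code{cell}, \code{dim1}, \code{dim2}.
#' @export
embedPloidy <- function(ploidyMat, nComponents = 10, seed = 1L,
                        maxExactCells = 2500L) {
  stopifnot(is(ploidyMat, "PloidyMatrix"))
  pl <- ploidy(ploidyMat)
  keep <- !(rownames(pl) %in% artifactAmplicons(ploidyMat))
  X <- t(pl[keep, , drop = FALSE])
  if (nrow(X) < 10L)
    stopf("embedding requires at least 10 cells")
  if (nrow(X) < nComponents)
    stopf("fewer cells (%d) than components (%d)", nrow(X), nComponents)
  nc <- min(nComponents, ncol(X))
  S <- prcomp(X, rank. = nc, center = TRUE, scale. = FALSE)$x
  n <- nrow(S)
  if (n <= maxExactCells) {
    U <- spectralCoords(S)
  } else {
    set.seed(stageSeed(seed, "embed-landmarks"))
    land <- sort(sample.int(n, maxExactCells))
    Ul <- spectralCoords(S[land, , drop = FALSE])
    U <- matrix(0, n, 2L)
    U[land, ] <- Ul
    rest <- setdiff(seq_len(n), land)
    if (length(rest)) {
      Sl <- S[land, , drop = FALSE]
      sq <- rowSums(Sl^2)
      for (i in rest) {
        d2 <- sq - 2 * as.vector(Sl %*% S[i, ]) + sum(S[i, ]^2)
        nb <- order(d2)[seq_len(min(10L, length(land)))]
        w <- 1 / (d2[nb] + 1e-9)
        U[i, ] <- colSums(Ul[nb, , drop = FALSE] * w) / sum(w)
      }
    }
  }
  data.frame(cell = rownames(X), dim1 = U[, 1L], dim2 = U[, 2L],
             stringsAsFactors = FALSE)
}
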