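## Three-state binomial-mixture genotyper.  Per cell and variant, the
## alt-read count k out of depth n is modelled as Binomial(n, p) with
## p = eps (WT), 0.5 (HET), 1 - eps (HOM); posteriors are prior x
## likelihood normalized in log space.  GQ is the phred-scaled posterior
## of the called state, capped at 99.  Allele dropout is deliberately not
## modelled here: it is absorbed at the clone level (see
## estimateCloneFractions), because the clone taxonomy is defined on
## per-cell WT/HET/HOM calls.

ZYG_LEVELS <- c("WT", "HET", "HOM")

#' Variant allele frequency
#'
#' @param altDepth,totalDepth non-negative counts (vectorized);
#'   \code{altDepth <= totalDepth} required.
#' @return \code{altDepth / totalDepth}; \code{NA} (undefined, signalled,
#'   not 0) where \code{totalDepth} is 0.
#' @examples
#' computeVaf(5, 10)
#' computeVaf(0, 0)   # NA
#' @export
computeVaf <- function(altDepth, totalDepth) {
  if (any(totalDepth < 0) || any(altDepth < 0))
    stopf("depths must be non-negative")
  if (any(altDepth > totalDepth))
    stopf("altDepth may not exceed totalDepth")
  ifelse(totalDepth == 0, NA_real_, altDepth / totalDepth)
}

## log-likelihood matrix (n x 3) of the three zygosity states.
zygosityLogLik <- function(k, n, eps) {
  cbind(WT  = xlogy(k, eps) + xlogy(n - k, 1 - eps),
        HET = n * log(0.5),
        HOM = xlogy(k, 1 - eps) + xlogy(n - k, eps))
}

#' Genotype posteriors under the three-state binomial mixture
#'
#' @param altDepth,totalDepth alt and total read counts (vectorized);
#'   every \code{totalDepth} must be >= 1 (route zero-depth cells to
#'   MISSING before calling).
#' @param eps per-read miscall probability in [0, 0.5).
#' @param priors prior 3-vector (WT, HET, HOM), summing to 1.
#' @return Matrix (cases x 3) of posterior probabilities with columns
#'   WT, HET, HOM; rows sum to 1.  Computed in log space; stable for
#'   depths up to 1e5.
#' @examples
#' genotypePosteriors(10, 20, eps = 0.01)
#' @export
genotypePosteriors <- function(altDepth, totalDepth, eps = 0.01,
                               priors = c(1, 1, 1) / 3) {
  if (any(totalDepth < 1))
    stopf("genotypePosteriors requires totalDepth >= 1")
  if (any(altDepth > totalDepth) || any(altDepth < 0))
    stopf("require 0 <= altDepth <= totalDepth")
  if (eps < 0 || eps >= 0.5)
    stopf("eps must lie in [0, 0.5)")
  if (length(priors) != 3L || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-9)
    stopf("priors must be a non-negative 3-vector summing to 1")
  ll <- zygosityLogLik(altDepth, totalDepth, eps)
  lp <- sweep(ll, 2L, log(priors), "+")
  lp[, is.infinite(log(priors)) & log(priors) < 0] <- -Inf
  post <- exp(lp - rowLogSumExp(lp))
  post / rowSums(post)
}

## Internal vectorized caller core: returns zygosity, gq for given k, n.
callCore <- function(k, n, eps, priors) {
  ll <- zygosityLogLik(k, n, eps)
  lp <- sweep(ll, 2L, log(priors), "+")
  norm <- rowLogSumExp(lp)
  lpost <- lp - norm
  ## ties break toward the lower variant burden (WT > HET > HOM)
  called <- max.col(lpost, ties.method = "first")
  ## log(1 - posterior of call) = logsumexp of the two non-called states
  tmp <- lpost
  tmp[cbind(seq_along(called), called)] <- -Inf
  other <- rowLogSumExp(tmp)
  gq <- -10 / log(10) * other
  gq[!is.finite(gq) | gq > 99] <- 99
  gq[gq < 0] <- 0
  list(zygosity = ZYG_LEVELS[called], gq = gq)
}

#' Call one genotype (or a vector of genotypes)
#'
#' @inheritParams genotypePosteriors
#' @param minDepth cells with \code{totalDepth < minDepth} are MISSING
#'   (default 10).
#' @return data.frame with columns \code{zygosity} ("WT"/"HET"/"HOM"/
#'   "MISSING"), \code{vaf} (NA when MISSING), \code{gq} (phred, capped at
#'   99, NA when MISSING) and \code{depth}.
#' @examples
#' callGenotype(8, 16)
#' callGenotype(0, 5)   # MISSING: below the depth floor
#' @export
callGenotype <- function(altDepth, totalDepth, eps = 0.01, minDepth = 10,
                         priors = c(1, 1, 1) / 3) {
  m <- max(length(altDepth), length(totalDepth))
  altDepth <- rep_len(altDepth, m); totalDepth <- rep_len(totalDepth, m)
  miss <- totalDepth < minDepth
  zyg <- rep("MISSING", m); gqv <- rep(NA_real_, m)
  if (any(!miss)) {
    cc <- callCore(altDepth[!miss], totalDepth[!miss], eps, priors)
    zyg[!miss] <- cc$zygosity
    gqv[!miss] <- cc$gq
  }
  vafv <- rep(NA_real_, m)
  ok <- !miss & totalDepth > 0
  vafv[ok] <- altDepth[ok] / totalDepth[ok]
  data.frame(zygosity = zyg, vaf = vafv, gq = gqv, depth = totalDepth)
}

#' Genotype every cell and variant of a sample
#'
#' Element-wise application of \code{\link{callGenotype}} to a
#' \linkS4class{CellAlleleCounts} (or the allele counts of a
#' \linkS4class{TimePointSample}); model parameters are recorded in the
#' result's metadata and are immutable afterwards.
#'
#' @param x a \linkS4class{CellAlleleCounts} or
#'   \linkS4class{TimePointSample}.
#' @inheritParams callGenotype
#' @return A \linkS4class{GenotypeCalls}.
#' @export
callGenotypes <- function(x, eps = 0.01, minDepth = 10,
                          priors = c(1, 1, 1) / 3) {
  if (is(x, "TimePointSample")) x <- alleleCounts(x)
  stopifnot(is(x, "CellAlleleCounts"))
  ref <- refDepth(x); alt <- altDepth(x)
  tot <- ref + alt
  calls <- callGenotype(as.vector(alt), as.vector(tot), eps = eps,
                        minDepth = minDepth, priors = priors)
  shape <- function(v) matrix(v, nrow(x), ncol(x), dimnames = dimnames(x))
  se <- SummarizedExperiment(
    assays = list(zygosity = shape(calls$zygosity),
                  vaf = shape(calls$vaf), gq = shape(calls$gq),
                  depth = shape(calls$depth)),
    rowData = rowData(x))
  metadata(se)$params <- list(eps = eps, minDepth = minDepth,
                              priors = priors)
  new("GenotypeCalls", se)
}

#' Pseudobulk variant allele frequency
#'
#' Aggregates all cells of a sample into one bulk-style measurement:
#' total alt reads over total reads at the variant.
#'
#' @param x a \linkS4class{TimePointSample} or
#'   \linkS4class{CellAlleleCounts}.
#' @param variantId variant identifier (must be in the panel).
#' @return A fraction, or \code{NA} when the total depth is 0.
#' @export
pseudobulkVaf <- function(x, variantId) {
  if (is(x, "TimePointSample")) x <- alleleCounts(x)
  stopifnot(is(x, "CellAlleleCounts"))
  if (!variantId %in% rownames(x))
    stopf("unknown variant '%s'", variantId)
  a <- sum(altDepth(x)[variantId, ])
  tot <- a + sum(refDepth(x)[variantId, ])
  if (tot == 0) NA_real_ else a / tot
}
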