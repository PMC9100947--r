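## Clone = exact zygosity tuple over a chosen driver-variant set, encoded
## "HET/WT" in driver order.  This mirrors the WT / het / hom / double /
## triple-mutant taxonomy used for single-cell amplicon clone tracking.

keyZygosities <- function(key) strsplit(key, "/", fixed = TRUE)

keyNonWtVariants <- function(key, driverSet) {
  z <- keyZygosities(key)[[1]]
  driverSet[z != "WT"]
}

cloneLabelFromKey <- function(key, driverGenes) {
  z <- keyZygosities(key)[[1]]
  if (all(z == "WT")) return("WT")
  paste(sprintf("%s:%s", driverGenes[z != "WT"], z[z != "WT"]),
        collapse = "+")
}

#' Assign cells to clones by zygosity profile over a driver set
#'
#' A cell is unassigned if any driver call is MISSING or below the GQ
#' threshold; otherwise its clone key is its zygosity tuple over the
#' driver set.  Raw per-key counts are retained on the object; corrected
#' fraction estimates come from \code{\link{estimateCloneFractions}}.
#'
#' @param gt a \linkS4class{GenotypeCalls}.
#' @param driverSet non-empty character vector of driver variant_ids (all
#'   must be in the panel).
#' @param gqMin GQ retention threshold (default 30).
#' @return A \linkS4class{CloneAssignment}.
#' @export
assignClones <- function(gt, driverSet, gqMin = 30) {
  stopifnot(is(gt, "GenotypeCalls"))
  if (length(driverSet) == 0L)
    stopf("driver set must be non-empty")
  missing <- setdiff(driverSet, rownames(gt))
  if (length(missing))
    stopf("driver variant(s) not in panel: %s",
          paste(missing, collapse = ", "))
  z <- zygosity(gt)[driverSet, , drop = FALSE]
  q <- gq(gt)[driverSet, , drop = FALSE]
  bad <- colSums(z == "MISSING" | is.na(q) | q < gqMin) > 0L
  keys <- do.call(paste, c(asplit(z, 1L), sep = "/"))
  keys[bad] <- NA_character_
  counts <- table(keys, useNA = "no")
  genes <- as.character(rowData(gt)$gene[match(driverSet, rownames(gt))])
  new("CloneAssignment", barcodes = colnames(gt), keys = keys,
      driverSet = driverSet, driverGenes = genes, gqMin = gqMin,
      counts = setNames(as.integer(counts), names(counts)))
}

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeCalls",
          function(x, ...) as.data.frame(rowData(x)))

## Per-variant zygosity observation matrix under allele dropout rate p:
## rows = true state, cols = observed state.  A HET cell is observed WT
## when its alt copy drops (prob p, including the both-drop case, whose
## reads are error-only), HOM when only the ref copy drops (p(1-p)); a
## HOM cell is observed WT only when every copy drops (p^2).
adoTransition <- function(p) {
  rbind(WT  = c(1, 0, 0),
        HET = c(p, (1 - p)^2, p * (1 - p)),
        HOM = c(p^2, 0, 1 - p^2))
}

## Misclassification probability M[k, c] = P(observed key k | true clone c)
## as a product of independent per-driver transitions.
keyConfusionMatrix <- function(obsKeys, candKeys, p) {
  Tm <- adoTransition(p)
  colnames(Tm) <- c("WT", "HET", "HOM")
  oz <- do.call(rbind, keyZygosities(obsKeys))
  cz <- do.call(rbind, keyZygosities(candKeys))
  M <- matrix(1, length(obsKeys), length(candKeys),
              dimnames = list(obsKeys, candKeys))
  for (v in seq_len(ncol(oz)))
    M <- M * Tm[cbind(rep(cz[, v], each = length(obsKeys)),
                      rep(oz[, v], times = length(candKeys)))]
  M
}

allKeysForDrivers <- function(d) {
  grid <- do.call(expand.grid,
                  rep(list(c("WT", "HET", "HOM")), d))
  apply(as.matrix(grid), 1L, paste, collapse = "/")
}

## Observed-state distribution of one variant in a doublet of zygosities
## (z1, z2): allele copies are summed, each copy drops independently with
## probability p, and the surviving allele balance maps to the called
## state (large-depth call boundaries ~0.15 / 0.85; zero survivors read
## as WT).  Enumerated exactly over the surviving-copy outcomes.
pairStateProb <- function(z1, z2, p) {
  cp <- function(z) switch(z, WT = c(0L, 2L), HET = c(1L, 2L),
                           HOM = c(2L, 2L))
  c1 <- cp(z1); c2 <- cp(z2)
  a <- c1[1L] + c2[1L]; tt <- c1[2L] + c2[2L]
  pr <- c(0, 0, 0)
  for (sa in 0:a) for (sr in 0:(tt - a)) {
    w <- stats::dbinom(sa, a, 1 - p) * stats::dbinom(sr, tt - a, 1 - p)
    st <- sa + sr
    b <- if (st == 0L) 0 else sa / st
    s <- if (b < 0.15) 1L else if (b > 0.85) 3L else 2L
    pr[s] <- pr[s] + w
  }
  pr
}

## P(observed key | unordered doublet of candidate clones i <= j):
## keySpace x nPairs matrix plus the pair index vectors.
pairConfusionMatrix <- function(obsKeys, candKeys, p) {
  K <- length(candKeys)
  idx <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  pairI <- idx[, 2L]; pairJ <- idx[, 1L]   # i <= j
  oz <- do.call(rbind, keyZygosities(obsKeys))
  cz <- do.call(rbind, keyZygosities(candKeys))
  zl <- c("WT", "HET", "HOM")
  cache <- array(NA_real_, c(3, 3, 3))
  getPr <- function(a, b) {
    i <- match(a, zl); j <- match(b, zl)
    lo <- min(i, j); hi <- max(i, j)
    if (is.na(cache[lo, hi, 1])) cache[lo, hi, ] <<-
        pairStateProb(zl[lo], zl[hi], p)
    cache[lo, hi, ]
  }
  M <- matrix(1, length(obsKeys), length(pairI))
  for (v in seq_len(ncol(oz))) {
    os <- match(oz[, v], zl)
    for (q in seq_along(pairI)) {
      pr <- getPr(cz[pairI[q], v], cz[pairJ[q], v])
      M[, q] <- M[, q] * pr[os]
    }
  }
  list(M = M, pairI = pairI, pairJ = pairJ)
}

## Joint EM over time points: per-time-point clone fractions plus one
## shared doublet rate; the confusion matrices (singlet and doublet) are
## fixed for a given dropout rate p.
emJointFractions <- function(obsMat, Msing, pairs, tol = 1e-8,
                             maxIter = 1000L, delta = NULL) {
  fixedDelta <- !is.null(delta)
  Tn <- ncol(obsMat); K <- ncol(Msing)
  Mp <- pairs$M; pI <- pairs$pairI; pJ <- pairs$pairJ
  A <- matrix(0, K, length(pI))        # pair-membership multiplicities
  for (q in seq_along(pI)) {
    A[pI[q], q] <- A[pI[q], q] + 1
    A[pJ[q], q] <- A[pJ[q], q] + 1
  }
  raw <- sweep(crossprod(Msing > 0.5, obsMat) + 1, 2,
               colSums(obsMat) + K, "/")  # crude init from exact keys
  f <- t(raw); f <- f / rowSums(f)
  if (!fixedDelta) delta <- 0.05
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    num <- matrix(0, Tn, K)
    dbl <- 0; llNew <- 0
    for (t in seq_len(Tn)) {
      o <- obsMat[, t]
      ft <- f[t, ]
      wS <- (1 - delta) * Msing * rep(ft, each = nrow(Msing))
      pp <- ft[pI] * ft[pJ] * ifelse(pI == pJ, 1, 2)
      wP <- delta * Mp * rep(pp, each = nrow(Mp))
      tot <- rowSums(wS) + rowSums(wP)
      tot[tot < 1e-300] <- 1e-300
      llNew <- llNew + sum(o[o > 0] * log(tot[o > 0]))
      scale <- o / tot
      sC <- colSums(wS * scale)
      pC <- colSums(wP * scale)
      w <- sC + as.vector(A %*% pC)
      num[t, ] <- w / sum(w)
      dbl <- dbl + sum(pC)
    }
    deltaNew <- if (fixedDelta) delta
                else min(max(dbl / sum(obsMat), 0), 0.49)
    done <- max(abs(num - f)) < tol && abs(deltaNew - delta) < tol
    f <- num; delta <- deltaNew; ll <- llNew
    if (done) break
  }
  list(f = f, delta = delta, logLik = ll)
}

#' Allele-dropout-corrected clone-fraction estimates
#'
#' Allele dropout makes a true heterozygous driver read as WT or HOM in a
#' predictable fraction of cells, so raw zygosity-tuple fractions are
#' biased (a double-HET clone loses roughly \eqn{1-(1-p)^4}{1-(1-p)^4} of
#' its cells at dropout rate p).  This estimator treats the observed key
#' counts as a multinomial mixture: each candidate clone emits observed
#' keys via a per-driver zygosity confusion matrix parameterised by a
#' single dropout rate, fitted by profile likelihood (grid + refinement)
#' with the per-time-point fractions obtained by EM.  The mixture also
#' carries doublet components (unordered clone pairs whose summed allele
#' copies are pushed through the same dropout model), since unmodelled
#' doublets collapse mixed clone pairs into heterozygous-looking keys
#' and bias the large-clone fractions.  The doublet rate is fixed at the
#' instrument-typical value by default — it is barely identifiable from
#' key counts alone, because doublet output mass lands almost entirely
#' on existing clone keys — but can be estimated in the EM by passing
#' \code{doubletRate = NULL}.
#'
#' Candidate clones are the observed keys reaching \code{minCells} in
#' some time point; because the saturated model (every key a clone) fits
#' perfectly at dropout rate 0, dropout-explainable phantom keys are
#' pruned by greedy backward elimination under BIC.
#'
#' @param x a \linkS4class{CloneAssignment} or a list of them (one per
#'   time point, sharing the driver set; the dropout rate is fitted
#'   jointly).
#' @param minCells a key must reach this many raw cells in at least one
#'   time point to be a candidate clone (default 5) — this is also the
#'   guard against dropout-generated phantom clones.
#' @param pAdo fix the dropout rate instead of fitting it.
#' @param maxAdo upper bound of the profiled dropout rate (default 0.25).
#' @param doubletRate doublet probability assumed by the mixture
#'   (default 0.03, a typical droplet-chemistry figure); \code{NULL} to
#'   estimate it jointly.
#' @param selectClones prune dropout-explainable phantom keys from the
#'   candidate clone set by greedy backward elimination under BIC
#'   (default TRUE).  Without pruning, the saturated model (every
#'   observed key its own clone) fits any data perfectly at dropout
#'   rate 0, so the rate would not be identifiable.
#' @return A list: \code{fractions} (time point x clone matrix, rows sum
#'   to 1), \code{rawFractions}, \code{pAdo}, \code{logLik},
#'   \code{cloneKeys}.
#' @export
estimateCloneFractions <- function(x, minCells = 5, pAdo = NULL,
                                   maxAdo = 0.25, selectClones = TRUE,
                                   doubletRate = 0.03) {
  if (is(x, "CloneAssignment")) x <- list(x)
  stopifnot(length(x) >= 1L,
            all(vapply(x, is, TRUE, class2 = "CloneAssignment")))
  d <- length(x[[1]]@driverSet)
  for (a in x)
    if (!identical(a@driverSet, x[[1]]@driverSet))
      stopf("assignments use inconsistent driver sets")
  countsOf <- function(a, keys) {
    out <- setNames(integer(length(keys)), keys)
    out[names(a@counts)] <- a@counts
    out
  }
  obsKeys <- sort(unique(unlist(lapply(x, function(a) names(a@counts)))))
  maxPerKey <- apply(vapply(x, countsOf, integer(length(obsKeys)),
                            keys = obsKeys), 1L, max)
  candKeys <- obsKeys[maxPerKey >= minCells]
  if (length(candKeys) == 0L) candKeys <- obsKeys
  keySpace <- if (d <= 6L) allKeysForDrivers(d)
              else sort(unique(c(obsKeys, candKeys)))
  obsMat <- vapply(x, countsOf, integer(length(keySpace)),
                   keys = keySpace)
  obsMat <- matrix(obsMat, nrow = length(keySpace))

  fitAt <- function(p, cand, maxIter = 400L, tol = 1e-7) {
    M <- keyConfusionMatrix(keySpace, cand, p)
    if (d > 6L) M <- sweep(M, 2L, colSums(M), "/")  # conditional lik
    pairs <- pairConfusionMatrix(keySpace, cand, p)
    emJointFractions(obsMat, M, pairs, tol = tol, maxIter = maxIter,
                     delta = doubletRate)
  }
  profileP <- function(cand) {
    grid <- seq(0, maxAdo, by = 0.01)
    lls <- vapply(grid, function(p) fitAt(p, cand, 250L)$logLik, 0)
    pBest <- grid[which.max(lls)]
    lo <- max(0, pBest - 0.01); hi <- min(maxAdo, pBest + 0.01)
    opt <- optimize(function(p) fitAt(p, cand, 250L)$logLik, c(lo, hi),
                    maximum = TRUE, tol = 5e-4)
    if (opt$objective >= max(lls)) list(p = opt$maximum,
                                        logLik = opt$objective)
    else list(p = pBest, logLik = max(lls))
  }
  N <- sum(obsMat)
  bicOf <- function(ll, nCand) {
    npar <- (nCand - 1L) * length(x) + 1L
    -2 * ll + npar * log(max(N, 2))
  }
  ## Greedy backward elimination under BIC at a fixed dropout rate.
  selectAt <- function(p, cand) {
    cur <- fitAt(p, cand)
    curBic <- bicOf(cur$logLik, length(cand))
    repeat {
      if (length(cand) == 1L) break
      fr <- matrix(cur$f, ncol = length(cand))
      wMean <- colSums(fr * colSums(obsMat)) / sum(obsMat)
      improved <- FALSE
      for (j in order(wMean)[seq_len(min(3L, length(cand)))]) {
        trial <- cand[-j]
        ev <- fitAt(p, trial)
        evBic <- bicOf(ev$logLik, length(trial))
        if (evBic < curBic - 1e-9) {
          cand <- trial; cur <- ev; curBic <- evBic; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    cand
  }
  fitP <- is.null(pAdo)
  ## On the saturated candidate set the likelihood is maximal at dropout
  ## rate 0 (every key fits itself), so the rate must not be profiled
  ## before a first pruning pass: start selection at a moderate rate and
  ## alternate selection and profiling until both are stable.
  p <- if (fitP) min(0.1, maxAdo) else pAdo
  if (selectClones) {
    for (round in 1:4) {
      cand2 <- selectAt(p, candKeys)
      changed <- !identical(cand2, candKeys)
      candKeys <- cand2
      if (fitP) {
        p2 <- profileP(candKeys)$p
        stable <- abs(p2 - p) < 0.005 && !changed
        p <- p2
        if (stable) break
      } else if (!changed) break
    }
  } else if (fitP) {
    p <- profileP(candKeys)$p
  }
  pAdo <- p
  final <- fitAt(pAdo, candKeys, maxIter = 3000L, tol = 1e-9)
  fr <- matrix(final$f, nrow = length(x), dimnames = list(
    names(x), candKeys))
  raw <- t(vapply(seq_along(x), function(t) {
    o <- obsMat[match(candKeys, keySpace), t]
    tot <- sum(x[[t]]@counts)
    if (tot == 0) rep(NA_real_, length(candKeys)) else o / tot
  }, numeric(length(candKeys))))
  raw <- matrix(raw, nrow = length(x), dimnames = dimnames(fr))
  list(fractions = fr, rawFractions = raw, pAdo = pAdo,
       doubletRate = final$delta, logLik = final$logLik,
       cloneKeys = candKeys)
}

#' Detect rare (sub-percent) mutant clones
#'
#' Reports non-wild-type clone keys carried by at least \code{minCells}
#' cells but below \code{rareFraction} of assigned cells — the regime in
#' which bulk sequencing is blind but single cells with high-GQ mutant
#' calls remain countable.  The cell floor is the guard against
#' allele-dropout phantom keys.
#'
#' @param assignment a \linkS4class{CloneAssignment}.
#' @param minCells minimum raw cell count (default 5).
#' @param rareFraction report clones below this assigned-cell fraction
#'   (default 0.01).
#' @return data.frame (key, label, cells, fraction) sorted by fraction,
#'   descending.
#' @export
detectRareClones <- function(assignment, minCells = 5,
                             rareFraction = 0.01) {
  stopifnot(is(assignment, "CloneAssignment"), minCells >= 1)
  cnt <- assignment@counts
  tot <- sum(cnt)
  if (tot == 0L)
    return(data.frame(key = character(), label = character(),
                      cells = integer(), fraction = numeric()))
  wt <- vapply(names(cnt), function(k)
    length(keyNonWtVariants(k, assignment@driverSet)) == 0L, TRUE)
  frac <- cnt / tot
  keep <- !wt & cnt >= minCells & frac < rareFraction
  out <- data.frame(
    key = names(cnt)[keep],
    label = vapply(names(cnt)[keep], cloneLabelFromKey, "",
                   driverGenes = assignment@driverGenes),
    cells = as.integer(cnt[keep]), fraction = as.numeric(frac[keep]),
    stringsAsFactors = FALSE)
  out[order(-out$fraction), , drop = FALSE]
}

#' Joint zygosity (co-occurrence) table over a variant set
#'
#' Counts cells per joint zygosity combination, using only cells with a
#' present (non-MISSING) call of at least \code{gqMin} GQ at every
#' queried variant; supports triple-mutant (and higher) queries.
#'
#' @param gt a \linkS4class{GenotypeCalls}.
#' @param variants two or more variant_ids.
#' @param gqMin GQ threshold (default 30).
#' @return A contingency \code{table} with one dimension per variant
#'   (levels WT/HET/HOM).
#' @export
cooccurrenceTable <- function(gt, variants, gqMin = 30) {
  stopifnot(is(gt, "GenotypeCalls"))
  if (length(variants) < 2L)
    stopf("co-occurrence requires at least two variants")
  missing <- setdiff(variants, rownames(gt))
  if (length(missing))
    stopf("variant(s) not in matrix: %s", paste(missing, collapse = ", "))
  z <- zygosity(gt)[variants, , drop = FALSE]
  q <- gq(gt)[variants, , drop = FALSE]
  ok <- colSums(z == "MISSING" | is.na(q) | q < gqMin) == 0L
  fct <- lapply(seq_along(variants), function(i)
    factor(z[i, ok], levels = ZYG_LEVELS))
  names(fct) <- variants
  table(fct)
}
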