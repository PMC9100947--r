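## Independent oracles used by the tests.  These deliberately take a
## different computational route from the package (stats::dbinom +
## max-scaling instead of hand-written log-space binomial terms;
## exhaustive enumeration instead of the generator's sampling).

## Brute-force genotype posterior: direct evaluation of the three
## binomial terms, normalized after scaling by the maximum.
oraclePosterior <- function(k, n, eps, priors = c(1, 1, 1) / 3) {
  ll <- dbinom(k, n, c(eps, 0.5, 1 - eps), log = TRUE) + log(priors)
  w <- exp(ll - max(ll))
  w / sum(w)
}

oracleCall <- function(k, n, eps, priors = c(1, 1, 1) / 3) {
  post <- oraclePosterior(k, n, eps, priors)
  called <- which.max(post)   # ties resolve to the first (WT < HET < HOM)
  gq <- -10 * log10(max(1 - post[called], 0))
  list(zygosity = c("WT", "HET", "HOM")[called],
       gq = min(gq, 99), posterior = post)
}

## E[p_eff] and E[p_eff^2] of the alt-read probability for a cell with
## alt0 alt copies out of tot0, under per-copy dropout p and read error
## eps (full dropout reads at the error rate), by exhaustive enumeration.
adoMoments <- function(alt0, tot0, pado, eps) {
  m1 <- 0; m2 <- 0
  for (sa in 0:alt0) {
    for (sr in 0:(tot0 - alt0)) {
      w <- dbinom(sa, alt0, 1 - pado) * dbinom(sr, tot0 - alt0, 1 - pado)
      st <- sa + sr
      b <- if (st == 0) 0 else sa / st
      pe <- b * (1 - 2 * eps) + eps
      m1 <- m1 + w * pe
      m2 <- m2 + w * pe^2
    }
  }
  c(m1 = m1, m2 = m2)
}

## Allele copies of a simulated cell at a variant (clone + optional
## doublet partner), mirroring the generative definitions.
configCopies <- function(zygs, cns) {
  alt <- 0L; tot <- 0L
  for (i in seq_along(zygs)) {
    cn <- cns[i]
    a <- switch(zygs[i], WT = 0L, HOM = cn,
                HET = if (cn >= 1L) max(1L, as.integer(round(cn / 2)))
                      else 0L)
    alt <- alt + a; tot <- tot + cn
  }
  c(alt = alt, tot = tot)
}

## Expected pseudobulk VAF and its SE at one time point, conditioning on
## the realized per-cell depths and the sidecar's true clone labels.
pseudobulkOracle <- function(sim, truth, tp, variantId) {
  s <- getSample(sim$dataset, tp)
  ac <- alleleCounts(s)
  d <- refDepth(ac)[variantId, ] + altDepth(ac)[variantId, ]
  ct <- sim$truth$cells[[tp]]
  zyg <- ampliClone:::cloneZygosityMatrix(truth)
  cn <- ampliClone:::cloneCopyMatrix(truth)
  gene <- variantInfo(ac)[variantId, "gene"]
  m1 <- numeric(nrow(ct)); varP <- numeric(nrow(ct))
  cache <- new.env()
  for (i in seq_len(nrow(ct))) {
    cl <- ct$clone[i]
    zz <- zyg[cl, variantId]; cc <- cn[cl, gene]
    if (ct$doublet[i]) {
      zz <- c(zz, zyg[ct$partner[i], variantId])
      cc <- c(cc, cn[ct$partner[i], gene])
    }
    key <- paste(zz, cc, collapse = "|")
    if (is.null(cache[[key]])) {
      cp <- configCopies(zz, cc)
      cache[[key]] <- adoMoments(cp["alt"], cp["tot"], truth@pAdo,
                                 truth@seqError)
    }
    mm <- cache[[key]]
    m1[i] <- mm["m1"]
    varP[i] <- mm["m2"] - mm["m1"]^2
  }
  D <- sum(d)
  ev <- sum(d * m1) / D
  ## Var(sum alt) = sum d*E[p(1-p)] + d^2 Var(p)   (depths conditioned on)
  vv <- sum(d * (m1 - (varP + m1^2)) + d^2 * varP) / D^2
  list(expected = ev, se = sqrt(vv))
}

## P(called HET | depth d, alt-read prob p) under the three-state caller
## with uniform priors, via the oracle posterior per possible alt count.
hetCallProb <- function(d, p, eps) {
  ks <- 0:d
  ll <- cbind(dbinom(ks, d, eps, log = TRUE),
              dbinom(ks, d, 0.5, log = TRUE),
              dbinom(ks, d, 1 - eps, log = TRUE))
  called <- max.col(ll, ties.method = "first")
  sum(dbinom(ks[called == 2L], d, p))
}

## Adjusted Rand index (used when mclust is unavailable; tests prefer
## mclust::adjustedRandIndex as the independent implementation).
ariIndex <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  expec <- ai * bj / choose(n, 2)
  (sumij - expec) / ((ai + bj) / 2 - expec)
}
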