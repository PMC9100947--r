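#' Build a longitudinal clone-evolution (fish) table
#'
#' Takes one \linkS4class{CloneAssignment} per time point (shared driver
#' set), estimates ADO-corrected clone fractions jointly
#' (\code{\link{estimateCloneFractions}}), takes the union of clone keys
#' across time points (fraction 0 where absent), drops keys never
#' observed with at least \code{minCells} cells at any time point, and
#' infers parent relations: the parent of clone C is the clone whose
#' mutant-variant set is the largest strict subset of C's, ties broken by
#' larger average fraction across time points, then lexicographic key.
#'
#' @param assignments list of \linkS4class{CloneAssignment} (one per time
#'   point, all sharing the driver set).
#' @param months time in months per assignment (default 0,1,2,...).
#' @param labels row labels (default "t1", "t2", ...).
#' @param minCells clone-retention cell floor (default 5).
#' @param correctAdo apply the allele-dropout correction (default TRUE);
#'   when FALSE the raw assigned-cell fractions (renormalized over the
#'   retained clones) are used.
#' @param pAdo optionally fix the dropout rate of the correction.
#' @return A \linkS4class{FishTable}.
#' @export
buildFishTable <- function(assignments, months = NULL, labels = NULL,
                           minCells = 5, correctAdo = TRUE, pAdo = NULL) {
  if (is(assignments, "CloneAssignment")) assignments <- list(assignments)
  stopifnot(length(assignments) >= 1L)
  driverSet <- assignments[[1]]@driverSet
  for (a in assignments)
    if (!identical(a@driverSet, driverSet))
      stopf("assignments use inconsistent driver sets")
  nt <- length(assignments)
  if (is.null(months)) months <- seq_len(nt) - 1
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(nt))
  est <- estimateCloneFractions(assignments, minCells = minCells,
                                pAdo = if (correctAdo) pAdo else 0)
  keys <- est$cloneKeys
  fr <- est$fractions
  raw <- est$rawFractions
  raw[is.na(raw)] <- 0
  rawRe <- raw / pmax(rowSums(raw), .Machine$double.eps)
  if (!correctAdo) fr <- rawRe
  rownames(fr) <- rownames(rawRe) <- labels

  nonWt <- lapply(keys, keyNonWtVariants, driverSet = driverSet)
  avg <- colMeans(fr)
  parents <- rep(NA_character_, length(keys))
  for (i in seq_along(keys)) {
    sizes <- vapply(seq_along(keys), function(j) {
      if (j == i) return(-1L)
      if (all(nonWt[[j]] %in% nonWt[[i]]) &&
          length(nonWt[[j]]) < length(nonWt[[i]]))
        length(nonWt[[j]])
      else -1L
    }, 0L)
    if (all(sizes < 0L)) next
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
      cand <- cand[order(-avg[cand], keys[cand])]
    }
    parents[i] <- keys[cand[1L]]
  }
  genes <- assignments[[1]]@driverGenes
  ## numerical guard: EM fractions sum to 1 up to fp drift
  fr <- fr / rowSums(fr)
  new("FishTable", driverSet = driverSet, cloneKeys = keys,
      cloneLabels = vapply(keys, cloneLabelFromKey, "",
                           driverGenes = genes),
      parents = parents, fractions = fr, rawFractions = rawRe,
      months = as.numeric(months), adoRate = est$pAdo)
}

#' Serialize a fish table to a plain list (for JSON export)
#'
#' @param fish a \linkS4class{FishTable}.
#' @return A list with elements \code{clones} (key, label, parent) and
#'   \code{fractions} (per time point), ready for
#'   \code{jsonlite::write_json}.
#' @export
fishTableAsList <- function(fish) {
  stopifnot(is(fish, "FishTable"))
  list(
    driver_set = as.list(fish@driverSet),
    ado_rate = fish@adoRate,
    clones = lapply(seq_along(fish@cloneKeys), function(i) list(
      key = fish@cloneKeys[i], label = fish@cloneLabels[i],
      parent = if (is.na(fish@parents[i])) NULL else fish@parents[i])),
    months = as.list(fish@months),
    fractions = lapply(seq_len(nrow(fish@fractions)), function(t)
      as.list(setNames(fish@fractions[t, ], fish@cloneKeys))))
}
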