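## Scenario truths used across the tests.  Sizes are kept at desk scale;
## the acceptance tests use the sizes stated in their descriptions.

## WT-only null: one clone, no mutant cells, no CNV.
nullTruth <- function(seed, n = 2000L, meanDepth = 50) {
  amp <- defaultPanel()
  v <- panelVariant(amp, "IDH2", ref = "C", alt = "T")
  simulationTruth(
    clones = list(cloneSpec("WT")),
    variants = v, fractions = matrix(1, 1, 1), amplicons = amp,
    ampliconEfficiency = rep(1, nrow(amp)),
    meanDepth = meanDepth, nCells = n, seed = seed)
}

## WT majority plus one rare HET clone at `frac`, plus an ultra-rare
## second clone expected at ~2 cells.
rareCloneTruth <- function(seed, n = 10000L, frac = 0.008,
                           tinyFrac = 2 / 10000) {
  amp <- defaultPanel()
  v1 <- panelVariant(amp, "GATA2", ref = "G", alt = "A")
  v2 <- panelVariant(amp, "KIT", ref = "A", alt = "T")
  variants <- rbind(v1, v2)
  clones <- list(
    cloneSpec("WT"),
    cloneSpec("rare", setNames("HET", v1$variant_id), parent_id = "WT"),
    cloneSpec("tiny", setNames("HET", v2$variant_id), parent_id = "WT"))
  fr <- matrix(c(1 - frac - tinyFrac, frac, tinyFrac), 1, 3)
  simulationTruth(clones, variants, fr, amp,
                  ampliconEfficiency = rep(1, nrow(amp)),
                  meanDepth = 60, nCells = n, seed = seed)
}

## 20% mutant subclone carrying a one-copy DNMT3A loss; uniform
## amplicon efficiency, 50x mean depth.
cnvLossTruth <- function(seed, n = 2000L, lostCopies = 1L,
                         subcloneFrac = 0.2, meanDepth = 50) {
  amp <- defaultPanel()
  v <- panelVariant(amp, "IDH2", ref = "C", alt = "T")
  clones <- list(
    cloneSpec("WT"),
    cloneSpec("mut", setNames("HET", v$variant_id),
              copyNumber = c(DNMT3A = lostCopies), parent_id = "WT"))
  fr <- matrix(c(1 - subcloneFrac, subcloneFrac), 1, 2)
  simulationTruth(clones, v, fr, amp,
                  ampliconEfficiency = rep(1, nrow(amp)),
                  meanDepth = meanDepth, nCells = n, seed = seed)
}

## Two clean clones with disjoint homozygous variants (for burden
## clustering): the "no noise" planted scenario — no dropout, no
## doublets, depth high enough that sub-floor cells are negligible.
disjointHomTruth <- function(seed, n = 1500L) {
  amp <- defaultPanel()
  v1 <- panelVariant(amp, "GATA2", ref = "G", alt = "A")
  v2 <- panelVariant(amp, "EZH2", ref = "C", alt = "T")
  variants <- rbind(v1, v2)
  clones <- list(
    cloneSpec("A", setNames("HOM", v1$variant_id)),
    cloneSpec("B", setNames("HOM", v2$variant_id)))
  fr <- matrix(c(0.5, 0.5), 1, 2)
  simulationTruth(clones, variants, fr, amp,
                  ampliconEfficiency = rep(1, nrow(amp)),
                  meanDepth = 150, pAdo = 0, doubletRate = 0,
                  nCells = n, seed = seed)
}

## Two independently assorting HET variants (for co-occurrence): clone
## fractions are products of per-variant marginals.
independentPairTruth <- function(seed, n = 4000L, fA = 0.3, fB = 0.2) {
  amp <- defaultPanel()
  vA <- panelVariant(amp, "GATA2", ref = "G", alt = "A")
  vB <- panelVariant(amp, "EZH2", ref = "C", alt = "T")
  variants <- rbind(vA, vB)
  ids <- variants$variant_id
  clones <- list(
    cloneSpec("WT"),
    cloneSpec("A", setNames("HET", ids[1])),
    cloneSpec("B", setNames("HET", ids[2])),
    cloneSpec("AB", setNames(c("HET", "HET"), ids)))
  fr <- matrix(c((1 - fA) * (1 - fB), fA * (1 - fB), (1 - fA) * fB,
                 fA * fB), 1, 4)
  simulationTruth(clones, variants, fr, amp,
                  ampliconEfficiency = rep(1, nrow(amp)),
                  meanDepth = 60, pAdo = 0, seqError = 0.001,
                  doubletRate = 0, nCells = n, seed = seed)
}

## Three clones: diploid WT plus two subclones carrying homozygous
## losses of disjoint genes (for ploidy embedding / clustering).
disjointLossTruth <- function(seed, n = 600L, meanDepth = 50) {
  amp <- defaultPanel()
  vA <- panelVariant(amp, "GATA2", ref = "G", alt = "A")
  vB <- panelVariant(amp, "EZH2", ref = "C", alt = "T")
  variants <- rbind(vA, vB)
  clones <- list(
    cloneSpec("WT"),
    cloneSpec("lossA", setNames("HET", vA$variant_id),
              copyNumber = c(DNMT3A = 0L), parent_id = "WT"),
    cloneSpec("lossB", setNames("HET", vB$variant_id),
              copyNumber = c(TET2 = 0L), parent_id = "WT"))
  fr <- matrix(c(0.34, 0.33, 0.33), 1, 3)
  simulationTruth(clones, variants, fr, amp,
                  ampliconEfficiency = rep(1, nrow(amp)),
                  meanDepth = meanDepth, nCells = n, seed = seed)
}

## Single pure-HET clone (for dropout-expectation checks).
pureHetTruth <- function(seed, n = 1000L, pAdo = 0.08) {
  amp <- defaultPanel()
  v <- panelVariant(amp, "IDH2", ref = "C", alt = "T")
  simulationTruth(
    clones = list(cloneSpec("het", setNames("HET", v$variant_id))),
    variants = v, fractions = matrix(1, 1, 1), amplicons = amp,
    ampliconEfficiency = rep(1, nrow(amp)), meanDepth = 60,
    pAdo = pAdo, doubletRate = 0, nCells = n, seed = seed)
}

## Tiny two-time-point dataset for IO round trips.
tinyDataset <- function(seed = 42L, n = 60L) {
  tr <- defaultTruth(seed)
  tr@nCells <- rep(as.integer(n), length(tr@nCells))
  tr@fractions <- tr@fractions[1:2, , drop = FALSE]
  tr@labels <- tr@labels[1:2]; tr@months <- tr@months[1:2]
  tr@nCells <- tr@nCells[1:2]
  simulateDataset(tr)$dataset
}
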