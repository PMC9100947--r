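gtFor <- function(truth, tp = 1L) {
  sim <- simulateDataset(truth)
  list(sim = sim,
       gt = callGenotypes(getSample(sim$dataset, tp)))
}

test_that("cells map to zygosity-tuple clone keys with GQ gating", {
  tr <- defaultTruth(seed = 13L)
  tr@nCells <- rep(800L, 5L)
  x <- gtFor(tr, 2L)
  drivers <- tr@variants$variant_id
  a <- assignClones(x$gt, drivers, gqMin = 30)
  expect_equal(sum(cloneCounts(a)) + sum(is.na(cloneKeys(a))), 800L)
  ## the double-heterozygous clone key exists and is large at this stage
  expect_true("HET/HET" %in% names(cloneCounts(a)))
  expect_gt(fractions(a)[["HET/HET"]], 0.2)
  ## raising gqMin can only shrink the assigned set
  sizes <- vapply(c(0, 30, 60, 90), function(q)
    sum(!is.na(cloneKeys(assignClones(x$gt, drivers, gqMin = q)))), 0L)
  expect_true(all(diff(sizes) <= 0L))
  expect_error(assignClones(x$gt, character()), "non-empty")
  expect_error(assignClones(x$gt, "chr1:1:A/T"), "not in panel")
})

test_that("an all-WT sample yields a single full-fraction clone", {
  x <- gtFor(nullTruth(seed = 14L, n = 500L))
  a <- assignClones(x$gt, rownames(x$gt))
  expect_equal(names(cloneCounts(a)), "WT")
  expect_equal(unname(fractions(a)[["WT"]]), 1)
  expect_equal(nrow(detectRareClones(a)), 0L)
})

test_that("ADO-corrected fractions recover a simulated trajectory", {
  tr <- defaultTruth(seed = 22L)
  tr@nCells <- rep(2500L, 5L)
  sim <- simulateDataset(tr)
  gts <- lapply(sim$dataset@samples, callGenotypes)
  as <- lapply(gts, assignClones, driverSet = tr@variants$variant_id)
  est <- estimateCloneFractions(as)
  expect_setequal(est$cloneKeys,
                  c("WT/WT", "HET/WT", "HET/HET", "HOM/HET", "HET/HOM"))
  expect_equal(est$pAdo, tr@pAdo, tolerance = 0.25)
  expect_true(all(abs(rowSums(est$fractions) - 1) < 1e-9))
  for (t in seq_len(5)) {
    ct <- sim$truth$cells[[t]]
    draws <- factor(c(ct$clone, ct$partner[ct$doublet]),
                    levels = colnames(tr@fractions))
    realized <- as.numeric(table(draws)) / length(draws)
    keys <- c("WT/WT", "HET/WT", "HET/HET", "HOM/HET", "HET/HOM")
    err <- abs(est$fractions[t, keys] - realized)
    expect_lt(max(err[tr@fractions[t, ] >= 0.03]), 0.03)
  }
})

test_that("spurious HOM keys appear at the analytic dropout rate", {
  tr <- pureHetTruth(seed = 33L, n = 2000L, pAdo = 0.08)
  sim <- simulateDataset(tr)
  gt <- callGenotypes(getSample(sim$dataset, 1L))
  a <- assignClones(gt, rownames(gt), gqMin = 0)
  p <- tr@pAdo
  nAssigned <- sum(cloneCounts(a))
  expected <- p * (1 - p)          # only the ref copy survives
  homs <- cloneCounts(a)[["HOM"]]
  se <- sqrt(expected * (1 - expected) * nAssigned)
  expect_lt(abs(homs - expected * nAssigned), 3 * se)
})

test_that("rare clones are reported above the cell floor only", {
  tr <- rareCloneTruth(seed = 17L, n = 10000L, frac = 0.008)
  sim <- simulateDataset(tr)
  gt <- callGenotypes(getSample(sim$dataset, 1L))
  a <- assignClones(gt, tr@variants$variant_id)
  rare <- detectRareClones(a, minCells = 5, rareFraction = 0.01)
  expect_true("HET/WT" %in% rare$key)        # the 0.8% GATA2 clone
  hit <- rare[rare$key == "HET/WT", ]
  expect_gt(hit$cells, 5)
  expect_lt(hit$fraction, 0.01)
  expect_gt(hit$fraction, 0.004)
  ## the ~2-cell clone stays below the floor and is not reported
  tinyCount <- sum(cloneKeys(a) == "WT/HET", na.rm = TRUE)
  expect_lt(tinyCount, 5)
  expect_false("WT/HET" %in% rare$key)
  ## ordering is by descending fraction
  expect_true(!is.unsorted(rev(rare$fraction)))
})

test_that("co-occurrence counts match independence and nesting structure", {
  tr <- independentPairTruth(seed = 19L, n = 4000L)
  sim <- simulateDataset(tr)
  gt <- callGenotypes(getSample(sim$dataset, 1L))
  tab <- cooccurrenceTable(gt, tr@variants$variant_id, gqMin = 30)
  n <- sum(tab)
  mutA <- sum(tab["HET", ]) / n
  mutB <- sum(tab[, "HET"]) / n
  jointExp <- mutA * mutB * n
  se <- sqrt(n * mutA * mutB * (1 - mutA * mutB))
  expect_lt(abs(tab["HET", "HET"] - jointExp), 3 * se)

  ## perfectly nested clones: no cell mutant at the child variant only
  amp <- defaultPanel()
  vP <- panelVariant(amp, "GATA2", ref = "G", alt = "A")
  vC <- panelVariant(amp, "EZH2", ref = "C", alt = "T")
  nested <- simulationTruth(
    clones = list(
      cloneSpec("WT"),
      cloneSpec("P", setNames("HET", vP$variant_id)),
      cloneSpec("PC", setNames(c("HET", "HET"),
                               c(vP$variant_id, vC$variant_id)),
                parent_id = "P")),
    variants = rbind(vP, vC), fractions = matrix(c(0.5, 0.3, 0.2), 1),
    amplicons = amp, ampliconEfficiency = rep(1, nrow(amp)),
    meanDepth = 60, pAdo = 0, seqError = 0.001, doubletRate = 0,
    nCells = 1500L, seed = 20L)
  simN <- simulateDataset(nested)
  gtN <- callGenotypes(getSample(simN$dataset, 1L))
  tabN <- cooccurrenceTable(gtN, nested@variants$variant_id)
  expect_equal(unname(tabN["WT", "HET"]), 0L)   # child without parent
  expect_error(cooccurrenceTable(gtN, vP$variant_id), "two variants")
  expect_error(cooccurrenceTable(gtN, c(vP$variant_id, "chr1:1:A/T")),
               "not in matrix")
})

test_that("fish tables nest clones by mutant-subset parentage", {
  tr <- defaultTruth(seed = 23L)
  tr@nCells <- rep(1200L, 5L)
  sim <- simulateDataset(tr)
  gts <- lapply(sim$dataset@samples, callGenotypes)
  as <- lapply(gts, assignClones, driverSet = tr@variants$variant_id)
  fish <- buildFishTable(as, months = tr@months, labels = tr@labels)
  expect_s4_class(fish, "FishTable")
  expect_true(all(abs(rowSums(fractions(fish)) - 1) < 1e-9))
  key <- setNames(fish@parents, fish@cloneKeys)
  expect_true(is.na(key[["WT/WT"]]))
  expect_equal(key[["HET/WT"]], "WT/WT")
  expect_equal(key[["HET/HET"]], "HET/WT")
  ## zygosity-only changes do not count as subsets: HOM/HET descends
  ## from the largest strict mutant subset, the single-mutant clone
  expect_equal(key[["HOM/HET"]], "HET/WT")
  ## determinism: identical rebuild gives identical structure
  fish2 <- buildFishTable(as, months = tr@months, labels = tr@labels)
  expect_identical(fractions(fish2), fractions(fish))
  expect_identical(fish2@parents, fish@parents)
})

test_that("fish-table construction rejects inconsistent driver sets", {
  tr <- defaultTruth(seed = 24L)
  tr@nCells <- rep(300L, 5L)
  sim <- simulateDataset(tr)
  gts <- lapply(sim$dataset@samples[1:2], callGenotypes)
  a1 <- assignClones(gts[[1]], tr@variants$variant_id)
  a2 <- assignClones(gts[[2]], tr@variants$variant_id[1])
  expect_error(buildFishTable(list(a1, a2)), "inconsistent")
})

test_that("allele-burden matrices drop, impute and pool as recorded", {
  tr <- defaultTruth(seed = 25L)
  tr@nCells <- rep(100L, 5L)
  sim <- simulateDataset(tr)
  gts <- lapply(sim$dataset@samples[1:2], callGenotypes)
  abm <- alleleBurdenMatrix(gts, labels = c("p1", "p2"))
  expect_equal(nrow(burden(abm)), 200L)
  expect_equal(abm@timePoint, rep(c("p1", "p2"), each = 100L))
  expect_true(all(burden(abm) >= 0 & burden(abm) <= 1))

  ## a variant missing in >50% of cells is dropped
  gt <- gts[[1]]
  v <- assay(gt, "vaf")
  v[2, seq_len(ceiling(ncol(v) * 0.6))] <- NA
  SummarizedExperiment::assay(gt, "vaf") <- v
  abm2 <- alleleBurdenMatrix(gt)
  expect_equal(abm2@droppedVariants, rownames(gt)[2])
  expect_equal(ncol(burden(abm2)), 1L)
})

test_that("density clustering separates clones and labels noise", {
  tr <- disjointHomTruth(seed = 26L, n = 1200L)
  sim <- simulateDataset(tr)
  gt <- callGenotypes(getSample(sim$dataset, 1L))
  abm <- alleleBurdenMatrix(gt)
  labels <- clusterAlleleBurden(abm, eps = 0.3, minSamples = 20)
  truthLab <- sim$truth$cells[[1]]$clone
  expect_equal(length(unique(labels[labels > 0])), 2L)
  expect_gte(ariIndex(labels, truthLab), 0.9)

  ## all cells identical -> one cluster; minSamples > n -> all noise
  same <- matrix(0.5, 60, 3)
  expect_equal(unique(clusterAlleleBurden(same, 0.3, 20)), 1L)
  expect_equal(unique(clusterAlleleBurden(same, 0.3, 100)), 0L)
})
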