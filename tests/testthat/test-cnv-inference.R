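## Shared CNV fixture: 2000 cells, 20% mutant subclone with a one-copy
## DNMT3A loss, 50x mean depth, uniform amplicon efficiency.
cnvFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- cnvLossTruth(seed = 41L, n = 2000L)
      sim <- simulateDataset(tr)
      s <- getSample(sim$dataset, 1L)
      gt <- callGenotypes(s)
      a <- assignClones(gt, tr@variants$variant_id)
      cache <<- list(tr = tr, sim = sim, s = s, gt = gt, a = a)
    }
    cache
  }
})

test_that("dropout amplicons are flagged by zero fraction or depth", {
  tr <- nullTruth(seed = 43L, n = 1000L, meanDepth = 50)
  tr <- injectArtifactAmplicon(tr, "AMP_SRSF2_02", 0.05)
  sim <- simulateDataset(tr)
  am <- ampliconCounts(getSample(sim$dataset, 1L))
  flagged <- flagDropoutAmplicons(am)
  expect_equal(flagged, "AMP_SRSF2_02")

  ## uniform panel -> no artifacts
  tr0 <- nullTruth(seed = 44L, n = 1000L, meanDepth = 50)
  am0 <- ampliconCounts(getSample(simulateDataset(tr0)$dataset, 1L))
  expect_length(flagDropoutAmplicons(am0), 0L)

  ## an all-zero amplicon is always flagged
  cnt <- counts(am0)
  cnt["AMP_WT1_01", ] <- 0L
  am1 <- AmpliconCounts(cnt, ampliconInfo(am0))
  expect_true("AMP_WT1_01" %in% flagDropoutAmplicons(am1))

  expect_warning(
    flagDropoutAmplicons(AmpliconCounts(cnt[, 1:50], ampliconInfo(am0))),
    "only 50 cells")
})

test_that("reference cells are the confidently wild-type population", {
  fx <- cnvFixture()
  ref <- selectReferenceCells(fx$gt, fx$tr@variants$variant_id)
  keys <- setNames(cloneKeys(fx$a), fx$a@barcodes)
  expect_true(all(keys[ref] == "WT"))
  ## roughly the WT clone among genotyped cells
  expect_gt(length(ref) / sum(cloneCounts(fx$a)), 0.68)

  ## an all-mutant sample has no reference population
  trM <- pureHetTruth(seed = 45L, n = 200L)
  gtM <- callGenotypes(getSample(simulateDataset(trM)$dataset, 1L))
  expect_error(selectReferenceCells(gtM, trM@variants$variant_id),
               "too few reference cells")
})

test_that("ploidy normalization anchors reference cells at 2 exactly", {
  fx <- cnvFixture()
  ref <- selectReferenceCells(fx$gt, fx$tr@variants$variant_id)
  plm <- normalizePloidy(ampliconCounts(fx$s), ref)
  pl <- ploidy(plm)
  med <- apply(pl[, referenceCells(plm)], 1L, median)
  expect_true(all(abs(med - 2) < 1e-6))

  ## scale invariance: doubling every count changes nothing
  am2 <- AmpliconCounts(counts(ampliconCounts(fx$s)) * 2L,
                        ampliconInfo(ampliconCounts(fx$s)))
  plm2 <- normalizePloidy(am2, ref, minCellReads = 1000)
  expect_equal(ploidy(plm2), pl, tolerance = 1e-12)

  ## cells matching the reference median profile sit at ploidy 2
  expect_lt(abs(median(pl[, referenceCells(plm)[1]]) - 2), 0.5)
})

test_that("a planted one-copy loss is detected and confirmed", {
  fx <- cnvFixture()
  ref <- selectReferenceCells(fx$gt, fx$tr@variants$variant_id)
  plm <- normalizePloidy(ampliconCounts(fx$s), ref)
  groups <- ampliClone:::cloneGroupsForPloidy(fx$a, colnames(ploidy(plm)))
  cand <- detectCandidateCnvs(plm, groups = groups)
  loss <- cand[cand$gene == "DNMT3A" & cand$group == "HET", ]
  expect_equal(nrow(loss), 1L)
  expect_equal(loss$direction, "loss")
  expect_lt(abs(loss$ploidy - 1), 0.15)
  conf <- confirmCnvs(cand, plm, groups)
  cLoss <- conf[conf$gene == "DNMT3A" & conf$group == "HET", ]
  expect_equal(cLoss$status, "confirmed")
  expect_gte(cLoss$supportingFrac, 0.75)
})

test_that("null data produces no candidate or confirmed calls", {
  tr <- nullTruth(seed = 46L, n = 2000L, meanDepth = 50)
  sim <- simulateDataset(tr)
  s <- getSample(sim$dataset, 1L)
  gt <- callGenotypes(s)
  ref <- selectReferenceCells(gt, tr@variants$variant_id)
  plm <- normalizePloidy(ampliconCounts(s), ref)
  groups <- cnvClusters(plm, seed = 2L)
  cand <- detectCandidateCnvs(plm, groups = groups)
  expect_lte(length(unique(cand$gene)), 1L)  # at most one false gene
  conf <- confirmCnvs(cand, plm, groups)
  expect_equal(sum(conf$status == "confirmed"), 0L)
})

test_that("a loss driven by a minority of amplicons is called artifact", {
  fx <- cnvFixture()
  ref <- selectReferenceCells(fx$gt, fx$tr@variants$variant_id)
  plm <- normalizePloidy(ampliconCounts(fx$s), ref)
  pl <- ploidy(plm)
  ## depress 1 of SRSF2's 3 amplicons in the mutant group only
  groups <- ampliClone:::cloneGroupsForPloidy(fx$a, colnames(pl))
  mut <- names(groups)[!is.na(groups) & groups == "HET"]
  pl["AMP_SRSF2_01", mut] <- pl["AMP_SRSF2_01", mut] * 0.05
  pl["AMP_SRSF2_02", mut] <- pl["AMP_SRSF2_02", mut] * 0.05
  plm2 <- plm
  SummarizedExperiment::assay(plm2, "ploidy") <- pl
  cand <- detectCandidateCnvs(plm2, groups = groups)
  srsf2 <- cand[cand$gene == "SRSF2" & cand$group == "HET", ]
  expect_equal(srsf2$direction, "loss")   # looks like a loss by median
  conf <- confirmCnvs(cand, plm2, groups)
  cSr <- conf[conf$gene == "SRSF2" & conf$group == "HET", ]
  expect_equal(cSr$status, "artifact")    # 2/3 supporting < 0.75
  expect_lt(cSr$supportingFrac, 0.75)
})

test_that("flagged artifact amplicons never reach a confirmed call", {
  tr <- cnvLossTruth(seed = 47L, n = 1500L)
  tr <- injectArtifactAmplicon(tr, "AMP_TET2_03", 0.05)
  sim <- simulateDataset(tr)
  s <- getSample(sim$dataset, 1L)
  gt <- callGenotypes(s)
  artifacts <- flagDropoutAmplicons(ampliconCounts(s))
  expect_true("AMP_TET2_03" %in% artifacts)
  ref <- selectReferenceCells(gt, tr@variants$variant_id)
  plm <- normalizePloidy(ampliconCounts(s), ref, artifacts = artifacts)
  expect_true(all(is.na(ploidy(plm)["AMP_TET2_03", ])))
  groups <- ampliClone:::cloneGroupsForPloidy(
    assignClones(gt, tr@variants$variant_id), colnames(ploidy(plm)))
  conf <- confirmCnvs(detectCandidateCnvs(plm, groups = groups),
                      plm, groups)
  expect_false(any(conf$gene == "TET2" & conf$status == "confirmed"))
  ## the genuine DNMT3A loss is still confirmed alongside
  expect_true(any(conf$gene == "DNMT3A" & conf$status == "confirmed"))
})

test_that("unbiased clustering finds the planted subclone structure", {
  fx <- cnvFixture()
  ref <- selectReferenceCells(fx$gt, fx$tr@variants$variant_id)
  plm <- normalizePloidy(ampliconCounts(fx$s), ref)
  groups <- cnvClusters(plm, seed = 3L)
  truthLab <- sim <- fx$sim$truth$cells[[1]]
  lab <- setNames(truthLab$clone, truthLab$barcode)[names(groups)]
  ## the mutant (DNMT3A-loss) cells should concentrate in one cluster
  tab <- table(groups, lab)
  purity <- max(tab[, "mut"]) / sum(tab[, "mut"])
  expect_gt(purity, 0.8)
  cand <- detectCandidateCnvs(plm, groups = groups)
  expect_true(any(cand$gene == "DNMT3A" & cand$direction == "loss"))
})

test_that("ploidy embedding separates planted groups deterministically", {
  tr <- disjointLossTruth(seed = 51L, n = 600L)
  sim <- simulateDataset(tr)
  s <- getSample(sim$dataset, 1L)
  gt <- callGenotypes(s)
  ref <- selectReferenceCells(gt, tr@variants$variant_id)
  am <- ampliconCounts(s)
  plm <- normalizePloidy(am, ref)
  emb <- embedPloidy(plm, seed = 5L)
  emb2 <- embedPloidy(plm, seed = 5L)
  expect_identical(emb, emb2)
  ct <- sim$truth$cells[[1]]
  lab <- setNames(ct$clone, ct$barcode)[emb$cell]
  keep <- lab %in% c("lossA", "lossB")
  sil <- cluster::silhouette(
    as.integer(factor(lab[keep])),
    dist(cbind(emb$dim1, emb$dim2)[keep, ]))
  expect_gte(mean(sil[, 3]), 0.5)

  ## identical cells collapse to a single point
  cnt <- counts(am)[, 1:60]
  cnt[] <- rep(counts(am)[, 1], 60)
  amI <- AmpliconCounts(cnt, ampliconInfo(am),
                        barcodes = sprintf("c%02d", 1:60))
  plI <- normalizePloidy(amI, sprintf("c%02d", 1:60))
  embI <- embedPloidy(plI, seed = 1L)
  expect_lt(max(abs(c(embI$dim1, embI$dim2))), 1e-8)

  expect_error(embedPloidy(plm[, 1:5]), "at least 10 cells")
  expect_error(embedPloidy(plm[, 1:12], nComponents = 20),
               "fewer cells")
})
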