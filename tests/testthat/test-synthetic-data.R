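test_that("the default truth matches the panel and trajectory design", {
  tr <- defaultTruth(seed = 1L)
  expect_equal(nrow(tr@amplicons), 127L)
  expect_equal(length(unique(tr@amplicons$gene)), 20L)
  expect_true(all(abs(rowSums(tr@fractions) - 1) < 1e-9))
  expect_equal(nrow(tr@fractions), 5L)
  ## dominant WT early, double-mutant expansion, late suppression
  expect_gt(tr@fractions[1, "WT"], 0.9)
  expect_gt(tr@fractions[3, "IDH2het_FLT3het"], tr@fractions[1, 3])
  expect_gt(tr@fractions[5, "WT"], 0.8)
  expect_true(all(tr@fractions[5, -1] > 0))  # nothing fully eradicated

  tr2 <- defaultTruth(seed = 2L)
  expect_identical(tr2@amplicons, tr@amplicons)
  expect_identical(tr2@variants, tr@variants)
  expect_false(identical(tr2@ampliconEfficiency,
                         tr@ampliconEfficiency))
})

test_that("simulation is deterministic and conserves variant reads", {
  tr <- defaultTruth(seed = 9L)
  tr@nCells <- rep(300L, 5L)
  s1 <- simulateDataset(tr)
  s2 <- simulateDataset(tr)
  for (i in 1:5) {
    a1 <- alleleCounts(getSample(s1$dataset, i))
    a2 <- alleleCounts(getSample(s2$dataset, i))
    expect_identical(refDepth(a1), refDepth(a2))
    expect_identical(altDepth(a1), altDepth(a2))
    expect_identical(counts(ampliconCounts(getSample(s1$dataset, i))),
                     counts(ampliconCounts(getSample(s2$dataset, i))))
  }
  expect_identical(s1$truth$cells, s2$truth$cells)

  ## ref+alt at a variant never exceeds the covering amplicon's count
  vamp <- ampliClone:::variantAmpliconIndex(tr@variants, tr@amplicons)
  for (i in 1:2) {
    s <- getSample(s1$dataset, i)
    ac <- alleleCounts(s); am <- counts(ampliconCounts(s))
    for (v in seq_len(nrow(ac))) {
      tot <- refDepth(ac)[v, ] + altDepth(ac)[v, ]
      expect_true(all(tot <= am[vamp[v], ]))
    }
  }
})

test_that("degenerate generators behave as their closed forms dictate", {
  ## single WT clone, no error, no dropout -> zero alt reads everywhere
  tr <- nullTruth(seed = 3L, n = 300L)
  tr@seqError <- 0; tr@pAdo <- 0
  sim <- simulateDataset(tr)
  ac <- alleleCounts(getSample(sim$dataset, 1L))
  expect_true(all(altDepth(ac) == 0L))

  ## single HOM clone -> VAF exactly 1 wherever depth > 0
  amp <- defaultPanel()
  v <- panelVariant(amp, "TP53", ref = "G", alt = "A")
  hom <- simulationTruth(
    clones = list(cloneSpec("hom", setNames("HOM", v$variant_id))),
    variants = v, fractions = matrix(1, 1, 1), amplicons = amp,
    ampliconEfficiency = rep(1, nrow(amp)), meanDepth = 40,
    pAdo = 0, seqError = 0, doubletRate = 0, nCells = 300L, seed = 4L)
  sim <- simulateDataset(hom)
  ac <- alleleCounts(getSample(sim$dataset, 1L))
  d <- refDepth(ac) + altDepth(ac)
  expect_true(all(altDepth(ac)[d > 0] == d[d > 0]))
})

test_that("per-amplicon depth means agree with the analytic expectation", {
  tr <- cnvLossTruth(seed = 15L, n = 1200L, meanDepth = 50)
  sim <- simulateDataset(tr)
  am <- counts(ampliconCounts(getSample(sim$dataset, 1L)))
  ct <- sim$truth$cells[[1]]
  cn <- ampliClone:::cloneCopyMatrix(tr)
  size <- tr@depthDispersion
  for (aid in c("AMP_DNMT3A_01", "AMP_TP53_01", "AMP_IDH2_02")) {
    g <- tr@amplicons$gene[match(aid, tr@amplicons$amplicon_id)]
    partner <- ifelse(ct$doublet, ct$partner, ct$clone)
    copies <- cn[ct$clone, g] + ifelse(ct$doublet, cn[partner, g], 0)
    mu <- 50 * tr@ampliconEfficiency[aid] * copies / 2
    vv <- mu + mu^2 / size
    se <- sqrt(sum(vv)) / length(mu)
    expect_lt(abs(mean(am[aid, ]) - mean(mu)), 3 * se)
  }
})

test_that("pseudobulk VAF matches the closed-form expectation oracle", {
  tr <- defaultTruth(seed = 7L)
  tr@nCells <- rep(1200L, 5L)
  sim <- simulateDataset(tr)
  for (tp in c(2L, 5L)) {
    for (v in tr@variants$variant_id) {
      ora <- pseudobulkOracle(sim, tr, tp, v)
      obs <- pseudobulkVaf(getSample(sim$dataset, tp), v)
      expect_lt(abs(obs - ora$expected), 3 * ora$se)
    }
  }
})

test_that("raising allele dropout depresses observed HET calls", {
  rates <- c(0, 0.08, 0.2)
  hetFrac <- vapply(rates, function(p) {
    sim <- simulateDataset(pureHetTruth(seed = 21L, n = 800L, pAdo = p))
    gt <- callGenotypes(getSample(sim$dataset, 1L))
    z <- zygosity(gt)[1L, ]
    mean(z == "HET")
  }, 0)
  expect_true(all(diff(hetFrac) < 0))
})

test_that("injected artifact amplicons scale depth as specified", {
  tr <- nullTruth(seed = 5L, n = 1500L, meanDepth = 50)
  aid <- "AMP_SRSF2_01"
  low <- injectArtifactAmplicon(tr, aid, efficiency = 0.05)
  sim <- simulateDataset(low)
  am <- counts(ampliconCounts(getSample(sim$dataset, 1L)))
  mu <- 50 * 0.05
  se <- sqrt(sum(rep(mu + mu^2 / tr@depthDispersion, ncol(am)))) /
    ncol(am)
  expect_lt(abs(mean(am[aid, ]) - mu), 3 * se)

  ## efficiency 1 is the identity for a fixed seed
  same <- injectArtifactAmplicon(tr, aid, efficiency = 1)
  expect_identical(counts(ampliconCounts(getSample(
    simulateDataset(same)$dataset, 1L))),
    counts(ampliconCounts(getSample(simulateDataset(tr)$dataset, 1L))))

  expect_error(injectArtifactAmplicon(tr, aid, 0), "positive")
  expect_error(injectArtifactAmplicon(tr, "AMP_NOPE_01", 0.5),
               "unknown amplicon")
})

test_that("truth validation enforces the generative invariants", {
  amp <- defaultPanel()
  v <- panelVariant(amp, "IDH2")
  ## fractions must sum to one
  expect_error(simulationTruth(
    clones = list(cloneSpec("WT")), variants = v,
    fractions = matrix(0.9, 1, 1), amplicons = amp, seed = 1L),
    "sum to 1")
  ## a variant uncovered by the panel is a configuration error
  orphan <- variantTable("chrX:5:C/T", "GATA2")
  expect_error(simulationTruth(
    clones = list(cloneSpec("WT")), variants = orphan,
    fractions = matrix(1, 1, 1), amplicons = amp, seed = 1L),
    "not covered")
  ## parent mutant set must be a subset of the child's
  bad <- list(
    cloneSpec("WT"),
    cloneSpec("A", setNames("HET", v$variant_id)),
    cloneSpec("B", parent_id = "A"))
  expect_error(simulationTruth(
    clones = bad, variants = v, fractions = matrix(1 / 3, 1, 3),
    amplicons = amp, seed = 1L), "subset")
  ## at most one fully wild-type clone
  dupWt <- list(cloneSpec("WT"), cloneSpec("WT2"))
  expect_error(simulationTruth(
    clones = dupWt, variants = v, fractions = matrix(0.5, 1, 2),
    amplicons = amp, seed = 1L), "wild type")
})
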