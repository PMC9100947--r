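## End-to-end orchestration: simulate/read -> genotype -> clones -> CNV
## -> report.  One user seed derives every stage seed; a rerun of an
## identical config reproduces report.json byte-identically (no
## timestamps enter the report).

#' Assemble and validate a pipeline run configuration
#'
#' @param truth a \linkS4class{SimulationTruth} to simulate from
#'   (default \code{\link{defaultTruth}(seed)}), or \code{NULL} when
#'   reading from \code{manifest}.
#' @param manifest manifest path of an on-disk dataset (alternative to
#'   \code{truth}).
#' @param driverSet driver variant_ids; default: all variants of the
#'   truth/panel annotation.
#' @param eps per-read miscall probability used by the genotyper.
#' @param minDepth genotyper MISSING floor.
#' @param gqMin GQ retention threshold.
#' @param minCells clone-retention cell floor.
#' @param rareFraction rare-clone fraction ceiling.
#' @param dbscanEps,dbscanMinSamples allelic-burden DBSCAN parameters.
#' @param dbscanMaxCells seeded subsample cap for the pooled DBSCAN
#'   stage.
#' @param lossMax,gainMin,confirmFrac CNV thresholds.
#' @param zeroFracMax,relDepthMin artifact-amplicon thresholds.
#' @param minRefCells reference-cell floor.
#' @param minCellReads per-cell count floor of the CNV normalization.
#' @param cnvMinCells minimum CNV group size.
#' @param correctAdo apply ADO correction to clone fractions.
#' @param seed run seed; governs simulation and every stochastic stage.
#' @return A validated \code{RunConfig} (list with class attribute).
#' @export
runConfig <- function(truth = NULL, manifest = NULL, driverSet = NULL,
                      eps = 0.01, minDepth = 10, gqMin = 30,
                      minCells = 5, rareFraction = 0.01,
                      dbscanEps = 0.3, dbscanMinSamples = 20,
                      dbscanMaxCells = 8000, lossMax = 1.5,
                      gainMin = 2.5, confirmFrac = 0.75,
                      zeroFracMax = 0.5, relDepthMin = 0.2,
                      minRefCells = 50, minCellReads = 500,
                      cnvMinCells = 20, correctAdo = TRUE, seed = 1L) {
  chk <- function(cond, msg) if (!cond) stopf("invalid config: %s", msg)
  chk(eps >= 0 && eps < 0.5, "eps must lie in [0, 0.5)")
  chk(minDepth >= 1, "minDepth must be >= 1")
  chk(gqMin >= 0 && gqMin <= 99, "gqMin must lie in [0, 99]")
  chk(minCells >= 1, "minCells must be >= 1")
  chk(rareFraction > 0 && rareFraction <= 1,
      "rareFraction must lie in (0, 1]")
  chk(dbscanEps > 0, "dbscanEps must be positive")
  chk(dbscanMinSamples >= 1, "dbscanMinSamples must be >= 1")
  chk(lossMax > 0 && gainMin > lossMax,
      "require 0 < lossMax < gainMin")
  chk(confirmFrac > 0 && confirmFrac <= 1,
      "confirmFrac must lie in (0, 1]")
  chk(zeroFracMax > 0 && zeroFracMax <= 1,
      "zeroFracMax must lie in (0, 1]")
  chk(relDepthMin >= 0, "relDepthMin must be non-negative")
  chk(isCount(seed) || (is.numeric(seed) && seed == round(seed)),
      "seed must be an integer")
  if (is.null(truth) && is.null(manifest))
    truth <- defaultTruth(seed)
  if (!is.null(truth)) stopifnot(is(truth, "SimulationTruth"))
  cfg <- list(truth = truth, manifest = manifest, driverSet = driverSet,
              eps = eps, minDepth = minDepth, gqMin = gqMin,
              minCells = minCells, rareFraction = rareFraction,
              dbscanEps = dbscanEps,
              dbscanMinSamples = dbscanMinSamples,
              dbscanMaxCells = dbscanMaxCells, lossMax = lossMax,
              gainMin = gainMin, confirmFrac = confirmFrac,
              zeroFracMax = zeroFracMax, relDepthMin = relDepthMin,
              minRefCells = minRefCells, minCellReads = minCellReads,
              cnvMinCells = cnvMinCells, correctAdo = correctAdo,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

configEcho <- function(config) {
  keep <- setdiff(names(config), c("truth", "manifest"))
  out <- config[keep]
  out$input <- if (!is.null(config$manifest))
    list(kind = "manifest", path = config$manifest)
  else list(kind = "simulation",
            truthSeed = config$truth@seed,
            nCells = as.list(config$truth@nCells),
            labels = as.list(config$truth@labels))
  out
}

stageStep <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read, per-time-point genotyping, clone assignment
#' and ADO-corrected fish-table construction, rare-clone detection,
#' driver co-occurrence, allelic-burden DBSCAN, artifact-amplicon
#' flagging, reference-cell ploidy normalization, clone-associated and
#' unbiased CNV candidate detection with multi-amplicon confirmation,
#' and a 2-D copy-number embedding.  Any stage failure aborts with the
#' stage named.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir optional output directory; when given, writes
#'   \code{report.json} plus TSV/JSON stage outputs (and
#'   \code{truth.json} for simulated runs).
#' @return The run report (list), invisibly when \code{outDir} is set.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  sim <- NULL
  if (!is.null(config$manifest)) {
    ds <- stageStep("read", readDataset(config$manifest))
  } else {
    sim <- stageStep("simulate", simulateDataset(config$truth))
    ds <- sim$dataset
  }
  labels <- sampleLabels(ds)
  months <- sampleMonths(ds)
  driverSet <- config$driverSet
  if (is.null(driverSet))
    driverSet <- rownames(alleleCounts(getSample(ds, 1L)))

  gts <- stageStep("genotype", lapply(ds@samples, function(s)
    callGenotypes(s, eps = config$eps, minDepth = config$minDepth)))
  names(gts) <- labels

  assignments <- stageStep("clones", lapply(gts, assignClones,
                                            driverSet = driverSet,
                                            gqMin = config$gqMin))
  fish <- stageStep("clones", buildFishTable(
    assignments, months = months, labels = labels,
    minCells = config$minCells, correctAdo = config$correctAdo))
  rare <- stageStep("clones", lapply(assignments, detectRareClones,
                                     minCells = config$minCells,
                                     rareFraction = config$rareFraction))
  cooc <- NULL
  if (length(driverSet) >= 2L) {
    cooc <- stageStep("clones", lapply(gts, function(g) {
      tb <- cooccurrenceTable(g, driverSet, gqMin = config$gqMin)
      df <- as.data.frame(tb, stringsAsFactors = FALSE)
      df[df$Freq > 0, , drop = FALSE]
    }))
  }

  abm <- stageStep("burden", alleleBurdenMatrix(gts, labels = labels))
  bm <- burden(abm)
  dbCells <- seq_len(nrow(bm))
  if (nrow(bm) > config$dbscanMaxCells) {
    set.seed(stageSeed(config$seed, "dbscan-subsample"))
    dbCells <- sort(sample.int(nrow(bm), config$dbscanMaxCells))
  }
  clusters <- stageStep("burden", clusterAlleleBurden(
    bm[dbCells, , drop = FALSE], eps = config$dbscanEps,
    minSamples = config$dbscanMinSamples))

  haveAmp <- !any(vapply(ds@samples,
                         function(s) is.null(s@ampliconCounts), TRUE))
  cnv <- NULL
  if (haveAmp) {
    cnv <- stageStep("cnv", {
      ampList <- lapply(ds@samples, ampliconCounts)
      artifacts <- flagDropoutAmplicons(ampList,
                                        zeroFracMax = config$zeroFracMax,
                                        relDepthMin = config$relDepthMin)
      refCells <- selectReferenceCells(gts, driverSet,
                                       gqMin = config$gqMin,
                                       minRefCells = config$minRefCells,
                                       labels = labels)
      plm <- normalizePloidy(ampList, refCells, artifacts,
                             minCellReads = config$minCellReads,
                             labels = labels)
      cloneGroups <- cloneGroupsForPloidy(assignments,
                                          colnames(ploidy(plm)))
      candClone <- detectCandidateCnvs(plm, groups = cloneGroups,
                                       lossMax = config$lossMax,
                                       gainMin = config$gainMin,
                                       minCells = config$cnvMinCells)
      confClone <- confirmCnvs(candClone, plm, cloneGroups,
                               confirmFrac = config$confirmFrac,
                               lossMax = config$lossMax,
                               gainMin = config$gainMin)
      ubGroups <- cnvClusters(plm, seed = config$seed)
      candUb <- detectCandidateCnvs(plm, groups = ubGroups,
                                    lossMax = config$lossMax,
                                    gainMin = config$gainMin,
                                    minCells = config$cnvMinCells)
      confUb <- confirmCnvs(candUb, plm, ubGroups,
                            confirmFrac = config$confirmFrac,
                            lossMax = config$lossMax,
                            gainMin = config$gainMin)
      emb <- embedPloidy(plm, seed = config$seed)
      tagMode <- function(df, m) {
        df$mode <- rep_len(m, nrow(df))
        df
      }
      list(artifacts = artifacts, referenceCells = refCells,
           ploidy = plm,
           calls = rbind(tagMode(confClone, "clone"),
                         tagMode(confUb, "unbiased")),
           unbiasedGroups = ubGroups, embedding = emb)
    })
  }

  trajVariants <- rownames(alleleCounts(getSample(ds, 1L)))
  traj <- stageStep("report", do.call(rbind, lapply(
    seq_along(ds@samples), function(t) data.frame(
      label = labels[t], months = months[t], variant = trajVariants,
      vaf = vapply(trajVariants, function(v)
        pseudobulkVaf(ds@samples[[t]], v), 0),
      stringsAsFactors = FALSE))))

  perTimePoint <- lapply(seq_along(ds@samples), function(t) {
    a <- assignments[[t]]
    list(label = labels[t], months = months[t],
         nCells = ncol(alleleCounts(ds@samples[[t]])),
         nVariants = nrow(alleleCounts(ds@samples[[t]])),
         nAssigned = sum(!is.na(a@keys)),
         nUnassigned = sum(is.na(a@keys)))
  })

  report <- list(
    package = "ampliClone",
    version = as.character(packageVersion("ampliClone")),
    config = configEcho(config),
    driverSet = as.list(driverSet),
    perTimePoint = perTimePoint,
    fish = fishTableAsList(fish),
    rareClones = lapply(rare, function(df)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))),
    cooccurrence = cooc,
    burden = list(nCells = nrow(bm), nVariants = ncol(bm),
                  dropped = as.list(abm@droppedVariants),
                  subsampled = length(dbCells),
                  clusterSizes = as.list(table(clusters))),
    cnv = if (is.null(cnv)) NULL else list(
      artifactAmplicons = as.list(cnv$artifacts),
      nReferenceCells = length(cnv$referenceCells),
      droppedCells = length(metadata(cnv$ploidy)$droppedCells),
      calls = lapply(seq_len(nrow(cnv$calls)), function(i)
        as.list(cnv$calls[i, ]))),
    vafTrajectories = lapply(seq_len(nrow(traj)), function(i)
      as.list(traj[i, ]))
  )

  result <- list(report = report, dataset = ds, genotypes = gts,
                 assignments = assignments, fish = fish, rare = rare,
                 burden = abm, clusters = clusters, cnv = cnv,
                 trajectories = traj, truth = sim$truth)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", null = "null")
    frm <- fractions(fish)
    writeTsv(data.frame(label = rownames(frm), frm,
                        check.names = FALSE),
             file.path(outDir, "clone_fractions.tsv"))
    writeTsv(traj, file.path(outDir, "vaf_trajectories.tsv"))
    jsonlite::write_json(fishTableAsList(fish),
                         file.path(outDir, "fish_table.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeTsv(data.frame(cell = names(clusters), cluster = clusters),
             file.path(outDir, "clusters.tsv"))
    if (!is.null(cnv)) {
      writeTsv(cnv$calls, file.path(outDir, "cnv_calls.tsv"))
      writeTsv(data.frame(amplicon_id = cnv$artifacts),
               file.path(outDir, "artifacts.tsv"))
      writeTsv(cnv$embedding, file.path(outDir, "embedding.tsv"))
    }
    if (!is.null(sim))
      jsonlite::write_json(sim$truth, file.path(outDir, "truth.json"),
                           auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null", null = "null")
    return(invisible(result))
  }
  result
}

#' Summarize the longitudinal outputs of a run
#'
#' Writes the fish table (JSON) and the per-variant pseudobulk VAF
#' trajectories (TSV) of a finished run for external plotting.
#'
#' @param result a \code{\link{runPipeline}} result.
#' @param outDir output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
summarizeLongitudinal <- function(result, outDir) {
  stopifnot(is.list(result), !is.null(result$fish),
            !is.null(result$trajectories))
  if (length(unique(result$trajectories$label)) < 2L)
    warning("single time point: longitudinal summaries are degenerate",
            call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fishPath <- file.path(outDir, "fish_table.json")
  trajPath <- file.path(outDir, "vaf_trajectories.tsv")
  jsonlite::write_json(fishTableAsList(result$fish), fishPath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeTsv(result$trajectories, trajPath)
  invisible(c(fish = fishPath, trajectories = trajPath))
}
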