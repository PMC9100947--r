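## Synthetic Tapestri-style data generator.  Generative model per cell:
##   clone ~ Categorical(fractions[t, ]); with prob doubletRate a second
##   clone is drawn and the cell's material is the sum of both.
##   depth[cell, amplicon] ~ NegBin(mu = meanDepth * efficiency *
##     copies/2, size = depthDispersion).
##   For each variant (located on its covering amplicon): each allele copy
##   drops independently with prob pAdo; the surviving allele balance b
##   gives the alt-read probability b(1-eps) + (1-b)eps; if no copy
##   survives the alt-read probability is eps.  alt ~ Binom(depth, .),
##   ref = depth - alt, so ref+alt equals the amplicon depth exactly.

#' Specify one clone of a simulation truth
#'
#' @param clone_id unique clone identifier.
#' @param genotypes named character vector \code{variant_id -> zygosity}
#'   ("HET"/"HOM"); unlisted variants are WT.
#' @param copyNumber named integer vector \code{gene -> copies} in 0..4;
#'   unlisted genes are diploid (2).
#' @param parent_id parent clone id or \code{NA} (root).  The parent's
#'   mutant-variant set must be a subset of the child's.
#' @return A clone specification list.
#' @export
cloneSpec <- function(clone_id, genotypes = character(),
                      copyNumber = integer(), parent_id = NA_character_) {
  if (length(genotypes) && !all(genotypes %in% c("WT", "HET", "HOM")))
    stopf("genotypes must be WT, HET or HOM")
  genotypes <- genotypes[genotypes != "WT"]
  list(clone_id = as.character(clone_id), genotypes = genotypes,
       copyNumber = setNames(as.integer(copyNumber), names(copyNumber)),
       parent_id = as.character(parent_id))
}

## The 20-gene / 127-amplicon AML-style panel.  Loci approximate hg19
## gene positions; IDH2 and FLT3 are anchored so that the two default
## driver variants fall inside an amplicon.
panelLayout <- function() {
  data.frame(
    gene = c("IDH2", "FLT3", "DNMT3A", "TET2", "GATA2", "EZH2", "KRAS",
             "KIT", "ASXL1", "SRSF2", "IDH1", "NPM1", "TP53", "RUNX1",
             "SF3B1", "NRAS", "JAK2", "CEBPA", "WT1", "PTPN11"),
    chrom = c("chr15", "chr13", "chr2", "chr4", "chr3", "chr7", "chr12",
              "chr4", "chr20", "chr17", "chr2", "chr5", "chr17", "chr21",
              "chr2", "chr1", "chr9", "chr19", "chr11", "chr12"),
    start = c(90631500L, 28607500L, 25457000L, 106155000L, 128199800L,
              148504400L, 25378500L, 55569500L, 30946000L, 74732000L,
              209101000L, 170814000L, 7572000L, 36160000L, 198256000L,
              115256000L, 5021000L, 33792200L, 32409300L, 112856000L),
    nAmplicons = c(6L, 12L, 11L, 11L, 6L, 9L, 5L, 8L, 8L, 3L, 4L, 4L,
                   6L, 6L, 6L, 4L, 5L, 3L, 4L, 6L),
    stringsAsFactors = FALSE)
}

#' The default 20-gene / 127-amplicon panel
#'
#' @return An \code{\link{ampliconTable}} with 127 amplicons over 20
#'   myeloid genes (240 bp amplicons tiled with 60 bp gaps).
#' @export
defaultPanel <- function() {
  lay <- panelLayout()
  rows <- lapply(seq_len(nrow(lay)), function(i) {
    k <- lay$nAmplicons[i]
    start <- lay$start[i] + (seq_len(k) - 1L) * 300L
    data.frame(amplicon_id = sprintf("AMP_%s_%02d", lay$gene[i],
                                     seq_len(k)),
               gene = lay$gene[i], chrom = lay$chrom[i],
               start = start, end = start + 239L,
               stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, rows)
  ampliconTable(a$amplicon_id, a$gene, a$chrom, a$start, a$end)
}

#' Construct a variant inside a panel amplicon
#'
#' Convenience for building simulation scenarios: places a SNV (or
#' insertion) at the midpoint of the chosen amplicon of a gene.
#'
#' @param amplicons an \code{\link{ampliconTable}}.
#' @param gene gene symbol.
#' @param which which amplicon of the gene (default 1).
#' @param ref,alt alleles (default C>T SNV).
#' @param protein_change optional annotation.
#' @param class variant class, inferred when NULL.
#' @return One-row \code{\link{variantTable}}.
#' @export
panelVariant <- function(amplicons, gene, which = 1L, ref = "C",
                         alt = "T", protein_change = NA_character_,
                         class = NULL) {
  rows <- amplicons[amplicons$gene == gene, , drop = FALSE]
  if (nrow(rows) < which)
    stopf("gene %s has no amplicon %d", gene, which)
  pos <- (rows$start[which] + rows$end[which]) %/% 2L
  id <- sprintf("%s:%d:%s/%s", rows$chrom[which], pos, ref, alt)
  variantTable(id, gene, protein_change, class)
}

#' Assemble a validated simulation truth
#'
#' @param clones list of \code{\link{cloneSpec}} entries.
#' @param variants a \code{\link{variantTable}} of the simulated variants
#'   (each must be covered by an amplicon).
#' @param fractions time point x clone matrix of clone fractions (rows sum
#'   to 1).
#' @param amplicons an \code{\link{ampliconTable}}; default
#'   \code{\link{defaultPanel}()}.
#' @param labels,months time-point labels and months from diagnosis.
#' @param ampliconEfficiency per-amplicon positive multiplier; by default
#'   sampled log-normally (sdlog 0.65, mean 1) from \code{seed} to emulate
#'   the wide per-amplicon coverage spread of real panels.
#' @param meanDepth mean per-cell per-amplicon depth at efficiency 1
#'   (default 120).
#' @param depthDispersion negative-binomial size parameter (default 3).
#' @param pAdo allele-dropout probability per allele copy (default 0.08).
#' @param seqError per-read miscall probability (default 0.01).
#' @param doubletRate doublet probability (default 0.03).
#' @param nCells cells per time point (recycled).
#' @param seed integer seed.
#' @return A \linkS4class{SimulationTruth}.
#' @export
simulationTruth <- function(clones, variants, fractions,
                            amplicons = defaultPanel(),
                            labels = NULL, months = NULL,
                            ampliconEfficiency = NULL,
                            meanDepth = 120, depthDispersion = 3,
                            pAdo = 0.08, seqError = 0.01,
                            doubletRate = 0.03, nCells = 5000L,
                            seed = 1L) {
  fractions <- as.matrix(fractions)
  nt <- nrow(fractions)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(nt))
  if (is.null(months)) months <- seq_len(nt) - 1
  if (is.null(ampliconEfficiency)) {
    set.seed(stageSeed(seed, "efficiency"))
    sdlog <- 0.65
    ampliconEfficiency <- rlnorm(nrow(amplicons), -sdlog^2 / 2, sdlog)
  }
  names(ampliconEfficiency) <- amplicons$amplicon_id
  colnames(fractions) <- vapply(clones, `[[`, "", "clone_id")
  rownames(fractions) <- labels
  variantAmpliconIndex(variants, amplicons)   # coverage is a hard error
  obj <- new("SimulationTruth", clones = clones, variants = variants,
             amplicons = amplicons, fractions = fractions,
             labels = as.character(labels), months = as.numeric(months),
             ampliconEfficiency = ampliconEfficiency,
             meanDepth = meanDepth, depthDispersion = depthDispersion,
             pAdo = pAdo, seqError = seqError,
             doubletRate = doubletRate,
             nCells = rep_len(as.integer(nCells), nt),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' The default simulation truth: a five-time-point serial AML/MDS course
#'
#' Models a patient whose marrow is dominated by a wild-type clone during
#' initial therapy, expands a double-heterozygous IDH2/FLT3-ITD clone at
#' transformation together with minor homozygous subclones, and collapses
#' back to wild-type dominance under late FLT3 inhibition without any
#' mutant clone being fully eradicated.  Drivers: IDH2 p.R140H
#' (chr15:90631934:C/T) and a FLT3 internal tandem duplication
#' (chr13:28608262:/CTGAAATCAACGTAGAAG).  The two mutant-expanded clones
#' additionally carry a one-copy DNMT3A loss.
#'
#' @param seed integer seed; fixes the sampled per-amplicon efficiencies
#'   and all downstream sampling.
#' @return A \linkS4class{SimulationTruth} over the
#'   \code{\link{defaultPanel}} (20 genes, 127 amplicons), 5 time points,
#'   5000 cells each.
#' @export
defaultTruth <- function(seed = 1L) {
  amplicons <- defaultPanel()
  idh2 <- "chr15:90631934:C/T"
  flt3 <- "chr13:28608262:/CTGAAATCAACGTAGAAG"
  variants <- variantTable(c(idh2, flt3), c("IDH2", "FLT3"),
                           c("p.R140H", NA), c("SNV", "ITD"))
  clones <- list(
    cloneSpec("WT"),
    cloneSpec("IDH2het", setNames("HET", idh2), parent_id = "WT"),
    cloneSpec("IDH2het_FLT3het",
              setNames(c("HET", "HET"), c(idh2, flt3)),
              copyNumber = c(DNMT3A = 1L), parent_id = "IDH2het"),
    cloneSpec("IDH2hom_FLT3het",
              setNames(c("HOM", "HET"), c(idh2, flt3)),
              copyNumber = c(DNMT3A = 1L),
              parent_id = "IDH2het_FLT3het"),
    cloneSpec("IDH2het_FLT3hom",
              setNames(c("HET", "HOM"), c(idh2, flt3)),
              copyNumber = c(DNMT3A = 1L),
              parent_id = "IDH2het_FLT3het"))
  fractions <- rbind(
    c(0.94, 0.05, 0.01, 0.00, 0.00),
    c(0.30, 0.25, 0.35, 0.05, 0.05),
    c(0.25, 0.20, 0.35, 0.08, 0.12),
    c(0.30, 0.22, 0.28, 0.08, 0.12),
    c(0.85, 0.08, 0.04, 0.01, 0.02))
  simulationTruth(clones, variants, fractions, amplicons,
                  labels = c("m04", "m18", "m21", "m22", "m25"),
                  months = c(4, 18, 21, 22, 25), seed = seed)
}

#' Replace one amplicon's PCR efficiency
#'
#' Emulates a low-efficiency artifact amplicon (the mechanism behind
#' apparent whole-amplicon dropouts): the returned truth is a copy with
#' the chosen amplicon's depth multiplier replaced.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param ampliconId amplicon to modify.
#' @param efficiency new positive multiplier.
#' @return A modified \linkS4class{SimulationTruth}.
#' @export
injectArtifactAmplicon <- function(truth, ampliconId, efficiency) {
  stopifnot(is(truth, "SimulationTruth"))
  if (!ampliconId %in% truth@amplicons$amplicon_id)
    stopf("unknown amplicon id '%s'", ampliconId)
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 0)
    stopf("efficiency must be a single positive number")
  truth@ampliconEfficiency[ampliconId] <- efficiency
  validObject(truth)
  truth
}

## Per-clone zygosity matrix (clones x variants) and copy-number matrix
## (clones x genes) used by both the generator and the analytic oracles.
cloneZygosityMatrix <- function(truth) {
  ids <- vapply(truth@clones, `[[`, "", "clone_id")
  z <- matrix("WT", length(ids), nrow(truth@variants),
              dimnames = list(ids, truth@variants$variant_id))
  for (cl in truth@clones)
    if (length(cl$genotypes))
      z[cl$clone_id, names(cl$genotypes)] <- unname(cl$genotypes)
  z
}

cloneCopyMatrix <- function(truth) {
  ids <- vapply(truth@clones, `[[`, "", "clone_id")
  genes <- unique(truth@amplicons$gene)
  cn <- matrix(2L, length(ids), length(genes),
               dimnames = list(ids, genes))
  for (cl in truth@clones)
    if (length(cl$copyNumber)) {
      g <- intersect(names(cl$copyNumber), genes)
      cn[cl$clone_id, g] <- cl$copyNumber[g]
    }
  cn
}

## Allele copies (alt, total) implied by a zygosity on a local copy number.
## HET = one mutated parental lineage: alt = max(1, round(cn/2)) for cn>=1.
alleleCopies <- function(zyg, cn) {
  alt <- integer(length(zyg))
  alt[zyg == "HOM"] <- cn[zyg == "HOM"]
  het <- zyg == "HET" & cn >= 1L
  alt[het] <- pmax(1L, as.integer(round(cn[het] / 2)))
  cbind(alt = alt, total = as.integer(cn))
}

#' Simulate a serial dataset from a simulation truth
#'
#' Deterministic for a fixed truth (including its seed): clone identity,
#' doublet status, per-amplicon negative-binomial depths and per-variant
#' allele-dropout / sequencing-error read draws are all derived from
#' \code{truth@seed}.  Doublets are unlabeled in the returned dataset;
#' the truth sidecar records every cell's clone (and doublet partner).
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @return A list with elements \code{dataset}
#'   (\linkS4class{ScAmpliconDataset}) and \code{truth} (sidecar list:
#'   per-cell clone labels per time point plus all generative
#'   parameters).
#' @export
simulateDataset <- function(truth) {
  stopifnot(is(truth, "SimulationTruth"))
  validObject(truth)
  amp <- truth@amplicons
  vIdx <- variantAmpliconIndex(truth@variants, amp)
  zyg <- cloneZygosityMatrix(truth)
  cn <- cloneCopyMatrix(truth)
  geneOfAmp <- amp$gene
  eff <- truth@ampliconEfficiency
  eps <- truth@seqError
  pado <- truth@pAdo
  K <- nrow(zyg)
  cloneIds <- rownames(zyg)
  samples <- vector("list", nrow(truth@fractions))
  cellTruth <- vector("list", nrow(truth@fractions))
  set.seed(stageSeed(truth@seed, "simulate"))
  for (t in seq_len(nrow(truth@fractions))) {
    n <- truth@nCells[t]
    lab <- truth@labels[t]
    frac <- truth@fractions[t, ]
    ci <- sample.int(K, n, replace = TRUE, prob = frac)
    isDbl <- runif(n) < truth@doubletRate
    cj <- sample.int(K, n, replace = TRUE, prob = frac)  # partner draw
    cj[!isDbl] <- NA_integer_
    barcodes <- sprintf("%s_cell%05d", lab, seq_len(n))

    ## per-cell per-gene copies (doublets: material of both clones)
    copies <- cn[ci, , drop = FALSE]
    dbl <- which(isDbl)
    if (length(dbl))
      copies[dbl, ] <- copies[dbl, , drop = FALSE] +
        cn[cj[dbl], , drop = FALSE]
    ## depth: NegBin with mu = meanDepth * eff * copies/2 (cells x amps);
    ## doublets carry the material of both components, hence ~2x depth

    mu <- truth@meanDepth *
      sweep(copies[, geneOfAmp, drop = FALSE] / 2, 2L, eff, "*")
    depth <- matrix(rnbinom(n * nrow(amp), size = truth@depthDispersion,
                            mu = as.vector(mu)), n, nrow(amp))
    colnames(depth) <- amp$amplicon_id

    ## variants: allele copies -> ADO -> binomial reads
    nv <- nrow(truth@variants)
    altReads <- matrix(0L, n, nv)
    refReads <- matrix(0L, n, nv)
    for (v in seq_len(nv)) {
      vid <- truth@variants$variant_id[v]
      g <- truth@variants$gene[v]
      ac1 <- alleleCopies(zyg[ci, vid], cn[cbind(ci, match(g, colnames(cn)))])
      alt0 <- ac1[, "alt"]; tot0 <- ac1[, "total"]
      if (length(dbl)) {
        ac2 <- alleleCopies(zyg[cj[dbl], vid],
                            cn[cbind(cj[dbl], match(g, colnames(cn)))])
        alt0[dbl] <- alt0[dbl] + ac2[, "alt"]
        tot0[dbl] <- tot0[dbl] + ac2[, "total"]
      }
      survAlt <- rbinom(n, alt0, 1 - pado)
      survTot <- survAlt + rbinom(n, tot0 - alt0, 1 - pado)
      b <- ifelse(survTot > 0, survAlt / survTot, 0)
      pEff <- b * (1 - 2 * eps) + eps
      d <- depth[, vIdx[v]]
      altReads[, v] <- rbinom(n, d, pEff)
      refReads[, v] <- d - altReads[, v]
    }
    ac <- CellAlleleCounts(t(refReads), t(altReads), truth@variants,
                           barcodes = barcodes)
    am <- AmpliconCounts(t(depth), amp, barcodes = barcodes)
    samples[[t]] <- TimePointSample(lab, truth@months[t], ac, am)
    cellTruth[[t]] <- data.frame(
      barcode = barcodes, clone = cloneIds[ci],
      doublet = isDbl,
      partner = ifelse(isDbl, cloneIds[cj], NA_character_),
      stringsAsFactors = FALSE)
  }
  names(cellTruth) <- truth@labels
  sidecar <- list(
    cells = cellTruth,
    parameters = list(
      meanDepth = truth@meanDepth,
      depthDispersion = truth@depthDispersion, pAdo = truth@pAdo,
      seqError = truth@seqError, doubletRate = truth@doubletRate,
      nCells = truth@nCells, seed = truth@seed,
      ampliconEfficiency = as.list(truth@ampliconEfficiency)),
    clones = truth@clones,
    fractions = truth@fractions)
  list(dataset = ScAmpliconDataset(samples,
                                   panelGenes = unique(amp$gene)),
       truth = sidecar)
}
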