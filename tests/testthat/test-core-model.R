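test_that("variant identifiers parse per the panel notation", {
  p <- parseVariantId("chr15:90631934:C/T")
  expect_equal(p$chrom, "chr15")
  expect_equal(p$pos, 90631934L)
  expect_equal(p$ref, "C")
  expect_equal(p$alt, "T")

  itd <- variantTable("chr13:28608262:/CTGAAATCAACGTAGAAG", "FLT3",
                      class = "ITD")
  expect_equal(itd$class, "ITD")
  expect_equal(itd$ref, "")
  expect_gte(nchar(itd$alt), 3)

  expect_error(parseVariantId("chr1:notanumber:C/T"), "malformed")
  expect_error(variantTable("chr1:0:C/T", "G"), ">= 1")
  expect_error(variantTable("chr1:5:C/C", "G"), "differ")
  ## ITD requires an empty ref and a real insertion
  expect_error(variantTable("chr1:5:C/TTTT", "G", class = "ITD"), "ITD")
  expect_error(variantTable("chr1:5:/TT", "G", class = "ITD"), "ITD")
  expect_error(variantTable(rep("chr1:5:C/T", 2), "G"), "duplicate")
})

test_that("container constructors reject invariant violations", {
  v <- variantTable(c("chr1:100:A/G", "chr1:200:C/T"), "GENE1")
  ref <- matrix(5L, 2, 3); alt <- matrix(1L, 2, 3)
  bc <- c("c1", "c2", "c3")
  expect_s4_class(CellAlleleCounts(ref, alt, v, bc), "CellAlleleCounts")

  expect_error(CellAlleleCounts(ref[, 1:2], alt, v, bc), "differ")
  expect_error(CellAlleleCounts(ref, alt, v, c("c1", "c1", "c3")),
               "unique")
  expect_error(CellAlleleCounts(ref, alt, v, bc[1:2]), "mismatch")
  expect_error(CellAlleleCounts(-ref, alt, v, bc), "negative")

  a <- ampliconTable(c("a1", "a2"), "GENE1", "chr1", c(1, 300),
                     c(200, 500))
  expect_error(ampliconTable("a1", "G", "chr1", 10, 5), "start <= end")
  expect_error(ampliconTable(c("a1", "a1"), "G", "chr1", c(1, 2),
                             c(5, 6)), "duplicate")
  cnt <- matrix(3L, 2, 3)
  expect_s4_class(AmpliconCounts(cnt, a, bc), "AmpliconCounts")

  ac <- CellAlleleCounts(ref, alt, v, bc)
  am <- AmpliconCounts(cnt, a, c("c1", "c2", "cX"))
  expect_error(validObject(TimePointSample("t1", 0, ac, am)),
               "barcode sets differ")
  expect_error(TimePointSample("t1", -1, ac), "non-negative")

  s1 <- TimePointSample("t1", 0, ac)
  s2 <- TimePointSample("t1", 3, ac)
  expect_error(validObject(new("ScAmpliconDataset", panelGenes = "G",
                               samples = list(s1, s2))), "unique")
  expect_error(ScAmpliconDataset(list()), "at least one")
})

test_that("datasets round-trip exactly through the interchange format", {
  ds <- tinyDataset(seed = 42L, n = 50L)
  for (fmt in c("mtx", "tsv")) {
    dir <- withr::local_tempdir()
    man <- writeDataset(ds, dir, format = fmt)
    ds2 <- readDataset(man)
    expect_equal(sampleLabels(ds2), sampleLabels(ds))
    expect_equal(sampleMonths(ds2), sampleMonths(ds))
    expect_identical(sort(ds2@panelGenes), sort(ds@panelGenes))
    for (i in seq_along(ds@samples)) {
      a1 <- alleleCounts(getSample(ds, i))
      a2 <- alleleCounts(getSample(ds2, i))
      expect_identical(refDepth(a2), refDepth(a1))
      expect_identical(altDepth(a2), altDepth(a1))
      expect_equal(variantInfo(a2), variantInfo(a1))
      m1 <- ampliconCounts(getSample(ds, i))
      m2 <- ampliconCounts(getSample(ds2, i))
      expect_identical(counts(m2), counts(m1))
    }
  }
})

test_that("a dataset without amplicon counts round-trips the absence", {
  ds <- tinyDataset(seed = 5L, n = 40L)
  ds@samples <- lapply(ds@samples, function(s) {
    s@ampliconCounts <- NULL
    s
  })
  dir <- withr::local_tempdir()
  man <- writeDataset(ds, dir)
  txt <- readLines(man)
  expect_false(any(grepl("amplicon_counts", txt)))
  ds2 <- readDataset(man)
  expect_true(all(vapply(ds2@samples,
                         function(s) is.null(s@ampliconCounts), TRUE)))
})

test_that("manifest reading fails loudly on corrupted inputs", {
  ds <- tinyDataset(seed = 6L, n = 30L)
  dir <- withr::local_tempdir()
  man <- writeDataset(ds, dir)

  ## remove one barcode -> dimension mismatch naming the cell axis
  bcPath <- file.path(dir, sampleLabels(ds)[1], "barcodes.tsv")
  bc <- readLines(bcPath)
  writeLines(bc[-length(bc)], bcPath)
  expect_error(readDataset(man), "dimension mismatch")

  ## duplicate barcode
  writeLines(c(bc[-length(bc)], bc[2]), bcPath)
  expect_error(readDataset(man), "duplicate barcode")
  writeLines(bc, bcPath)

  ## missing file -> I/O error naming the path
  mtx <- file.path(dir, sampleLabels(ds)[1], "alt_depth.mtx")
  file.remove(mtx)
  expect_error(readDataset(man), "alt_depth.mtx")
  expect_error(readDataset(file.path(dir, "nope.yaml")), "not found")
})

writeTestVcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr15>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "cellA", "cellB", "cellC", sep = "\t"),
    paste("chr15", "90631934", ".", "C", "T", ".", "PASS", ".", "GT:AD",
          "0/0:10,0", "0/1:6,5", "1/1:0,12", sep = "\t"),
    paste("chr15", "90632000", ".", "C", "T,G", ".", "PASS", ".",
          "GT:AD", "0/1:8,2,3", "./.:.", "0/0:5,0,0", sep = "\t"))
  writeLines(lines, path)
  path
}

test_that("VCF allele depths are transcribed, split and conserved", {
  vcf <- writeTestVcf(withr::local_tempfile(fileext = ".vcf"))
  ac <- readVcfAlleleDepths(vcf)
  expect_equal(colnames(ac), c("cellA", "cellB", "cellC"))
  expect_equal(rownames(ac),
               c("chr15:90631934:C/T", "chr15:90632000:C/T",
                 "chr15:90632000:C/G"))
  ## direct field transcription
  expect_equal(unname(altDepth(ac)["chr15:90631934:C/T", ]),
               c(0L, 5L, 12L))
  expect_equal(unname(refDepth(ac)["chr15:90631934:C/T", ]),
               c(10L, 6L, 0L))
  ## multi-allelic split: shared REF depth, per-ALT alt depth
  expect_equal(unname(refDepth(ac)["chr15:90632000:C/T", "cellA"]), 8L)
  expect_equal(unname(altDepth(ac)["chr15:90632000:C/T", "cellA"]), 2L)
  expect_equal(unname(altDepth(ac)["chr15:90632000:C/G", "cellA"]), 3L)
  ## missing AD -> both depths zero
  expect_equal(unname(refDepth(ac)["chr15:90632000:C/T", "cellB"]), 0L)
  expect_equal(unname(altDepth(ac)["chr15:90632000:C/T", "cellB"]), 0L)
  ## conservation: per split column, ref+alt never exceeds the AD total
  adTotals <- c(cellA = 13, cellB = 0, cellC = 5)
  for (v in c("chr15:90632000:C/T", "chr15:90632000:C/G")) {
    tot <- refDepth(ac)[v, ] + altDepth(ac)[v, ]
    expect_true(all(tot <= adTotals))
  }
})

test_that("VCFs without AD are rejected as unsupported", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "cellA", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", ".", ".", "GT", "0/1",
          sep = "\t")), path)
  expect_error(readVcfAlleleDepths(path), "AD")
})
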