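test_that("GMT parsing handles the canonical collection, round trips, and rejects malformed input", {
  genes <- sprintf("G%03d", 1:500)
  sc <- makeImmuneSignatures(genes, size = 10)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  cats <- withr::local_tempfile(fileext = ".tsv")
  writeGeneSets(sc, gmt, cats)
  rd <- readGeneSets(gmt, cats)
  expect_identical(geneSets(rd), geneSets(sc))
  expect_identical(signatureCategory(rd), signatureCategory(sc))
  tab <- table(signatureCategory(rd))
  expect_equal(unname(tab[c("adaptive", "innate", "other")]),
               c(11L, 12L, 3L), ignore_attr = TRUE)
  # identical on re-read: no ordering nondeterminism
  expect_identical(geneSets(readGeneSets(gmt, cats)), geneSets(rd))

  one <- withr::local_tempfile(fileext = ".gmt")
  writeLines("T_cells\tdesc\tCD8A\tCD3E", one)
  expect_identical(geneSets(readGeneSets(one))$T_cells, c("CD8A", "CD3E"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tdesc\tA\tB", "empty\tdesc"), bad)
  expect_error(readGeneSets(bad), "line 2")
  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("s\td\tA", "s\td\tB"), dup)
  expect_error(readGeneSets(dup), "duplicate")
})

test_that("expression TSV reading enforces invariants and collapses duplicates by max", {
  expr <- randomExprMatrix(3, 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(expr, f)
  rd <- readExpressionMatrix(f)
  expect_equal(rd, expr, tolerance = 1e-12)

  dupf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "gA\t1\t5", "gA\t3\t2", "gB\t4\t4"), dupf)
  expect_warning(m <- readExpressionMatrix(dupf), "duplicated")
  expect_equal(m["gA", ], c(s1 = 3, s2 = 5))

  naf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "gA\tNA\t5", "gB\t1\t2"), naf)
  expect_error(readExpressionMatrix(naf), "non-numeric")
  negf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "gA\t-1\t5", "gB\t1\t2"), negf)
  expect_error(readExpressionMatrix(negf), "negative")
})

test_that("SEG and clinical readers validate, normalize stages and round trip", {
  seg <- data.frame(sample = "S1", chrom = "chr1", start = c(100L, 301L),
                    end = c(300L, 500L), log2_ratio = c(-1.5, 0.2),
                    n_probes = c(30L, 40L), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".seg")
  writeSegTable(seg, f)
  expect_equal(readSegTable(f), seg)
  bad <- seg; bad$start[2] <- 250L
  fb <- withr::local_tempfile(fileext = ".seg")
  writeSegTable(bad, fb)
  expect_error(readSegTable(fb), "overlap")

  clin <- data.frame(sample = c("S1", "S2"), histology = c("ADC", "SQCC"),
                     age = c(60L, 70L), sex = c("F", "M"),
                     stage = c("IIIA", "IB"),
                     smoking = c("smoker", "non-smoker"),
                     os_days = c(100, 900), os_event = c(1L, 0L),
                     treatment = "surgery_only", stringsAsFactors = FALSE)
  fc <- withr::local_tempfile(fileext = ".tsv")
  writeClinicalTable(clin, fc)
  rd <- readClinicalTable(fc)
  expect_equal(rd$stage, c("III", "I"))
  bad2 <- clin; bad2$os_days[1] <- -5
  writeClinicalTable(bad2, fc)
  expect_error(readClinicalTable(fc), "os_days")
  bad3 <- clin; bad3$histology[1] <- "SCLC"
  writeClinicalTable(bad3, fc)
  expect_error(readClinicalTable(fc), "histology")
})

test_that("VCF round trip preserves calls; records lacking depth fall back to zero reads", {
  calls <- data.frame(
    sample_id = "S1", chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 50L), ref = c("C", "G", "T"), alt = c("A", "T", "C"),
    caller_id = "mutA", supporting_reads = c(12L, 7L, 30L),
    effect_class = c("nonsynonymous", "synonymous", "UTR"),
    popdb_1000g = c(FALSE, TRUE, FALSE), popdb_exac = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVariantCalls(calls, f)
  rd <- readVariantCalls(f, "mutA")
  ord <- order(calls$chrom, calls$pos)
  expect_equal(rd[order(rd$chrom, rd$pos), ], calls[ord, ],
               ignore_attr = TRUE)

  # union across two callers with one shared record
  f2 <- withr::local_tempfile(fileext = ".vcf")
  calls2 <- calls
  calls2$caller_id <- "mutB"
  calls2$pos <- c(100L, 999L, 888L)  # first record shared with mutA
  writeVariantCalls(calls2, f2)
  both <- readVariantCalls(c(f, f2), c("mutA", "mutB"))
  expect_equal(nrow(both), 6L)

  noad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S9", sep = "\t"),
               paste("chr1", "77", ".", "C", "T", ".", "PASS", "EFF=UTR",
                     "GT", "0/1", sep = "\t")), noad)
  expect_warning(v <- readVariantCalls(noad, "mutC"), "supporting_reads")
  expect_equal(v$supporting_reads, 0L)
  expect_equal(v$effect_class, "UTR")
})

test_that("run configuration carries the published defaults and accepts YAML overrides", {
  cfg <- profilerConfig()
  expect_equal(cfg$qThreshold, 0.1)
  expect_equal(cfg$minReads, 8L)
  expect_equal(cfg$fusionThreshold, 9)
  expect_equal(cfg$censorHorizon, 1200)
  expect_equal(cfg$ssgseaAlpha, 0.25)
  expect_error(profilerConfig(nope = 1), "unknown")
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("minReads: 10", "targetMb: 45.5"), y)
  cy <- readProfilerConfig(y)
  expect_equal(cy$minReads, 10)
  expect_equal(cy$targetMb, 45.5)
  expect_equal(cy$qThreshold, 0.1)
})
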