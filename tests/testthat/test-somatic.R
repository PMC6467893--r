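mkCall <- function(sample = "S1", chrom = "chr1", pos = 100L, ref = "C",
                   alt = "A", caller = "mutA", reads = 20L,
                   eff = "nonsynonymous", kg = FALSE, exac = FALSE) {
  data.frame(sample_id = sample, chrom = chrom, pos = pos, ref = ref,
             alt = alt, caller_id = caller, supporting_reads = reads,
             effect_class = eff, popdb_1000g = kg, popdb_exac = exac,
             stringsAsFactors = FALSE)
}

test_that("multi-caller merging unions by variant key, keeps max depth, reconciles effects", {
  calls <- rbind(
    mkCall(caller = "mutA", reads = 5L, eff = "synonymous"),
    mkCall(caller = "mutB", reads = 12L, eff = "nonsynonymous"),
    mkCall(caller = "mutC", reads = 8L, eff = "UTR"),
    mkCall(pos = 900L, caller = "mutB"))
  m <- mergeCallerCalls(calls)
  expect_equal(nrow(m), 2L)
  shared <- m[m$pos == 100L, ]
  expect_equal(shared$caller_count, 3L)
  expect_equal(shared$callers, "mutA;mutB;mutC")
  expect_equal(shared$max_supporting_reads, 12L)
  expect_equal(shared$effect_class, "nonsynonymous")  # most deleterious wins

  disjoint <- rbind(mkCall(pos = 1L), mkCall(pos = 2L, caller = "mutB"))
  expect_equal(nrow(mergeCallerCalls(disjoint)), 2L)

  conflict <- rbind(mkCall(ref = "C"), mkCall(ref = "G", caller = "mutB"))
  expect_error(mergeCallerCalls(conflict), "conflicting REF")
})

test_that("the filter cascade reports exact per-stage counts on the planted fixture", {
  fx <- makeFilterFixture()
  res <- applySomaticFilters(fx$merged, fx$germlineKeys, fx$ponKeys)
  expect_identical(filterCounts(res$report), fx$expected)
  expect_equal(nrow(res$variants), 32L)
  # survivors are exactly the planted somatic class
  expect_true(all(fx$class_lab[match(res$variants$pos, fx$merged$pos)] ==
                    "somatic"))

  # boundary: 7 reads removed, 8 reads retained
  two <- rbind(mkCall(pos = 10L, reads = 7L), mkCall(pos = 20L, reads = 8L))
  m <- mergeCallerCalls(two)
  out <- applySomaticFilters(m)
  expect_equal(out$variants$pos, 20L)

  # idempotence and removal bookkeeping
  again <- applySomaticFilters(res$variants, fx$germlineKeys, fx$ponKeys)
  expect_equal(again$variants, res$variants)
  cnt <- filterCounts(res$report)
  expect_true(all(diff(cnt) <= 0))
  removals <- -diff(cnt)
  expect_equal(sum(removals) + cnt[["panel_of_normals"]], cnt[["input"]])

  # identity when nothing is filterable
  clean <- mergeCallerCalls(rbind(mkCall(pos = 1L), mkCall(pos = 2L)))
  expect_equal(applySomaticFilters(clean)$variants, clean)
  # empty input
  empty <- applySomaticFilters(clean[0, ])
  expect_equal(unname(filterCounts(empty$report)), rep(0L, 6))
})

test_that("mutation burden is per-Mb arithmetic and linear under concatenation", {
  v <- mergeCallerCalls(do.call(rbind, lapply(1:38, function(i)
    mkCall(pos = i * 10L))))
  b <- mutationBurden(v, targetMb = 38)
  expect_equal(b$nonsyn_per_mb, 1.0)
  expect_equal(b$total_per_mb, 1.0)
  expect_equal(mutationBurden(v[0, ], targetMb = 38,
                              samples = "S1")$total_per_mb, 0)
  expect_error(mutationBurden(v, targetMb = 0), "targetMb")

  v2 <- v; v2$sample_id <- "S2"; v2 <- v2[1:19, ]
  both <- mutationBurden(rbind(v, v2), targetMb = 38)
  expect_equal(both$total_per_mb, c(1.0, 0.5))
  # mixed effects: totals count all survivors, nonsyn only nonsynonymous
  v3 <- rbind(v[1:10, ], transform(v[11:15, ], effect_class = "other"))
  b3 <- mutationBurden(v3, targetMb = 38)
  expect_equal(b3$total_per_mb * 38, 15)
  expect_equal(b3$nonsyn_per_mb * 38, 10)
})

test_that("substitution spectra collapse purine references and compare across groups", {
  v <- mergeCallerCalls(rbind(
    mkCall(pos = 1L, ref = "G", alt = "T"),   # G>T == C>A
    mkCall(pos = 2L, ref = "C", alt = "A"),
    mkCall(pos = 3L, ref = "T", alt = "C"),
    mkCall(pos = 4L, ref = "A", alt = "G"),   # A>G == T>C
    mkCall(sample = "S2", pos = 5L, ref = "AT", alt = "A")))  # indel only
  expect_warning(sp <- substitutionSpectrum(v), "zero SNVs")
  expect_equal(unname(sp["S1", "C>A"]), 0.5)
  expect_equal(unname(sp["S1", "T>C"]), 0.5)
  expect_equal(unname(rowSums(sp)), 1)

  # planted smoker C>A excess is detected (BH q < 0.05) in most seeds
  hits <- 0L
  nseeds <- 5L
  for (sd in seq_len(nseeds)) {
    co <- simulateCohort(simulationParams(nAdc = 30, nSqcc = 30,
                                          nGenes = 600), seed = 700 + sd)
    m <- mergeCallerCalls(co$calls)
    filt <- applySomaticFilters(m, co$germlineKeys, co$ponKeys)
    spec <- suppressWarnings(substitutionSpectrum(filt$variants))
    cmp <- compareSpectra(spec, co$truth$smoking)
    if (cmp$q[cmp$class == "C>A"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, nseeds - 1L)
})
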