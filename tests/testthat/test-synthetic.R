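smallParams <- function(...) simulationParams(nAdc = 12, nSqcc = 10,
                                              nGenes = 600, ...)

test_that("the generator is fully deterministic under a fixed seed", {
  a <- simulateCohort(smallParams(), seed = 42)
  b <- simulateCohort(smallParams(), seed = 42)
  expect_identical(a$expression, b$expression)
  expect_identical(a$calls, b$calls)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c2 <- simulateCohort(smallParams(), seed = 43)
  expect_false(identical(a$expression, c2$expression))
})

test_that("every sample appears in all tables and ground truth covers the cohort", {
  co <- simulateCohort(smallParams(), seed = 3)
  ids <- colnames(co$expression)
  expect_setequal(co$clinical$sample, ids)
  expect_setequal(unique(co$segments$sample), ids)
  expect_true(all(co$calls$sample_id %in% ids))
  expect_setequal(names(co$truth$group), ids)
  expect_identical(colnames(co$truth$enrich), ids)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(simulationParams(groupProps = c(HIGH = 0.5, MIX = 0.2,
                                               LOW = 0.2)), "sum to 1")
  expect_error(simulationParams(delta = -1), "delta")
  expect_error(simulationParams(contamFracs = c(low_read = 1.4, syn_utr = 0,
                                                germline = 0, popdb = 0,
                                                pon = 0)), "probabilities")
  expect_error(simulationParams(survBeta = Inf), "finite")
  expect_error(simulationParams(banana = 1), "unknown")
})

test_that("delta shifts signature-gene expression only when infiltration is planted", {
  # delta = 2: planted infiltration raises signature-gene means
  co <- simulateCohort(smallParams(delta = 2), seed = 11)
  sig <- geneSets(co$signatures)[["NK_cells"]]
  on <- co$truth$enrich["NK_cells", ]
  lg <- log(co$expression[sig, , drop = FALSE])
  expect_gt(mean(lg[, on]) - mean(lg[, !on]), 1)

  # delta = 0: no group signal in signature genes (alpha = 0.01 t-test,
  # at most 1 rejection tolerated across 8 replicates)
  rejections <- 0L
  for (sd in 1:8) {
    c0 <- simulateCohort(smallParams(delta = 0), seed = 100 + sd)
    hi <- c0$truth$group == "HIGH"
    lo <- c0$truth$group == "LOW"
    sigg <- geneSets(c0$signatures)[["T_cells"]]
    x <- colMeans(log(c0$expression[sigg, hi, drop = FALSE]))
    y <- colMeans(log(c0$expression[sigg, lo, drop = FALSE]))
    if (stats::t.test(x, y)$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("planted contaminant classes and smoking spectra behave as declared", {
  co <- simulateCohort(smallParams(), seed = 5)
  cls <- co$truth$variantClasses
  key_reads <- tapply(co$calls$supporting_reads,
                      paste(co$calls$sample_id, co$calls$chrom, co$calls$pos,
                            co$calls$ref, co$calls$alt, sep = "|"), max)
  low <- cls$key[cls$class == "low_read"]
  expect_true(all(key_reads[low] < 8))
  expect_true(all(key_reads[setdiff(cls$key, low)] >= 8))
  expect_true(all(cls$key[cls$class == "germline"] %in% co$germlineKeys))

  # with all contaminant fractions zero nothing is planted beyond somatic
  clean <- simulateCohort(smallParams(
    contamFracs = c(low_read = 0, syn_utr = 0, germline = 0, popdb = 0,
                    pon = 0)), seed = 6)
  expect_identical(unique(clean$truth$variantClasses$class), "somatic")
  expect_length(clean$germlineKeys, 0)

  # smokers carry a C>A excess relative to non-smokers
  snv <- co$calls[!duplicated(paste(co$calls$sample_id, co$calls$pos)), ]
  spec <- substitutionSpectrum(snv)
  smk <- co$truth$smoking[rownames(spec)]
  expect_gt(mean(spec[smk == "smoker", "C>A"]),
            mean(spec[smk == "non-smoker", "C>A"]))
})

test_that("survival times exercise the censoring horizon and carry the planted hazard", {
  co <- simulateCohort(smallParams(nAdc = 60, nSqcc = 60), seed = 8)
  expect_true(all(co$clinical$os_days >= 0))
  expect_gt(sum(co$clinical$os_days > 1200), 0)  # horizon rule is not a no-op
  hi <- co$truth$group[co$clinical$sample] == "HIGH"
  km <- kmLogrank(co$clinical, ifelse(hi, "HIGH", "rest"))
  expect_true(is.finite(km$p))
  # HIGH samples live longer on average under the planted log-HR
  expect_gt(mean(co$clinical$os_days[hi]), mean(co$clinical$os_days[!hi]))
})
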