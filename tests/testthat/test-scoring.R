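test_that("ssGSEA matches a literal brute-force transcription of the running-sum formula", {
  for (seed in 1:3) {
    expr <- randomExprMatrix(50, 5, seed = seed)
    set.seed(seed + 100)
    sets <- list(s1 = sample(rownames(expr), 6),
                 s2 = sample(rownames(expr), 12),
                 s3 = sample(rownames(expr), 3))
    for (alpha in c(0.25, 0)) {
      got <- ssgseaScores(expr, sets, alpha = alpha, normalize = FALSE)
      want <- bruteSsgsea(expr, sets, alpha = alpha)
      expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("ssGSEA responds to rank concentration, is rank-only, and normalizes by global range", {
  expr <- randomExprMatrix(30, 3, seed = 9)
  top <- rownames(expr)[order(-expr[, 1])][1:5]
  sc <- ssgseaScores(expr, list(top = top), normalize = FALSE)
  expect_gt(sc["top", 1], 0)

  # invariance to a monotone per-sample transform (rank-only dependence)
  sets <- list(a = rownames(expr)[c(2, 5, 9)], b = rownames(expr)[20:26])
  expect_equal(ssgseaScores(expr, sets, normalize = FALSE),
               ssgseaScores(expr^3, sets, normalize = FALSE),
               tolerance = 1e-12)

  norm <- ssgseaScores(expr, sets, normalize = TRUE)
  raw <- ssgseaScores(expr, sets, normalize = FALSE)
  expect_equal(norm, raw / (max(raw) - min(raw)), ignore_attr = TRUE)
  expect_lte(max(norm) - min(norm), 1 + 1e-12)

  expect_error(ssgseaScores(expr, list(x = c("NOPE1", "NOPE2"))), "no genes")
  expect_error(ssgseaScores(expr, list(x = rownames(expr))), "whole gene")
})

test_that("z-score normalization is exact, flags constant genes, and is idempotent", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  z <- zscoreNormalize(m)
  expect_equal(z["g1", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_identical(attr(z, "constant_genes"), "g2")
  expect_equal(zscoreNormalize(z)["g1", ], z["g1", ], tolerance = 1e-12)
  expect_error(zscoreNormalize(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("preranked enrichment: extremal sets hit the permutation floor and q is a BH adjustment", {
  expr <- randomExprMatrix(200, 3, seed = 21)
  z <- zscoreNormalize(log2(expr + 1))
  topset <- rownames(z)[order(-z[, 1])][1:15]
  set.seed(22)
  sets <- c(list(top = topset),
            lapply(1:5, function(i) sample(rownames(z), 15)))
  names(sets) <- c("top", paste0("r", 1:5))
  er <- prerankedEnrichment(z, sets, nPerm = 200, seed = 7)
  tb <- enrichmentTable(er)
  s1 <- tb[tb$sample == colnames(z)[1], ]
  expect_equal(s1$p[s1$signature == "top"], 1 / 201)
  expect_equal(max(s1$es), s1$es[s1$signature == "top"])
  # q-values equal an independent sort-and-cummin BH oracle, per sample
  for (s in unique(tb$sample)) {
    sub <- tb[tb$sample == s, ]
    expect_equal(sub$q, bruteBH(sub$p), tolerance = 1e-12)
  }
  expect_true(all(tb$q >= tb$p - 1e-12))
  # determinism under the stated seed
  er2 <- prerankedEnrichment(z, sets, nPerm = 200, seed = 7)
  expect_identical(enrichmentTable(er2), tb)
  expect_error(prerankedEnrichment(z, sets, nPerm = 50), "nPerm")
  expect_error(prerankedEnrichment(z, list(x = rownames(z)), nPerm = 100),
               "universe")
})

test_that("the enrichment statistic agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  expr <- randomExprMatrix(300, 2, seed = 31)
  z <- zscoreNormalize(log2(expr + 1))
  set.seed(32)
  sets <- list(a = sample(rownames(z), 20), b = sample(rownames(z), 8))
  er <- prerankedEnrichment(z, sets, nPerm = 100, seed = 1)
  tb <- enrichmentTable(er)
  for (j in 1:2) {
    stats_j <- sort(z[, j], decreasing = TRUE)
    for (nm in names(sets)) {
      ref <- fgsea::calcGseaStat(stats_j,
                                 which(names(stats_j) %in% sets[[nm]]),
                                 gseaParam = 1)
      got <- tb$es[tb$sample == colnames(z)[j] & tb$signature == nm]
      expect_equal(got, ref, tolerance = 1e-6)
    }
  }
})

test_that("the enrichment call boundary is inclusive at the q threshold", {
  tab <- data.frame(sample = "s1", signature = c("a", "b"),
                    es = c(0.5, 0.2), nes = c(1.5, 0.6),
                    p = c(0.05, 0.1), q = c(0.1, 0.1),
                    enriched = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_s4_class(new("EnrichmentResult", table = tab, qThreshold = 0.1),
                  "EnrichmentResult")
  tab$enriched <- c(FALSE, FALSE)  # q == threshold must be called enriched
  expect_error(new("EnrichmentResult", table = tab, qThreshold = 0.1),
               "enriched")
})

test_that("planted infiltration flags are recovered when infiltration is a cohort minority", {
  p <- simulationParams(nAdc = 10, nSqcc = 10, nGenes = 2000,
                        groupProps = c(HIGH = 0.2, MIX = 0.2, LOW = 0.6))
  co <- simulateCohort(p, seed = 13)
  z <- zscoreNormalize(log2(co$expression + 1))
  er <- prerankedEnrichment(z, co$signatures, nPerm = 300, seed = 1)
  tb <- enrichmentTable(er)
  truth <- co$truth$enrich[cbind(tb$signature, tb$sample)]
  sens <- sum(tb$enriched & truth) / sum(truth)
  spec <- sum(!tb$enriched & !truth) / sum(!truth)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("TIL profiles report exact per-stratum enrichment percentages", {
  # 95 of 131 enriched -> 72.5%
  samples <- sprintf("A%03d", 1:131)
  tab <- data.frame(sample = samples, signature = "T_cells", es = 1,
                    nes = 1, p = 0.01,
                    q = c(rep(0.05, 95), rep(0.5, 36)),
                    enriched = c(rep(TRUE, 95), rep(FALSE, 36)),
                    stringsAsFactors = FALSE)
  er <- new("EnrichmentResult", table = tab, qThreshold = 0.1)
  strata <- setNames(rep("ADC", 131), samples)
  tp <- tilProfile(er, strata)
  expect_equal(tp$percent[tp$signature == "T_cells"], 72.5, tolerance = 0.05)
  expect_equal(tp$percent[tp$signature == "any_TIL"], 72.5, tolerance = 0.05)

  tab$enriched <- FALSE; tab$q <- 0.5
  tp0 <- tilProfile(new("EnrichmentResult", table = tab, qThreshold = 0.1),
                    strata)
  expect_true(all(tp0$percent == 0))

  one <- tab[1, ]; one$enriched <- TRUE; one$q <- 0.01
  tp1 <- tilProfile(new("EnrichmentResult", table = one, qThreshold = 0.1),
                    strata[1])
  expect_true(all(tp1$percent == 100))
  expect_error(tilProfile(er, strata[-1]), "stratum")
})
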