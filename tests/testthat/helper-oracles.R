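# Independent oracles and small fixture builders, all generated in code.

# literal transcription of the ssGSEA weighted running-sum formula,
# written as explicit loops, independently of the package implementation
bruteSsgsea <- function(expr, sets, alpha) {
  G <- nrow(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    # descending expression, ties by gene id
    ord <- order(-x, rownames(expr))
    g_sorted <- rownames(expr)[ord]
    rank_value <- G:1
    for (k in seq_along(sets)) {
      S <- sets[[k]]
      denom_in <- 0
      for (i in seq_len(G)) if (g_sorted[i] %in% S)
        denom_in <- denom_in + abs(rank_value[i])^alpha
      n_out <- G - sum(g_sorted %in% S)
      es <- 0; pin <- 0; pout <- 0
      for (i in seq_len(G)) {
        if (g_sorted[i] %in% S) pin <- pin + abs(rank_value[i])^alpha / denom_in
        else pout <- pout + 1 / n_out
        es <- es + (pin - pout)
      }
      out[k, j] <- es
    }
  }
  out
}

# sort-and-cummin Benjamini-Hochberg oracle
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# empirical survivor function (no censoring): S(t) = P(T > t)
empiricalSurvivor <- function(times, t) mean(times > t)

randomExprMatrix <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  matrix(stats::rlnorm(nGenes * nSamples, 1, 1), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# merged-variant fixture with exactly planted contaminant classes:
# 32 clean somatic + 10 matched-germline + 5 popdb + 3 PoN (all read-depth
# and effect clean, 50 total entering the germline stage) plus nLowRead
# low-read and nSynUtr synonymous/UTR extras removed at stage 1.
makeFilterFixture <- function(nLowRead = 4, nSynUtr = 6) {
  n <- 50 + nLowRead + nSynUtr
  df <- data.frame(
    sample_id = "S1", chrom = "chr1", pos = seq_len(n) * 100L,
    ref = "C", alt = "A", caller_count = 2L, callers = "mutA;mutB",
    max_supporting_reads = 20L, effect_class = "nonsynonymous",
    popdb_1000g = FALSE, popdb_exac = FALSE, stringsAsFactors = FALSE)
  class_lab <- c(rep("somatic", 32), rep("germline", 10), rep("popdb", 5),
                 rep("pon", 3), rep("low_read", nLowRead),
                 rep("syn_utr", nSynUtr))
  low <- which(class_lab == "low_read")
  df$max_supporting_reads[low] <- c(7L, seq_len(max(0, nLowRead - 1)))[seq_along(low)]
  syn <- which(class_lab == "syn_utr")
  df$effect_class[syn] <- rep(c("synonymous", "UTR"), length.out = length(syn))
  pop <- which(class_lab == "popdb")
  df$popdb_1000g[pop[1:3]] <- TRUE
  df$popdb_exac[pop[-(1:3)]] <- TRUE
  germKeys <- paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt,
                    sep = "|")[class_lab == "germline"]
  ponKeys <- paste(df$chrom, df$pos, df$ref, df$alt,
                   sep = "|")[class_lab == "pon"]
  list(merged = df, class_lab = class_lab,
       germlineKeys = germKeys, ponKeys = ponKeys,
       expected = c(input = as.integer(n),
                    min_reads = as.integer(n - nLowRead),
                    effect_class = 50L, matched_germline = 40L,
                    popdb = 35L, panel_of_normals = 32L))
}

# block-structured score matrix for deterministic grouping fixtures
blockScores <- function(nHigh, nMix, nLow, highLevel = 2, mixInnate = 1) {
  sigs <- c(TMEprofiler:::adaptiveSignatures,
            TMEprofiler:::innateSignatures,
            TMEprofiler:::otherSignatures)
  n <- nHigh + nMix + nLow
  m <- matrix(0, length(sigs), n,
              dimnames = list(sigs, sprintf("P%02d", seq_len(n))))
  hi <- seq_len(nHigh)
  mx <- nHigh + seq_len(nMix)
  m[, hi] <- highLevel
  innate <- c(TMEprofiler:::innateSignatures, TMEprofiler:::otherSignatures)
  m[innate, mx] <- mixInnate
  m
}
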