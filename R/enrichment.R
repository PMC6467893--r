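# run expr with a temporary RNG state; restores the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# signed max-deviation weighted KS running-sum (GSEA statistic, exponent 1)
# absw: |ranking metric| in ranked order; inset: logical membership per position
gseaRunningES <- function(absw, inset) {
  nh <- sum(absw[inset])
  g <- length(absw)
  ns <- sum(inset)
  hit <- if (nh > 0) ifelse(inset, absw, 0) / nh else inset / ns
  dev <- cumsum(hit - (!inset) / (g - ns))
  dev[which.max(abs(dev))]
}

#' Per-patient preranked gene-set enrichment with permutation FDR
#'
#' For each sample, genes are ranked by their cohort z-score (descending,
#' ties broken by gene-id order) and each signature's weighted
#' Kolmogorov-Smirnov enrichment statistic (weight exponent 1 on the
#' ranking metric) is computed. The null distribution comes from
#' \code{nPerm} random gene sets of the same size; the p-value is the
#' positive-tail permutation probability
#' \eqn{p = (1 + \#\{ES_{null} \ge ES\}) / (1 + nPerm)}, so depleted
#' signatures get large p. q-values are Benjamini-Hochberg adjusted across
#' the signatures within each sample, and a signature is called enriched
#' when \code{q <= qThreshold} (boundary inclusive).
#'
#' @param zexpr z-score normalized genes x samples matrix
#'   (\code{\link{zscoreNormalize}}).
#' @param sets a \linkS4class{SignatureCollection} or named list.
#' @param nPerm number of random-set permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation stream.
#' @param qThreshold enrichment call threshold on q (default 0.1).
#' @return An \linkS4class{EnrichmentResult}.
#' @export
prerankedEnrichment <- function(zexpr, sets, nPerm = 1000L, seed = 1L,
                                qThreshold = 0.1) {
  if (is(sets, "SignatureCollection")) sets <- geneSets(sets)
  if (nPerm < 100) stop("nPerm must be >= 100")
  G <- nrow(zexpr)
  genes <- rownames(zexpr)
  sizes <- vapply(sets, function(s) sum(s %in% genes), integer(1))
  if (any(sizes == 0))
    stop("signature(s) with no genes in the matrix: ",
         paste(names(sets)[sizes == 0], collapse = ", "))
  if (any(sizes >= G))
    stop("signature at least as large as the gene universe: ",
         paste(names(sets)[sizes >= G], collapse = ", "))
  gene_order <- order(genes)
  rows <- vector("list", ncol(zexpr))
  withSeed(seed, {
    for (j in seq_len(ncol(zexpr))) {
      x <- zexpr[gene_order, j]
      ord <- order(-x)
      ranked_genes <- genes[gene_order][ord]
      absw <- abs(x[ord])
      es <- vapply(sets, function(s)
        gseaRunningES(absw, ranked_genes %in% s), numeric(1))
      # one shared null per distinct set size within this sample
      null_by_size <- lapply(unique(sizes), function(sz) {
        vapply(seq_len(nPerm), function(b) {
          idx <- sample.int(G, sz)
          inset <- logical(G)
          inset[idx] <- TRUE
          gseaRunningES(absw, inset)
        }, numeric(1))
      })
      names(null_by_size) <- as.character(unique(sizes))
      p <- nes <- numeric(length(sets))
      for (k in seq_along(sets)) {
        nul <- null_by_size[[as.character(sizes[k])]]
        p[k] <- (1 + sum(nul >= es[k])) / (1 + nPerm)
        nes[k] <- es[k] / mean(abs(nul))
      }
      q <- stats::p.adjust(p, method = "BH")
      rows[[j]] <- data.frame(
        sample = colnames(zexpr)[j], signature = names(sets),
        es = unname(es), nes = nes, p = p, q = q,
        enriched = q <= qThreshold,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab, qThreshold = qThreshold)
}

#' Cohort TIL enrichment profile
#'
#' Percent of samples with an enriched call per signature within each cohort
#' stratum (e.g. histology, smoking status), plus an \code{"any_TIL"}
#' summary row per stratum: the percent of samples enriched for at least one
#' of the lymphocyte signatures in \code{anySignatures}.
#'
#' @param enrichment an \linkS4class{EnrichmentResult}.
#' @param strata named character/factor vector assigning each sample to
#'   exactly one stratum.
#' @param anySignatures signatures whose union defines "any TIL" (default:
#'   every signature named \code{T_cells} or \code{B_cells} if present,
#'   otherwise all signatures).
#' @return data.frame: stratum, signature, n_enriched, n_total, percent.
#' @export
tilProfile <- function(enrichment, strata, anySignatures = NULL) {
  tb <- enrichmentTable(enrichment)
  samples <- unique(tb$sample)
  if (!all(samples %in% names(strata)))
    stop("every sample needs a stratum assignment")
  strata <- factor(strata[samples])
  if (any(table(strata) == 0)) stop("empty stratum")
  sigs <- unique(tb$signature)
  if (is.null(anySignatures)) {
    anySignatures <- intersect(c("T_cells", "B_cells"), sigs)
    if (!length(anySignatures)) anySignatures <- sigs
  }
  out <- list()
  for (st in levels(strata)) {
    in_st <- samples[strata == st]
    sub <- tb[tb$sample %in% in_st, ]
    for (sg in sigs) {
      hit <- sub$enriched[sub$signature == sg]
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, signature = sg,
        n_enriched = sum(hit), n_total = length(in_st),
        percent = 100 * sum(hit) / length(in_st))
    }
    any_hit <- tapply(sub$enriched & sub$signature %in% anySignatures,
                      sub$sample, any)[in_st]
    out[[length(out) + 1L]] <- data.frame(
      stratum = st, signature = "any_TIL",
      n_enriched = sum(any_hit), n_total = length(in_st),
      percent = 100 * sum(any_hit) / length(in_st))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
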