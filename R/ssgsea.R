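#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression in descending order (ties
#' broken by gene-id order for determinism) and assigned rank weights
#' \eqn{G, G-1, \ldots, 1} from the top. The signature score is the
#' integrated difference between two empirical distribution functions walked
#' down the ranked list,
#' \deqn{ES = \sum_{i=1}^{G} \left[ P^w_{in}(i) - P_{out}(i) \right],}
#' where \eqn{P^w_{in}} accumulates \eqn{|rank|^\alpha} over in-set genes
#' (normalized by the in-set total) and \eqn{P_{out}} accumulates
#' \eqn{1/(G-|S|)} over out-of-set genes. With \code{normalize = TRUE} all
#' scores are divided by the range (max - min) of the whole score matrix.
#'
#' The score depends on expression only through ranks, so it is invariant to
#' any monotone per-sample transform.
#'
#' @param expr genes x samples non-negative expression matrix.
#' @param sets a \linkS4class{SignatureCollection} (or named list of gene
#'   vectors).
#' @param alpha rank-weight exponent, >= 0; default 0.25. \code{alpha = 0}
#'   gives the unweighted running-sum statistic.
#' @param normalize divide by the global score range (default TRUE).
#' @return signatures x samples numeric matrix with attribute
#'   \code{"normalized"}.
#' @examples
#' expr <- matrix(abs(rnorm(60)), 20, 3,
#'                dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
#' sc <- SignatureCollection(list(a = c("g1", "g2", "g3")))
#' ssgseaScores(expr, sc, normalize = FALSE)
#' @export
ssgseaScores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  validateExpressionMatrix(expr)
  if (is(sets, "SignatureCollection")) sets <- geneSets(sets)
  stopifnot(alpha >= 0)
  G <- nrow(expr)
  genes <- rownames(expr)
  for (nm in names(sets)) {
    ov <- sum(sets[[nm]] %in% genes)
    if (ov == 0)
      stop("signature '", nm, "' has no genes in the expression matrix")
    if (ov == G)
      stop("signature '", nm, "' covers the whole gene universe")
  }
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  gene_order <- order(genes)  # tie-break: stable gene-id order
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    ord <- order(-x[gene_order])
    ranked_genes <- genes[gene_order][ord]
    w <- (G:1)^alpha  # weight of position i is its descending rank value
    for (k in seq_along(sets)) {
      inset <- ranked_genes %in% sets[[k]]
      ns <- sum(inset)
      p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
      p_out <- cumsum(!inset) / (G - ns)
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) scores <- scores / (max(scores) - min(scores))
  attr(scores, "normalized") <- normalize
  scores
}

#' Z-score normalize an expression matrix across samples
#'
#' Each gene row is centered and scaled to mean 0, sd 1 across samples.
#' Zero-variance genes are set to all-zero and flagged in the
#' \code{"constant_genes"} attribute. Idempotent on already-normalized input.
#'
#' @param expr genes x samples numeric matrix with >= 2 samples.
#' @return matrix of the same shape.
#' @export
zscoreNormalize <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2)
    stop("z-score normalization needs a matrix with >= 2 samples")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  flat <- sdv == 0
  sdv[flat] <- 1
  z <- (expr - mu) / sdv
  z[flat, ] <- 0
  attr(z, "constant_genes") <- rownames(expr)[flat]
  z
}
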