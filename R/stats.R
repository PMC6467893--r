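#' Fisher's exact test on a 2x2 contingency table
#'
#' Direct hypergeometric enumeration with fixed margins. The two-sided
#' p-value sums the probabilities of all tables whose point probability does
#' not exceed the observed table's (the standard exact-test convention).
#' The odds ratio is the sample odds ratio \eqn{ad/bc} (infinite when
#' \eqn{bc = 0} and \eqn{ad > 0}).
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   \code{c(a, b, c, d)} filling the table by row.
#' @return list with \code{odds_ratio} and \code{p} (two-sided).
#' @examples
#' # EGFR-mutated vs wild-type, non-smoking women vs men
#' fisherExact2x2(matrix(c(28, 5, 9, 5), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(tab) {
  if (is.vector(tab) && length(tab) == 4)
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integer counts")
  n <- sum(tab)
  if (n < 1) stop("empty table")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + cc          # first-column margin
  k <- a + b           # first-row margin
  support <- max(0, k - (n - m)):min(k, m)
  dens <- stats::dhyper(support, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * cc)
  list(odds_ratio = or, p = min(1, p))
}

#' Differentially expressed genes among the three immune groups
#'
#' Per gene: one-way ANOVA and Kruskal-Wallis tests across the HIGH/MIX/LOW
#' groups, each Benjamini-Hochberg adjusted across genes; maximum absolute
#' Pearson correlation with the immune marker genes (on z-scored
#' expression); and the largest pairwise fold change among the three group
#' means on the linear FPKM scale. The fold-change pseudocount is expressed
#' in units of the global mean expression (\code{pseudocount * mean(expr)})
#' so the criterion is invariant to global rescaling of the FPKM matrix.
#' A gene is selected
#' when both q-values are < 0.01, the marker correlation is < 0.6 and the
#' maximum pairwise fold change exceeds 2.
#'
#' @param expr genes x samples FPKM matrix.
#' @param groups an \linkS4class{ImmuneGroupAssignment} or named 3-level
#'   vector over the samples.
#' @param markerGenes immune marker gene ids present in \code{expr}.
#' @param qCut FDR cut for both tests (default 0.01).
#' @param corCut marker-correlation exclusion threshold (default 0.6).
#' @param fcCut minimum max pairwise fold change (default 2).
#' @param pseudocount added to linear group means (default 0.1).
#' @return data.frame: gene, anova_q, kw_q, max_abs_corr, max_fold_change,
#'   selected.
#' @export
groupDeGenes <- function(expr, groups, markerGenes, qCut = 0.01,
                         corCut = 0.6, fcCut = 2, pseudocount = 0.1) {
  if (is(groups, "ImmuneGroupAssignment")) groups <- immuneGroups(groups)
  g <- factor(groups[colnames(expr)])
  g <- droplevels(g)
  if (nlevels(g) != 3) stop("need exactly 3 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  miss <- setdiff(markerGenes, rownames(expr))
  if (length(miss))
    stop("marker gene(s) absent from expression: ",
         paste(miss, collapse = ", "))
  z <- zscoreNormalize(expr)
  marker_z <- t(z[markerGenes, , drop = FALSE])
  pc <- pseudocount * mean(expr)
  anova_p <- kw_p <- max_corr <- max_fc <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    y <- expr[i, ]
    anova_p[i] <- tryCatch(
      stats::oneway.test(y ~ g, var.equal = TRUE)$p.value,
      error = function(e) 1)
    kw_p[i] <- tryCatch(
      suppressWarnings(stats::kruskal.test(y, g)$p.value),
      error = function(e) 1)
    cz <- suppressWarnings(stats::cor(z[i, ], marker_z))
    max_corr[i] <- if (all(is.na(cz))) 1 else max(abs(cz), na.rm = TRUE)
    mns <- tapply(y, g, mean) + pc
    prs <- utils::combn(mns, 2)
    max_fc[i] <- max(pmax(prs[1, ] / prs[2, ], prs[2, ] / prs[1, ]))
  }
  anova_p[is.na(anova_p)] <- 1
  kw_p[is.na(kw_p)] <- 1
  max_corr[!is.finite(max_corr)] <- 1  # constant gene: treat as uninformative
  anova_q <- stats::p.adjust(anova_p, method = "BH")
  kw_q <- stats::p.adjust(kw_p, method = "BH")
  data.frame(gene = rownames(expr), anova_q = anova_q, kw_q = kw_q,
             max_abs_corr = max_corr, max_fold_change = max_fc,
             selected = anova_q < qCut & kw_q < qCut &
               max_corr < corCut & max_fc > fcCut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate a pathway's ssGSEA score with a target across samples
#'
#' The pathway gene set is scored per sample with \code{\link{ssgseaScores}}
#' and Spearman rank correlation (ties handled by average rank, asymptotic
#' p) against the target is returned.
#'
#' @param expr genes x samples FPKM matrix.
#' @param pathwaySet character vector of pathway gene ids.
#' @param target numeric vector named by sample, or a gene id in
#'   \code{expr}.
#' @param alpha ssGSEA weight exponent (default 0.25).
#' @return list with \code{rho}, \code{p}, and \code{flag}
#'   (\code{"constant_target"} when rho is undefined).
#' @export
pathwayScoreCorrelation <- function(expr, pathwaySet, target, alpha = 0.25) {
  if (ncol(expr) < 3) stop("need >= 3 samples")
  score <- ssgseaScores(expr, list(pathway = pathwaySet), alpha = alpha,
                        normalize = FALSE)[1, ]
  if (is.character(target) && length(target) == 1) {
    if (!target %in% rownames(expr)) stop("target gene not in expression")
    target <- expr[target, ]
  }
  target <- target[colnames(expr)]
  if (stats::sd(target) == 0) {
    warning("constant target: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, flag = "constant_target"))
  }
  ct <- suppressWarnings(
    stats::cor.test(score, target, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, flag = "ok")
}
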