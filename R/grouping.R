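#' Hierarchically cluster samples on their signature score matrix
#'
#' Agglomerative clustering of sample columns with Euclidean (default) or
#' 1 - Pearson correlation distance and Ward/average/complete linkage.
#' Cluster labels are re-ordered by descending mean signature score so that
#' cluster 1 is always the most infiltrated.
#'
#' @param scores signatures x samples numeric matrix.
#' @param k number of clusters (2 or 3).
#' @param distance \code{"pearson"} (1 - correlation) or \code{"euclidean"}.
#' @param linkage \code{"average"}, \code{"complete"} or \code{"ward"}
#'   (ward.D2).
#' @return integer vector of cluster labels (1 = most infiltrated), named by
#'   sample.
#' @export
clusterSamples <- function(scores, k = 3, distance = c("euclidean", "pearson"),
                           linkage = c("ward", "average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (k > ncol(scores)) stop("k exceeds the number of samples")
  if (stats::sd(as.vector(scores)) == 0)
    stop("degenerate: no immune structure (zero-variance score matrix)")
  d <- if (distance == "pearson") {
    cc <- suppressWarnings(stats::cor(scores))
    cc[!is.finite(cc)] <- 0  # constant columns carry no correlation signal
    stats::as.dist(1 - cc)
  } else {
    stats::dist(t(scores))
  }
  hc <- stats::hclust(d, method = c(average = "average", complete = "complete",
                                    ward = "ward.D2")[linkage])
  raw <- stats::cutree(hc, k = k)
  means <- tapply(colMeans(scores), raw, mean)
  relabel <- match(raw, as.integer(names(sort(means, decreasing = TRUE))))
  setNames(as.integer(relabel), colnames(scores))
}

#' Assign immune HIGH/MIX/LOW groups with histology-specific refinement
#'
#' ADC samples are clustered into two major clusters; the lower-score cluster
#' is LOW and the high cluster is split on T-cell and B-cell signature
#' levels: samples with both above the ADC cohort median become HIGH, the
#' rest MIX. SQCC samples are clustered into three clusters mapped to
#' HIGH/MIX/LOW by descending mean score; MIX samples whose T-cell and
#' B-cell signature scores and PD-1 and CD8 marker expression all exceed the
#' SQCC cohort 75th percentile are promoted to HIGH
#' (\code{refinement_rule = "sqcc_mix_promotion"}).
#'
#' @param scores normalized signatures x samples score matrix
#'   (\code{\link{ssgseaScores}}).
#' @param markerExpr genes x samples expression matrix holding the PD-1 and
#'   CD8 marker rows (required for the SQCC path).
#' @param histology named vector (\code{"ADC"}/\code{"SQCC"}) per sample.
#' @param config a \code{\link{profilerConfig}} (signature/marker names,
#'   distance, linkage, split quantiles).
#' @return An \linkS4class{ImmuneGroupAssignment}.
#' @export
assignImmuneGroups <- function(scores, markerExpr = NULL, histology,
                               config = profilerConfig()) {
  samples <- colnames(scores)
  if (!all(samples %in% names(histology)))
    stop("every sample needs a histology label")
  histology <- histology[samples]
  tSig <- config$tSignature
  bSig <- config$bSignature
  if (!all(c(tSig, bSig) %in% rownames(scores)))
    stop("score matrix must include the '", tSig, "' and '", bSig,
         "' signatures")
  res <- list()
  for (h in intersect(c("ADC", "SQCC"), unique(histology))) {
    ids <- samples[histology == h]
    sub <- scores[, ids, drop = FALSE]
    if (h == "ADC") {
      cl <- clusterSamples(sub, k = 2, distance = config$clusterDistance,
                           linkage = config$clusterLinkage)
      grp <- ifelse(cl == 1, NA_character_, "LOW")
      rule <- ifelse(cl == 1, "adc_high_split", "none")
      tmed <- stats::quantile(sub[tSig, ], config$adcSplitQuantile)
      bmed <- stats::quantile(sub[bSig, ], config$adcSplitQuantile)
      hi <- cl == 1 & sub[tSig, ] > tmed & sub[bSig, ] > bmed
      grp[cl == 1] <- ifelse(hi[cl == 1], "HIGH", "MIX")
    } else {
      cl <- clusterSamples(sub, k = 3, distance = config$clusterDistance,
                           linkage = config$clusterLinkage)
      grp <- c("HIGH", "MIX", "LOW")[cl]
      rule <- rep("none", length(ids))
      if (is.null(markerExpr) ||
          !all(c(config$pd1Gene, config$cd8Gene) %in% rownames(markerExpr)))
        stop("SQCC refinement needs marker rows '", config$pd1Gene,
             "' and '", config$cd8Gene, "' in markerExpr")
      qn <- config$sqccPromoteQuantile
      tq <- stats::quantile(sub[tSig, ], qn)
      bq <- stats::quantile(sub[bSig, ], qn)
      pdq <- stats::quantile(markerExpr[config$pd1Gene, ids], qn)
      cdq <- stats::quantile(markerExpr[config$cd8Gene, ids], qn)
      promote <- grp == "MIX" &
        sub[tSig, ] > tq & sub[bSig, ] > bq &
        markerExpr[config$pd1Gene, ids] > pdq &
        markerExpr[config$cd8Gene, ids] > cdq
      grp[promote] <- "HIGH"
      rule[promote] <- "sqcc_mix_promotion"
    }
    res[[h]] <- data.frame(sample = ids, group = grp,
                           cluster_id = as.integer(cl),
                           refinement_rule = rule,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[match(samples, out$sample), ]
  rownames(out) <- NULL
  new("ImmuneGroupAssignment", assignments = out)
}
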