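#' Pipeline run configuration
#'
#' Collects every tunable constant of the profiling pipeline in one list, with
#' the published analysis settings as defaults: enrichment call threshold
#' q <= 0.1, minimum supporting reads 8, fusion high-confidence threshold
#' strictly > 9, right-censoring horizon 1200 days, ssGSEA weight exponent
#' 0.25 and GISTIC-convention copy-number state thresholds.
#'
#' @param ... named overrides for any default listed below.
#' @return A named list of class \code{profiler_config}.
#' @details Defaults:
#' \describe{
#'   \item{ssgseaAlpha}{0.25 — rank-weight exponent of the ssGSEA score.}
#'   \item{nPerm}{1000 — random gene-set permutations for preranked
#'     enrichment.}
#'   \item{qThreshold}{0.1 — BH q-value at or below which a signature is
#'     called enriched.}
#'   \item{minReads}{8 — variants with fewer supporting reads are removed
#'     (a variant with exactly 8 survives).}
#'   \item{targetMb}{38 — interrogated exome size used as the mutation-burden
#'     denominator.}
#'   \item{fusionThreshold}{9 — total fusion score must strictly exceed this
#'     to be called high confidence.}
#'   \item{cnvThresholds}{log2-ratio cut points for the 5-state gene CNV
#'     coding.}
#'   \item{clusterDistance, clusterLinkage}{\code{"euclidean"} with
#'     \code{"ward"} (Ward.D2) linkage. Euclidean distance is the default
#'     because the HIGH/MIX/LOW labels are defined by the overall signature
#'     score level, which a correlation distance discards, and Ward linkage
#'     recovers compact level-based clusters where average linkage tends to
#'     chain; \code{"pearson"} (1 - correlation) and the other linkages
#'     remain available.}
#'   \item{censorHorizon}{1200 days.}
#'   \item{tSignature, bSignature}{signature names used by the immune-group
#'     refinement rules.}
#'   \item{pd1Gene, cd8Gene}{marker gene ids used by the SQCC MIX-to-HIGH
#'     promotion rule.}
#'   \item{adcSplitQuantile}{0.5 — the ADC high cluster splits on the cohort
#'     median of T and B signature scores.}
#'   \item{sqccPromoteQuantile}{0.75 — SQCC MIX promotion requires T/B scores
#'     and PD-1/CD8 expression above this cohort quantile.}
#'   \item{depthKey}{\code{"AD"} — FORMAT key holding the ALT allelic depth
#'     taken as "supporting reads".}
#'   \item{effectKey}{\code{"EFF"} — INFO key holding the annotated effect
#'     class.}
#'   \item{foldChangePseudocount}{0.1 — added to linear-scale group means
#'     before fold-change ratios.}
#'   \item{corThreshold}{0.6 — DE genes correlated at or above this with any
#'     immune marker are excluded.}
#' }
#' @examples
#' cfg <- profilerConfig(minReads = 10)
#' cfg$minReads
#' @export
profilerConfig <- function(...) {
  cfg <- list(
    ssgseaAlpha = 0.25,
    nPerm = 1000L,
    qThreshold = 0.1,
    minReads = 8L,
    targetMb = 38,
    fusionWeights = list(
      readHigh = 3, readMid = 2, readLow = 1,
      canonical = 3,
      perCaller = 1, maxCallerPoints = 3,
      censusPerPartner = 1, maxCensusPoints = 2,
      recurrencePerSample = 1, maxRecurrencePoints = 2),
    fusionThreshold = 9,
    cnvThresholds = c(homdel = -1.3, hetdel = -0.3,
                      hetamp = 0.3, homamp = 0.9),
    clusterDistance = "euclidean",
    clusterLinkage = "ward",
    censorHorizon = 1200,
    tSignature = "T_cells",
    bSignature = "B_cells",
    pd1Gene = "PDCD1",
    cd8Gene = "CD8A",
    adcSplitQuantile = 0.5,
    sqccPromoteQuantile = 0.75,
    depthKey = "AD",
    effectKey = "EFF",
    foldChangePseudocount = 0.1,
    corThreshold = 0.6)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "profiler_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override \code{\link{profilerConfig}} defaults;
#' absent fields keep them.
#'
#' @param path path to a YAML file whose top-level keys mirror
#'   \code{profilerConfig} fields.
#' @return a \code{profiler_config} list.
#' @export
readProfilerConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cnvThresholds)) y$cnvThresholds <- unlist(y$cnvThresholds)
  do.call(profilerConfig, y)
}

#' @export
print.profiler_config <- function(x, ...) {
  cat("profiler_config with", length(x), "settings\n")
  scal <- vapply(x, function(v) is.atomic(v) && length(v) == 1, logical(1))
  for (n in names(x)[scal]) cat(sprintf("  %-22s %s\n", n, format(x[[n]])))
  for (n in names(x)[!scal]) cat(sprintf("  %-22s <%s>\n", n, class(x[[n]])[1]))
  invisible(x)
}
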