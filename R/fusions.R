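#' Build a fusion knowledge base
#'
#' @param canonicalPairs two-column data.frame or character matrix of known
#'   canonical fusion gene pairs (orientation-free).
#' @param censusGenes character vector of cancer gene census symbols.
#' @return list with normalized unordered pair keys and the census set.
#' @export
fusionKnowledge <- function(canonicalPairs = NULL, censusGenes = character()) {
  pairs <- character()
  if (!is.null(canonicalPairs) && nrow(canonicalPairs))
    pairs <- unname(apply(as.matrix(canonicalPairs[, 1:2]), 1, pairKey))
  list(canonical = unique(pairs), census = unique(censusGenes))
}

pairKey <- function(g) paste(sort(as.character(g)), collapse = "--")

#' Score fusion candidates on five evidence features
#'
#' Each candidate earns points for (i) junction plus spanning read support
#' (>= 10 reads: 3 points; 3-9: 2; 1-2: 1; 0: 0), (ii) membership of the
#' gene pair among canonical fusions (3 points), (iii) the number of fusion
#' callers reporting it (1 point per caller, capped at 3), (iv) either
#' partner in the cancer gene census (1 per partner, capped at 2) and
#' (v) recurrence in the cohort (1 point per additional sample carrying the
#' same unordered gene pair, capped at 2). A candidate is high confidence
#' when its total strictly exceeds the threshold (default 9); the maximum
#' attainable total under the default weights is 13.
#'
#' @param candidates data.frame: sample_id, gene5, gene3, junction_reads,
#'   spanning_mates, callers (semicolon-joined caller names).
#' @param knowledge a \code{\link{fusionKnowledge}} list.
#' @param weights the \code{fusionWeights} element of
#'   \code{\link{profilerConfig}}.
#' @param threshold high-confidence threshold, strict (default 9).
#' @return data.frame with per-feature points, total and high_confidence.
#' @export
scoreFusions <- function(candidates, knowledge = fusionKnowledge(),
                         weights = profilerConfig()$fusionWeights,
                         threshold = 9) {
  if (!nrow(candidates))
    return(cbind(candidates[0, , drop = FALSE],
                 data.frame(pts_reads = numeric(), pts_canonical = numeric(),
                            pts_callers = numeric(), pts_census = numeric(),
                            pts_recurrence = numeric(), total = numeric(),
                            high_confidence = logical())))
  if (any(candidates$junction_reads < 0) || any(candidates$spanning_mates < 0))
    stop("read counts must be non-negative")
  if (any(candidates$gene5 == candidates$gene3))
    stop("gene5 and gene3 must differ")
  reads <- candidates$junction_reads + candidates$spanning_mates
  pts_reads <- ifelse(reads >= 10, weights$readHigh,
                      ifelse(reads >= 3, weights$readMid,
                             ifelse(reads >= 1, weights$readLow, 0)))
  keys <- mapply(function(a, b) pairKey(c(a, b)),
                 candidates$gene5, candidates$gene3, USE.NAMES = FALSE)
  pts_canonical <- ifelse(keys %in% knowledge$canonical,
                          weights$canonical, 0)
  ncall <- lengths(strsplit(as.character(candidates$callers), ";",
                            fixed = TRUE))
  pts_callers <- pmin(ncall * weights$perCaller, weights$maxCallerPoints)
  census_hits <- (candidates$gene5 %in% knowledge$census) +
    (candidates$gene3 %in% knowledge$census)
  pts_census <- pmin(census_hits * weights$censusPerPartner,
                     weights$maxCensusPoints)
  # recurrence: distinct *other* samples in the cohort with the same pair
  n_samples_per_pair <- tapply(candidates$sample_id, keys,
                               function(s) length(unique(s)))
  pts_recurrence <- pmin((n_samples_per_pair[keys] - 1) *
                           weights$recurrencePerSample,
                         weights$maxRecurrencePoints)
  total <- pts_reads + pts_canonical + pts_callers + pts_census +
    pts_recurrence
  cbind(candidates,
        data.frame(pts_reads = pts_reads, pts_canonical = pts_canonical,
                   pts_callers = as.numeric(pts_callers),
                   pts_census = as.numeric(pts_census),
                   pts_recurrence = as.numeric(unname(pts_recurrence)),
                   total = as.numeric(unname(total)),
                   high_confidence = unname(total) > threshold,
                   row.names = NULL))
}

#' Rank fusion candidates by score
#'
#' Scores every candidate (recurrence computed over the whole input cohort
#' first) and orders descending by total, with deterministic tie-breaking by
#' caller count, read support, then gene-pair lexicographic order.
#'
#' @inheritParams scoreFusions
#' @return the scored data.frame, ordered.
#' @export
rankFusions <- function(candidates, knowledge = fusionKnowledge(),
                        weights = profilerConfig()$fusionWeights,
                        threshold = 9) {
  sc <- scoreFusions(candidates, knowledge, weights, threshold)
  if (!nrow(sc)) return(sc)
  reads <- sc$junction_reads + sc$spanning_mates
  ord <- order(-sc$total, -sc$pts_callers, -reads,
               paste(sc$gene5, sc$gene3))
  out <- sc[ord, ]
  rownames(out) <- NULL
  out
}
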