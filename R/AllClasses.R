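#' @title Core S4 classes
#' @name TMEprofiler-classes
#' @description S4 containers for immune signature collections, per-sample
#'   enrichment results, immune group assignments and somatic filter reports.
NULL

#' An immune gene-signature collection
#'
#' Named gene sets with an immunity-category label per set. The canonical
#' collection used for NSCLC immune profiling holds 26 signatures: 11 for
#' adaptive immune cell types, 12 for innate cell types and 3 others
#' (MDSC, angiogenesis, antigen presentation machinery).
#'
#' @slot sets named list of character vectors (gene identifiers), all non-empty.
#' @slot category named character vector, one of \code{"adaptive"},
#'   \code{"innate"}, \code{"other"} per set; names match \code{sets}.
#' @export
setClass("SignatureCollection",
         representation(sets = "list", category = "character"))

setValidity("SignatureCollection", function(object) {
  msgs <- character()
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msgs <- c(msgs, "signature names must be unique and non-empty")
  if (any(lengths(object@sets) == 0))
    msgs <- c(msgs, "every signature must contain at least one gene")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msgs <- c(msgs, "gene sets must be character vectors")
  if (!identical(sort(names(object@category)), sort(nm)))
    msgs <- c(msgs, "category must be named for exactly the signature names")
  if (!all(object@category %in% c("adaptive", "innate", "other")))
    msgs <- c(msgs, "categories must be adaptive/innate/other")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignatureCollection
#'
#' @param sets named list of character gene-id vectors.
#' @param category named character vector (\code{adaptive}/\code{innate}/
#'   \code{other}) covering every set; defaults every set to \code{"other"}.
#' @return A \linkS4class{SignatureCollection}.
#' @examples
#' sc <- SignatureCollection(list(T_cells = c("CD3E", "CD8A")),
#'                           c(T_cells = "adaptive"))
#' signatureNames(sc)
#' @export
SignatureCollection <- function(sets, category = NULL) {
  if (is.null(category))
    category <- setNames(rep("other", length(sets)), names(sets))
  new("SignatureCollection", sets = sets,
      category = category[names(sets)])
}

#' @describeIn SignatureCollection-class names of the signatures
#' @param x a \code{SignatureCollection}
#' @export
signatureNames <- function(x) names(x@sets)

#' @describeIn SignatureCollection-class the gene sets as a named list
#' @export
geneSets <- function(x) x@sets

#' @describeIn SignatureCollection-class per-signature immunity category
#' @export
signatureCategory <- function(x) x@category

setMethod("show", "SignatureCollection", function(object) {
  tab <- table(factor(object@category, c("adaptive", "innate", "other")))
  cat("SignatureCollection with", length(object@sets), "signatures\n")
  cat(sprintf("  adaptive: %d, innate: %d, other: %d\n",
              tab["adaptive"], tab["innate"], tab["other"]))
  cat("  set sizes:", paste(range(lengths(object@sets)), collapse = "-"),
      "genes\n")
})

#' @describeIn SignatureCollection-class number of signatures in the
#'   collection
#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' Per-sample gene-set enrichment results
#'
#' Long-form results of per-patient preranked gene-set enrichment: one row
#' per (sample, signature) with the running-sum enrichment score, its
#' permutation-normalized value, the permutation p-value, the
#' Benjamini-Hochberg q-value (adjusted within each sample across its
#' signature family) and the enrichment call \code{q <= qThreshold}.
#'
#' @slot table data.frame with columns sample, signature, es, nes, p, q,
#'   enriched.
#' @slot qThreshold numeric scalar in (0, 1].
#' @export
setClass("EnrichmentResult",
         representation(table = "data.frame", qThreshold = "numeric"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  need <- c("sample", "signature", "es", "nes", "p", "q", "enriched")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$p < 0 | tb$p > 1) || any(tb$q < 0 | tb$q > 1))
      return("p and q must lie in [0, 1]")
    if (any(tb$q + 1e-12 < tb$p))
      return("q must be >= p within each sample's signature family")
    if (!identical(tb$enriched, tb$q <= object@qThreshold))
      return("enriched flag must equal q <= qThreshold")
  }
  if (length(object@qThreshold) != 1 || object@qThreshold <= 0 ||
      object@qThreshold > 1)
    return("qThreshold must be a scalar in (0, 1]")
  TRUE
})

#' @describeIn EnrichmentResult-class the long-form result table
#' @param x an \code{EnrichmentResult}
#' @export
enrichmentTable <- function(x) x@table

#' @describeIn EnrichmentResult-class the q-value call threshold
#' @export
qThreshold <- function(x) x@qThreshold

setMethod("show", "EnrichmentResult", function(object) {
  tb <- object@table
  cat("EnrichmentResult:", length(unique(tb$sample)), "samples x",
      length(unique(tb$signature)), "signatures\n")
  cat(sprintf("  enriched calls (q <= %g): %d of %d pairs\n",
              object@qThreshold, sum(tb$enriched), nrow(tb)))
})

#' Immune group assignment (HIGH/MIX/LOW)
#'
#' Per-sample immune status labels produced by hierarchical clustering of
#' normalized ssGSEA scores with histology-specific refinement: the ADC high
#' cluster is split on T/B-cell signature levels, and SQCC MIX samples with
#' elevated T/B signatures and PD-1/CD8 expression are promoted to HIGH.
#'
#' @slot assignments data.frame with columns sample, group (HIGH/MIX/LOW),
#'   cluster_id, refinement_rule (none/adc_high_split/sqcc_mix_promotion).
#' @export
setClass("ImmuneGroupAssignment",
         representation(assignments = "data.frame"))

setValidity("ImmuneGroupAssignment", function(object) {
  a <- object@assignments
  need <- c("sample", "group", "cluster_id", "refinement_rule")
  if (!all(need %in% names(a)))
    return(paste("assignments needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$sample))
    return("every sample must be assigned exactly once")
  if (!all(a$group %in% c("HIGH", "MIX", "LOW")))
    return("groups must be HIGH, MIX or LOW")
  if (!all(a$refinement_rule %in%
           c("none", "adc_high_split", "sqcc_mix_promotion")))
    return("unknown refinement_rule")
  TRUE
})

#' @describeIn ImmuneGroupAssignment-class named factor of group labels
#' @param x an \code{ImmuneGroupAssignment}
#' @export
immuneGroups <- function(x)
  setNames(factor(x@assignments$group, c("HIGH", "MIX", "LOW")),
           x@assignments$sample)

#' @describeIn ImmuneGroupAssignment-class the full assignment table
#' @export
groupAssignments <- function(x) x@assignments

setMethod("show", "ImmuneGroupAssignment", function(object) {
  g <- table(factor(object@assignments$group, c("HIGH", "MIX", "LOW")))
  cat("ImmuneGroupAssignment for", nrow(object@assignments), "samples\n")
  cat(sprintf("  HIGH: %d, MIX: %d, LOW: %d\n", g["HIGH"], g["MIX"], g["LOW"]))
  nref <- sum(object@assignments$refinement_rule != "none")
  if (nref) cat("  refined samples:", nref, "\n")
})

#' Somatic filter cascade report
#'
#' Survivor counts after each stage of the somatic filter cascade:
#' minimum supporting reads, effect-class exclusion (synonymous/UTR),
#' matched-normal germline subtraction, population-database exclusion
#' (1000 Genomes / ExAC) and panel-of-normals removal.
#'
#' @slot counts named integer vector over stages input, min_reads,
#'   effect_class, matched_germline, popdb, panel_of_normals; monotone
#'   non-increasing.
#' @export
setClass("FilterReport", representation(counts = "integer"))

filterStages <- c("input", "min_reads", "effect_class",
                  "matched_germline", "popdb", "panel_of_normals")

setValidity("FilterReport", function(object) {
  if (!identical(names(object@counts), filterStages))
    return(paste("counts must be named:", paste(filterStages, collapse = ", ")))
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(diff(object@counts) > 0))
    return("counts must be monotone non-increasing through stages")
  TRUE
})

#' @describeIn FilterReport-class named per-stage survivor counts
#' @param x a \code{FilterReport}
#' @export
filterCounts <- function(x) x@counts

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport (variants surviving each stage)\n")
  for (s in filterStages)
    cat(sprintf("  %-17s %d\n", s, object@counts[s]))
})
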