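# most-deleterious-first order used to reconcile effect annotations
effectOrder <- c("nonsynonymous", "synonymous", "UTR", "other")

variantKey <- function(df, with_sample = TRUE) {
  if (with_sample)
    paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = "|")
  else
    paste(df$chrom, df$pos, df$ref, df$alt, sep = "|")
}

#' Merge per-caller variant calls into consensus records
#'
#' Calls sharing the merge key (sample, chrom, pos, ref, alt) are collapsed
#' to one record carrying the caller set, the maximum supporting-read count
#' across callers, the union of population-database flags and the
#' most-deleterious effect class (nonsynonymous > synonymous > UTR > other)
#' when annotations disagree. Two calls at the same (sample, chrom, pos)
#' with different REF alleles are an error.
#'
#' @param calls data.frame as from \code{\link{readVariantCalls}}.
#' @return data.frame of merged variants: sample_id, chrom, pos, ref, alt,
#'   caller_count, callers (semicolon-joined), max_supporting_reads,
#'   effect_class, popdb_1000g, popdb_exac.
#' @export
mergeCallerCalls <- function(calls) {
  if (!nrow(calls))
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      caller_count = integer(), callers = character(),
                      max_supporting_reads = integer(),
                      effect_class = character(), popdb_1000g = logical(),
                      popdb_exac = logical(), stringsAsFactors = FALSE))
  site <- paste(calls$sample_id, calls$chrom, calls$pos, sep = "|")
  refs_per_site <- tapply(calls$ref, site, function(r) length(unique(r)))
  if (any(refs_per_site > 1))
    stop("conflicting REF alleles at site ",
         names(refs_per_site)[which(refs_per_site > 1)[1]])
  key <- variantKey(calls)
  idx <- split(seq_len(nrow(calls)), key)
  merged <- lapply(idx, function(i) {
    callers <- sort(unique(calls$caller_id[i]))
    data.frame(
      sample_id = calls$sample_id[i[1]], chrom = calls$chrom[i[1]],
      pos = calls$pos[i[1]], ref = calls$ref[i[1]], alt = calls$alt[i[1]],
      caller_count = length(callers),
      callers = paste(callers, collapse = ";"),
      max_supporting_reads = max(calls$supporting_reads[i]),
      effect_class = effectOrder[min(match(calls$effect_class[i],
                                           effectOrder))],
      popdb_1000g = any(calls$popdb_1000g[i]),
      popdb_exac = any(calls$popdb_exac[i]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$sample_id, out$chrom, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Apply the four-step somatic filter cascade
#'
#' Stages, in order: (1a) remove variants with fewer than \code{minReads}
#' supporting reads (a variant with exactly \code{minReads} survives);
#' (1b) exclude synonymous and UTR variants; (2) subtract matched-normal
#' germline variants; (3) exclude variants present in the 1000 Genomes
#' project or ExAC; (4) remove panel-of-normals variants pooled from blood
#' samples. Re-applying the cascade to its own output changes nothing.
#'
#' @param merged data.frame from \code{\link{mergeCallerCalls}}.
#' @param germlineKeys character keys \code{"sample|chrom|pos|ref|alt"} of
#'   matched-normal variants.
#' @param ponKeys character keys \code{"chrom|pos|ref|alt"} of
#'   panel-of-normals variants (sample-independent).
#' @param minReads minimum supporting reads (default 8).
#' @return list with \code{variants} (the survivors) and \code{report}
#'   (a \linkS4class{FilterReport}).
#' @export
applySomaticFilters <- function(merged, germlineKeys = character(),
                                ponKeys = character(), minReads = 8L) {
  counts <- integer(length(filterStages))
  names(counts) <- filterStages
  cur <- merged
  counts["input"] <- nrow(cur)
  cur <- cur[cur$max_supporting_reads >= minReads, , drop = FALSE]
  counts["min_reads"] <- nrow(cur)
  cur <- cur[!cur$effect_class %in% c("synonymous", "UTR"), , drop = FALSE]
  counts["effect_class"] <- nrow(cur)
  cur <- cur[!variantKey(cur) %in% germlineKeys, , drop = FALSE]
  counts["matched_germline"] <- nrow(cur)
  cur <- cur[!(cur$popdb_1000g | cur$popdb_exac), , drop = FALSE]
  counts["popdb"] <- nrow(cur)
  cur <- cur[!variantKey(cur, with_sample = FALSE) %in% ponKeys, ,
             drop = FALSE]
  counts["panel_of_normals"] <- nrow(cur)
  rownames(cur) <- NULL
  list(variants = cur, report = new("FilterReport", counts = counts))
}

#' Tumor mutational burden per sample
#'
#' Post-filter variant counts divided by the interrogated exome size in Mb.
#'
#' @param filtered data.frame of filtered variants (needs sample_id,
#'   effect_class).
#' @param targetMb exome target size in megabases (> 0; default 38).
#' @param samples optional sample ids to report (zero burden for samples
#'   without variants); defaults to samples present in \code{filtered}.
#' @return data.frame: sample_id, total_per_mb, nonsyn_per_mb, target_mb.
#' @export
mutationBurden <- function(filtered, targetMb = 38, samples = NULL) {
  if (targetMb <= 0) stop("targetMb must be > 0")
  if (is.null(samples)) samples <- sort(unique(filtered$sample_id))
  tot <- table(factor(filtered$sample_id, samples))
  nonsyn <- table(factor(
    filtered$sample_id[filtered$effect_class == "nonsynonymous"], samples))
  data.frame(sample_id = samples,
             total_per_mb = as.numeric(tot) / targetMb,
             nonsyn_per_mb = as.numeric(nonsyn) / targetMb,
             target_mb = targetMb,
             stringsAsFactors = FALSE, row.names = NULL)
}

substitutionClasses <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# collapse a ref>alt SNV to its pyrimidine-reference class (G>T == C>A)
collapseSubstitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  paste0(ref, ">", alt)
}

#' Per-sample substitution-class spectrum
#'
#' Proportions of the six pyrimidine-reference single-nucleotide
#' substitution classes per sample; indels are ignored and purine-reference
#' substitutions are complemented (G>T counts as C>A). Samples with no SNV
#' are excluded with a warning.
#'
#' @param filtered data.frame of filtered variants.
#' @return samples x 6 matrix of proportions (rows sum to 1).
#' @export
substitutionSpectrum <- function(filtered) {
  snv <- filtered[nchar(filtered$ref) == 1 & nchar(filtered$alt) == 1 &
                    filtered$ref %in% c("A", "C", "G", "T") &
                    filtered$alt %in% c("A", "C", "G", "T"), , drop = FALSE]
  samples <- sort(unique(filtered$sample_id))
  cls <- collapseSubstitution(snv$ref, snv$alt)
  counts <- table(factor(snv$sample_id, samples),
                  factor(cls, substitutionClasses))
  none <- rowSums(counts) == 0
  if (any(none)) {
    warning("excluding ", sum(none), " sample(s) with zero SNVs")
    counts <- counts[!none, , drop = FALSE]
  }
  props <- sweep(unclass(counts), 1, rowSums(counts), "/")
  props
}

#' Compare substitution spectra between two groups
#'
#' Two-sample t-test per substitution class with Benjamini-Hochberg
#' adjustment across the six classes.
#'
#' @param spectra samples x classes proportion matrix
#'   (\code{\link{substitutionSpectrum}}).
#' @param groups named two-level factor/character vector over the spectrum's
#'   samples.
#' @return data.frame: class, mean_group1, mean_group2, t, p, q.
#' @export
compareSpectra <- function(spectra, groups) {
  groups <- factor(groups[rownames(spectra)])
  if (nlevels(groups) != 2) stop("compareSpectra needs exactly two groups")
  res <- lapply(colnames(spectra), function(cl) {
    x <- spectra[groups == levels(groups)[1], cl]
    y <- spectra[groups == levels(groups)[2], cl]
    tt <- stats::t.test(x, y)
    data.frame(class = cl, mean_group1 = mean(x), mean_group2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
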