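#' Gene-level 5-state copy-number calls from segmented data
#'
#' For each gene and sample, the length-weighted mean log2 ratio over the
#' segments overlapping the gene span is thresholded into the five states
#' -2 (homozygous deletion), -1 (heterozygous deletion), 0 (diploid),
#' +1 (heterozygous amplification), +2 (homozygous amplification).
#' GISTIC-convention default thresholds: <= -1.3 gives -2, <= -0.3 gives -1,
#' >= +0.9 gives +2, >= +0.3 gives +1, otherwise 0. Genes without any
#' covering segment in a sample are NA and flagged with a warning.
#'
#' @param segments SEG data.frame (\code{\link{readSegTable}}).
#' @param geneModel data.frame: gene, chrom, start, end (1-based inclusive).
#' @param thresholds named numeric vector \code{homdel}, \code{hetdel},
#'   \code{hetamp}, \code{homamp}.
#' @return integer matrix genes x samples of states in \{-2..2\}, NA where
#'   uncovered.
#' @export
geneCnvStatus <- function(segments, geneModel,
                          thresholds = profilerConfig()$cnvThresholds) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(geneModel)))
  samples <- sort(unique(segments$sample))
  genes_gr <- GenomicRanges::GRanges(
    geneModel$chrom, IRanges::IRanges(geneModel$start, geneModel$end))
  status <- matrix(NA_integer_, nrow(geneModel), length(samples),
                   dimnames = list(geneModel$gene, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    seg_gr <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start, seg$end))
    hits <- GenomicRanges::findOverlaps(genes_gr, seg_gr)
    if (!length(hits)) next
    ov <- IRanges::pintersect(genes_gr[S4Vectors::queryHits(hits)],
                              seg_gr[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    lr <- seg$log2_ratio[S4Vectors::subjectHits(hits)]
    wmean <- tapply(w * lr, S4Vectors::queryHits(hits), sum) /
      tapply(w, S4Vectors::queryHits(hits), sum)
    gi <- as.integer(names(wmean))
    status[gi, s] <- ifelse(
      wmean <= thresholds["homdel"], -2L,
      ifelse(wmean <= thresholds["hetdel"], -1L,
             ifelse(wmean >= thresholds["homamp"], 2L,
                    ifelse(wmean >= thresholds["hetamp"], 1L, 0L))))
  }
  if (anyNA(status))
    warning(sum(is.na(status)),
            " (gene, sample) pair(s) have no covering segment; set to NA")
  status
}

#' Decide whether two focal copy-number peaks are "similar"
#'
#' Two peaks match if their known target genes are equal (and non-missing),
#' or if they fall in the same cytoband and their genomic intervals overlap
#' after symmetrically padding each interval by 1 Mb. Peaks on different
#' chromosomes never match.
#'
#' @param a,b lists or one-row data.frames with chrom, start, end and
#'   optionally target_gene.
#' @param cytobands data.frame: chrom, start, end, band. A peak's band is
#'   the one containing its midpoint.
#' @param padBp padding added to each side of each peak (default 1e6).
#' @return logical; symmetric in its two arguments.
#' @export
peakSimilarity <- function(a, b, cytobands = NULL, padBp = 1e6) {
  ta <- if (!is.null(a$target_gene)) as.character(a$target_gene) else NA
  tb <- if (!is.null(b$target_gene)) as.character(b$target_gene) else NA
  if (!is.na(ta) && !is.na(tb) && nzchar(ta) && nzchar(tb) && ta == tb)
    return(TRUE)
  if (as.character(a$chrom) != as.character(b$chrom)) return(FALSE)
  sameBand <- TRUE
  if (!is.null(cytobands)) {
    band_of <- function(p) {
      mid <- (p$start + p$end) / 2
      hit <- cytobands$chrom == as.character(p$chrom) &
        cytobands$start <= mid & cytobands$end >= mid
      if (!any(hit)) NA_character_ else cytobands$band[which(hit)[1]]
    }
    ba <- band_of(a); bb <- band_of(b)
    sameBand <- !is.na(ba) && !is.na(bb) && ba == bb
  }
  if (!sameBand) return(FALSE)
  (a$start - padBp) <= (b$end + padBp) && (b$start - padBp) <= (a$end + padBp)
}
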