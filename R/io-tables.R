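#' Read a segmented copy-number (SEG) table
#'
#' Six-column tab-delimited SEG dialect with header. Both the classic header
#' (ID, chrom, loc.start, loc.end, num.mark, seg.mean) and the package's
#' canonical one (sample, chrom, start, end, log2_ratio, n_probes) are
#' accepted; columns are matched by name. Coordinates are 1-based inclusive.
#'
#' @param path SEG file.
#' @return data.frame with columns sample, chrom, start, end, log2_ratio,
#'   n_probes; per-sample, per-chromosome segments are checked for overlap.
#' @export
readSegTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  alias <- c(ID = "sample", id = "sample", loc.start = "start",
             loc.end = "end", seg.mean = "log2_ratio", num.mark = "n_probes",
             num_mark = "n_probes", chromosome = "chrom")
  nm <- names(df)
  hit <- nm %in% names(alias)
  nm[hit] <- alias[nm[hit]]
  names(df) <- nm
  need <- c("sample", "chrom", "start", "end", "log2_ratio", "n_probes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  validateSegTable(df)
  df
}

validateSegTable <- function(df) {
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("SEG coordinates must be finite")
  if (any(df$start >= df$end)) stop("SEG segments require start < end")
  if (any(df$start < 1)) stop("SEG coordinates are 1-based (start >= 1)")
  for (key in split(seq_len(nrow(df)), paste(df$sample, df$chrom))) {
    if (length(key) < 2) next
    o <- key[order(df$start[key])]
    if (any(df$start[o][-1] <= df$end[o][-length(o)]))
      stop("overlapping segments for sample ", df$sample[o[1]],
           " chrom ", df$chrom[o[1]])
  }
  invisible(TRUE)
}

#' Write a SEG table
#' @param seg data.frame as returned by \code{\link{readSegTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSegTable <- function(seg, path) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the clinical table
#'
#' Tab-delimited with header; required columns: sample, histology (ADC/SQCC),
#' age, sex, stage, smoking (smoker/non-smoker), os_days, os_event (0/1),
#' treatment. Sub-stage labels (IA, IIIB, ...) are collapsed to their major
#' Roman-numeral stage.
#'
#' @param path TSV file.
#' @return data.frame with normalized stage labels.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "histology", "age", "sex", "stage", "smoking",
            "os_days", "os_event", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in clinical table")
  bad <- setdiff(unique(df$histology), c("ADC", "SQCC"))
  if (length(bad))
    stop("unknown histology label(s): ", paste(bad, collapse = ", "))
  df$stage <- normalizeStage(df$stage)
  bad <- setdiff(unique(df$smoking), c("smoker", "non-smoker"))
  if (length(bad))
    stop("unknown smoking label(s): ", paste(bad, collapse = ", "))
  if (any(df$os_days < 0)) stop("os_days must be non-negative")
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  df
}

#' Collapse clinical sub-stages to major Roman-numeral stage
#'
#' \code{"IIIA"} becomes \code{"III"}; unknown labels are errors.
#'
#' @param stage character vector of stage labels.
#' @return character vector over I/II/III/IV.
#' @export
normalizeStage <- function(stage) {
  s <- sub("[AB]$", "", toupper(trimws(stage)))
  bad <- setdiff(unique(s), c("I", "II", "III", "IV"))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  s
}

#' Write the clinical table
#' @param clin data.frame as from \code{\link{readClinicalTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClinicalTable <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
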