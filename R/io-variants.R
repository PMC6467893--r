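#' Read per-caller somatic variant calls from VCF files
#'
#' One VCF per caller; every record of every file becomes one call row (the
#' union is merged later by \code{\link{mergeCallerCalls}}). "Supporting
#' reads" is the ALT allelic depth taken from a configurable FORMAT key
#' (default \code{AD}, \code{ref,alt} encoded); a record lacking the key is
#' kept with \code{supporting_reads = 0} and a warning, so the minimum-read
#' filter removes it deterministically. The effect class comes from a
#' configurable INFO key and population-database membership from the INFO
#' flags \code{KG1000} (1000 Genomes) and \code{EXAC}.
#'
#' @param paths character vector of VCF paths.
#' @param callerIds caller label per file (same length as \code{paths}).
#' @param depthKey FORMAT key holding allelic depths (default \code{"AD"}).
#' @param effectKey INFO key holding the effect class (default \code{"EFF"};
#'   values outside nonsynonymous/synonymous/UTR map to \code{"other"}).
#' @return data.frame of calls: sample_id, chrom, pos, ref, alt, caller_id,
#'   supporting_reads, effect_class, popdb_1000g, popdb_exac.
#' @export
readVariantCalls <- function(paths, callerIds, depthKey = "AD",
                             effectKey = "EFF") {
  stopifnot(length(paths) == length(callerIds))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    v <- vcfR::read.vcfR(paths[i], verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    n <- nrow(fix)
    if (n == 0) { out[[i]] <- NULL; next }
    sample_id <- colnames(v@gt)[2]
    if (is.null(sample_id)) stop("VCF has no sample column: ", paths[i])
    ad <- tryCatch(vcfR::extract.gt(v, element = depthKey),
                   error = function(e) NULL)
    reads <- rep(0L, n)
    if (!is.null(ad)) {
      alt_depth <- suppressWarnings(as.integer(
        vapply(strsplit(as.character(ad[, 1]), ",", fixed = TRUE),
               function(x) if (length(x) >= 2) x[2] else NA_character_,
               character(1))))
      missing_ad <- is.na(alt_depth)
      reads[!missing_ad] <- alt_depth[!missing_ad]
      if (any(missing_ad))
        warning(sum(missing_ad), " record(s) in ", basename(paths[i]),
                " lack FORMAT/", depthKey,
                "; supporting_reads set to 0")
    } else {
      warning("FORMAT/", depthKey, " absent in ", basename(paths[i]),
              "; supporting_reads set to 0 for all records")
    }
    info <- fix[, "INFO"]
    eff <- sub(paste0(".*(?:^|;)", effectKey, "=([^;]+).*"), "\\1", info)
    eff[!grepl(paste0("(^|;)", effectKey, "="), info)] <- "other"
    eff[!eff %in% c("nonsynonymous", "synonymous", "UTR")] <- "other"
    out[[i]] <- data.frame(
      sample_id = sample_id,
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = as.character(fix[, "REF"]),
      alt = as.character(fix[, "ALT"]),
      caller_id = callerIds[i],
      supporting_reads = reads,
      effect_class = eff,
      popdb_1000g = grepl("(^|;)KG1000(;|$)", info),
      popdb_exac = grepl("(^|;)EXAC(;|$)", info),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      caller_id = character(), supporting_reads = integer(),
                      effect_class = character(), popdb_1000g = logical(),
                      popdb_exac = logical(), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  if (any(res$pos < 1)) stop("VCF positions must be >= 1")
  if (any(res$ref == res$alt)) stop("REF must differ from ALT")
  res
}

#' Write a single sample/caller's calls as a minimal VCF 4.2 file
#'
#' The writer used by the synthetic cohort generator and the round-trip
#' tests; encodes supporting reads as FORMAT \code{AD} (\code{ref,alt}),
#' effect class as INFO \code{EFF=} and population-database membership as
#' the INFO flags \code{KG1000}/\code{EXAC}.
#'
#' @param calls data.frame with the columns produced by
#'   \code{\link{readVariantCalls}}, one sample and one caller only.
#' @param path output VCF path.
#' @return \code{path}, invisibly.
#' @export
writeVariantCalls <- function(calls, path) {
  stopifnot(length(unique(calls$sample_id)) <= 1,
            length(unique(calls$caller_id)) <= 1)
  sample_id <- if (nrow(calls)) calls$sample_id[1] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=TMEprofiler_", if (nrow(calls)) calls$caller_id[1] else "caller"),
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=KG1000,Number=0,Type=Flag,Description=\"Present in 1000 Genomes\">",
    "##INFO=<ID=EXAC,Number=0,Type=Flag,Description=\"Present in ExAC\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    info <- paste0("EFF=", calls$effect_class,
                   ifelse(calls$popdb_1000g, ";KG1000", ""),
                   ifelse(calls$popdb_exac, ";EXAC", ""))
    gt <- paste0("0/1:", pmax(0L, 30L - calls$supporting_reads), ",",
                 calls$supporting_reads)
    ord <- order(calls$chrom, calls$pos)
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "GT:AD", gt, sep = "\t")[ord]
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
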