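#' Read immune gene signatures from a GMT file
#'
#' Parses the tab-delimited GMT dialect (set name, description, then one gene
#' per field). Categories come either from a named character vector or from a
#' two-column TSV sidecar (signature, category).
#'
#' @param path GMT file.
#' @param categories named character vector mapping signature name to
#'   \code{adaptive}/\code{innate}/\code{other}, or the path of a two-column
#'   headerless TSV with those mappings. Signatures absent from the mapping
#'   default to \code{"other"}.
#' @return A \linkS4class{SignatureCollection}.
#' @export
readGeneSets <- function(path, categories = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT parse error: line ", bad[1],
         " has no genes (need name, description, >=1 gene)")
  nm <- vapply(fields, `[[`, character(1), 1)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate gene-set name(s) in GMT: ", paste(unique(dup), collapse = ", "))
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    unique(g)
  })
  names(sets) <- nm
  empty <- which(lengths(sets) == 0)
  if (length(empty))
    stop("GMT parse error: line ", empty[1], " has no genes")
  if (is.character(categories) && length(categories) == 1 &&
      is.null(names(categories)) && file.exists(categories)) {
    tab <- utils::read.delim(categories, header = FALSE,
                             col.names = c("signature", "category"),
                             colClasses = "character")
    categories <- setNames(tab$category, tab$signature)
  }
  cat_full <- setNames(rep("other", length(sets)), nm)
  if (!is.null(categories)) {
    known <- intersect(names(categories), nm)
    cat_full[known] <- categories[known]
  }
  SignatureCollection(sets, cat_full)
}

#' Write a SignatureCollection to GMT (plus optional category sidecar)
#'
#' @param x a \linkS4class{SignatureCollection}.
#' @param path output GMT path.
#' @param categoryPath optional path for a two-column TSV of categories.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(x, path, categoryPath = NULL) {
  lines <- vapply(signatureNames(x), function(n)
    paste(c(n, "na", geneSets(x)[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  if (!is.null(categoryPath))
    utils::write.table(
      data.frame(signature = signatureNames(x),
                 category = unname(signatureCategory(x))),
      categoryPath, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}
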