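#' Read an FPKM expression matrix from TSV
#'
#' First column = gene identifiers, header = sample identifiers, cells =
#' non-negative FPKM. Duplicate gene rows are collapsed to their per-sample
#' maximum with a warning; negative or non-numeric cells are errors.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3) stop("expression matrix needs >= 2 sample columns")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    stop(sprintf("negative FPKM at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup),
            " duplicated gene id(s) by per-sample maximum: ",
            paste(utils::head(dup, 5), collapse = ", "))
    num <- do.call(rbind, lapply(split(seq_along(genes), genes)[unique(genes)],
                                 function(i)
                                   apply(num[i, , drop = FALSE], 2, max)))
  }
  if (anyDuplicated(colnames(num))) stop("duplicate sample identifiers")
  validateExpressionMatrix(num)
  num
}

#' Write an expression matrix as TSV (first column \code{gene})
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared invariants for an in-memory expression matrix
validateExpressionMatrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (nrow(expr) < 2 || ncol(expr) < 2)
    stop("expression matrix needs >= 2 genes and >= 2 samples")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample identifiers")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("FPKM values must be finite and non-negative")
  invisible(TRUE)
}
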