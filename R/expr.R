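#' Construct a validated expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix of
#' log2-scale values with genes in rows and samples in columns. Row names
#' carry gene symbols; an optional parallel vector of Entrez IDs is stored
#' in the \code{"entrez"} attribute (\code{NA} where unknown). All
#' downstream operations (differential expression, scoring, PCA) accept the
#' object returned here.
#'
#' @param values numeric matrix, genes x samples, log2 scale, row names =
#'   gene symbols, column names = sample identifiers.
#' @param entrez optional character or integer vector of Entrez gene IDs,
#'   one per row (\code{NA} allowed).
#' @param collapse_duplicates collapse duplicated gene symbols by their
#'   per-sample mean (default \code{TRUE}). The number of collapsed rows is
#'   reported with a message.
#' @return a numeric matrix of class \code{"expr_matrix"} with an
#'   \code{"entrez"} attribute.
#' @export
expr_matrix <- function(values, entrez = NULL, collapse_duplicates = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("expression matrix needs >= 1 gene and >= 2 samples")
  if (is.null(rownames(values)) || anyNA(rownames(values)) || any(rownames(values) == ""))
    stop("row names (gene symbols) are required")
  if (is.null(colnames(values)))
    stop("column names (sample identifiers) are required")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (!is.null(entrez)) {
    if (length(entrez) != nrow(values))
      stop("`entrez` must have one entry per gene row")
    entrez <- as.character(entrez)
  }
  if (collapse_duplicates && anyDuplicated(rownames(values))) {
    sym <- rownames(values)
    n_dup <- sum(duplicated(sym))
    grp <- match(sym, sym)             # first-occurrence index per symbol
    values <- rowsum(values, group = grp, reorder = FALSE) /
      as.vector(table(factor(grp, levels = unique(grp))))
    keep <- !duplicated(sym)
    rownames(values) <- sym[keep]
    if (!is.null(entrez)) entrez <- entrez[keep]
    message(n_dup, " duplicated gene row(s) collapsed by mean")
  }
  structure(values, entrez = entrez, class = c("expr_matrix", class(values)))
}

#' Entrez IDs attached to an expression matrix or signature
#' @param x an \code{expr_matrix} or \code{gene_signature}.
#' @return character vector of Entrez IDs, or \code{NULL} if none attached.
#' @export
entrez_ids <- function(x) {
  if (inherits(x, "gene_signature")) return(x$entrez)
  attr(x, "entrez")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x), " genes x ", ncol(x), " samples (log2 scale)\n", sep = "")
  cat("  entrez IDs: ", if (is.null(attr(x, "entrez"))) "absent" else "present", "\n", sep = "")
  invisible(x)
}

# drop the class when subsetting; callers re-wrap if needed
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  y <- NextMethod()
  y
}
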