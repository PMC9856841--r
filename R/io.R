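#' Read an expression matrix from TSV
#'
#' Expected layout: a header line, first column gene symbols, an optional
#' second column named \code{entrez}, remaining columns one per sample with
#' numeric log2-scale values. Lines starting with \code{#} are treated as
#' comments (the package's own writers emit one). Duplicate gene symbols
#' are collapsed by mean and the number of collapsed rows is reported.
#'
#' @param path path to a tab-separated file.
#' @return an \code{\link{expr_matrix}}.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression TSV needs a symbol column and >= 2 samples")
  sym <- as.character(df[[1L]])
  entrez <- NULL
  first_sample <- 2L
  if (tolower(names(df)[2L]) == "entrez") {
    entrez <- as.character(df[[2L]])
    first_sample <- 3L
  }
  vals <- df[, first_sample:ncol(df), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric expression value at row %d, column '%s'",
                   bad[1L], names(vals)[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- sym
  expr_matrix(m, entrez = entrez)
}

#' Write an expression matrix to TSV
#'
#' Emits a single comment header line with the package version so runs are
#' traceable, then \code{symbol}, optional \code{entrez}, and one column per
#' sample. Round-trips losslessly through \code{\link{read_expression}} up
#' to numeric formatting.
#'
#' @param x an \code{\link{expr_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path) {
  entrez <- attr(x, "entrez")
  df <- data.frame(symbol = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(entrez)) df$entrez <- entrez
  df <- cbind(df, as.data.frame(unclass(x), check.names = FALSE))
  .write_tsv(df, path)
}

#' Read a clinical table from TSV
#'
#' Required columns: \code{sample}, \code{time} (positive, one unit per
#' cohort), \code{event} (1 = event, 0 = censored). Optional: \code{race},
#' \code{dataset}; any other columns are preserved as annotations.
#' Violations are reported with the offending row.
#'
#' @param path path to a tab-separated file.
#' @return a \code{data.frame} with validated survival fields.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicated sample IDs: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  df$time <- as.numeric(df$time)
  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad)) stop(sprintf("non-positive or missing time at row %d", bad[1L]))
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad)) stop(sprintf("event must be 0 or 1; offending row %d", bad[1L]))
  df$event <- as.integer(df$event)
  df
}

#' Write a clinical table to TSV
#' @param df a clinical \code{data.frame} (see \code{\link{read_clinical}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clinical <- function(df, path) {
  lead <- intersect(c("sample", "time", "event", "race", "dataset"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  .write_tsv(df, path)
}

# deterministic column order, one version comment line
.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sigsurv ", as.character(utils::packageVersion("sigsurv"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
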