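#' Construct a gene signature with signed unit weights
#'
#' A signature is a set of genes with weights \eqn{W_i \in \{+1, -1\}} and a
#' variant tag. Directional variants (\code{Up}, \code{Dn}, \code{NoDir})
#' carry only +1 weights; the full \code{Sig} variant weights each gene by
#' the sign of its source log2 fold change.
#'
#' @param symbol gene symbols (unique).
#' @param weight numeric weights, all +1 or -1.
#' @param entrez optional Entrez IDs (\code{NA} allowed).
#' @param log2fc optional source log2 fold changes.
#' @param variant one of \code{"Sig"}, \code{"NoDir"}, \code{"Up"},
#'   \code{"Dn"}, or a free label for user-defined sets.
#' @return a \code{data.frame} of class \code{"gene_signature"} with
#'   attribute \code{variant}.
#' @export
gene_signature <- function(symbol, weight, entrez = NULL, log2fc = NULL,
                           variant = "Sig") {
  if (!length(symbol)) stop("empty signature")
  if (anyDuplicated(symbol))
    stop("duplicate genes in signature: ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  if (length(weight) != length(symbol)) stop("one weight per gene required")
  if (!all(weight %in% c(-1, 1))) stop("weights must be +1 or -1")
  if (variant %in% c("NoDir", "Up", "Dn") && any(weight != 1))
    stop("variant ", variant, " admits only +1 weights")
  out <- data.frame(
    symbol = as.character(symbol),
    entrez = if (is.null(entrez)) NA_character_ else as.character(entrez),
    weight = as.numeric(weight),
    log2fc = if (is.null(log2fc)) NA_real_ else as.numeric(log2fc),
    stringsAsFactors = FALSE)
  structure(out, variant = variant, class = c("gene_signature", "data.frame"))
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", attr(x, "variant"), "': ", nrow(x), " genes (",
      sum(x$weight > 0), " at +1, ", sum(x$weight < 0), " at -1)\n", sep = "")
  invisible(x)
}

#' Build the four signature variants from a filtered DE table
#'
#' From a filtered differential-expression table (see
#' \code{\link{filter_signature_genes}}) builds: \code{Sig} — all genes,
#' weight = sign of log2FC; \code{NoDir} — all genes at +1; \code{Up} —
#' upregulated genes at +1; \code{Dn} — downregulated genes at +1. A variant
#' with no members (e.g. \code{Dn} when every gene is up) is omitted with a
#' warning.
#'
#' @param filtered a non-empty \code{de_table} carrying \code{direction}.
#' @param prefix name prefix for the variants (cosmetic).
#' @return named list of \code{\link{gene_signature}} objects.
#' @export
build_signatures <- function(filtered, prefix = "Sig") {
  if (!nrow(filtered)) stop("empty filtered DE table")
  up <- filtered$direction == "up"
  sigs <- list(
    Sig = gene_signature(filtered$symbol, ifelse(up, 1, -1),
                         filtered$entrez, filtered$log2fc, variant = "Sig"),
    NoDir = gene_signature(filtered$symbol, rep(1, nrow(filtered)),
                           filtered$entrez, filtered$log2fc, variant = "NoDir"))
  if (any(up)) {
    sigs$Up <- gene_signature(filtered$symbol[up], rep(1, sum(up)),
                              filtered$entrez[up], filtered$log2fc[up],
                              variant = "Up")
  } else warning("no upregulated genes: Up variant omitted")
  if (any(!up)) {
    sigs$Dn <- gene_signature(filtered$symbol[!up], rep(1, sum(!up)),
                              filtered$entrez[!up], filtered$log2fc[!up],
                              variant = "Dn")
  } else warning("no downregulated genes: Dn variant omitted")
  sigs
}

#' Map signature genes onto an expression matrix
#'
#' Members are matched by Entrez ID when both the signature and the matrix
#' carry one, otherwise by gene symbol. Unmatched members are dropped and
#' counted; coverage below 50% raises a warning, zero coverage is an error.
#'
#' @param sig a \code{\link{gene_signature}}.
#' @param expr an \code{\link{expr_matrix}}.
#' @return list: \code{signature} (matched members, with \code{row} index
#'   into \code{expr}), \code{n_matched}, \code{n_missing}, \code{coverage}.
#' @export
map_genes <- function(sig, expr) {
  mat_entrez <- attr(expr, "entrez")
  idx <- rep(NA_integer_, nrow(sig))
  if (!is.null(mat_entrez)) {
    has_e <- !is.na(sig$entrez)
    idx[has_e] <- match(sig$entrez[has_e], mat_entrez)
  }
  no_hit <- is.na(idx)
  idx[no_hit] <- match(sig$symbol[no_hit], rownames(expr))
  matched <- !is.na(idx)
  if (!any(matched)) stop("no signature gene found in the expression matrix")
  coverage <- mean(matched)
  if (coverage < 0.5)
    warning(sprintf("signature coverage %.0f%% (< 50%%)", 100 * coverage))
  out <- sig[matched, , drop = FALSE]
  out$row <- idx[matched]
  list(signature = out, n_matched = sum(matched),
       n_missing = sum(!matched), coverage = coverage)
}

#' Per-sample module score
#'
#' The module score of a sample is the weight-normalized sum
#' \eqn{s = \sum_i W_i X_i / \sum_i |W_i|} over the signature genes present
#' in the matrix, with \eqn{X_i} the gene's log2 expression and
#' \eqn{W_i = \pm 1}. The denominator uses the total weight magnitude, so
#' the score is the mean expression of +1 genes minus the mean-weighted
#' contribution of -1 genes and stays finite for balanced signatures.
#' Duplicate gene rows are collapsed by mean before scoring.
#'
#' @param expr an \code{\link{expr_matrix}}.
#' @param sig a \code{\link{gene_signature}}.
#' @return a \code{data.frame} of class \code{"score_vector"}: \code{sample},
#'   \code{raw}; attributes \code{n_genes_used}, \code{n_genes_missing},
#'   \code{variant}.
#' @export
module_score <- function(expr, sig) {
  mp <- map_genes(sig, expr)
  s <- mp$signature
  x <- unclass(expr)[s$row, , drop = FALSE]
  raw <- as.numeric(crossprod(x, s$weight)) / sum(abs(s$weight))
  structure(data.frame(sample = colnames(expr), raw = raw,
                       stringsAsFactors = FALSE),
            n_genes_used = mp$n_matched, n_genes_missing = mp$n_missing,
            variant = attr(sig, "variant"),
            class = c("score_vector", "data.frame"))
}

#' Rescale scores to fixed quantile anchors
#'
#' Affine rescaling so that the empirical 2.5% and 97.5% quantiles of the
#' raw scores map to -1 and +1:
#' \eqn{s' = 2 (s - q_{low}) / (q_{high} - q_{low}) - 1}. Values beyond the
#' anchors are retained (no clipping), and sample ranking is preserved
#' exactly. Quantiles use the linear-interpolation convention (type 7).
#'
#' @param x a \code{score_vector} from \code{\link{module_score}}, or a
#'   plain numeric vector of raw scores.
#' @param anchors two quantile fractions in (0, 1), low < high.
#' @param type quantile algorithm passed to \code{\link[stats]{quantile}}.
#' @return same shape as the input with scaled values: a
#'   \code{score_vector} gains a \code{scaled} column; a numeric vector is
#'   returned scaled. Attributes \code{q_low}, \code{q_high},
#'   \code{anchors}, \code{quantile_type} record the map.
#' @export
rescale_scores <- function(x, anchors = c(0.025, 0.975), type = 7) {
  if (length(anchors) != 2L || any(anchors <= 0) || any(anchors >= 1) ||
      anchors[1L] >= anchors[2L])
    stop("anchors must be two fractions in (0, 1) with low < high")
  raw <- if (inherits(x, "score_vector")) x$raw else as.numeric(x)
  if (sum(!duplicated(raw)) < 2L) stop("scores are (near-)constant; cannot rescale")
  q <- stats::quantile(raw, anchors, type = type, names = FALSE)
  if (q[1L] >= q[2L]) stop("quantile anchors coincide; cannot rescale")
  scaled <- 2 * (raw - q[1L]) / (q[2L] - q[1L]) - 1
  if (inherits(x, "score_vector")) {
    x$scaled <- scaled
    attr(x, "q_low") <- q[1L]; attr(x, "q_high") <- q[2L]
    attr(x, "anchors") <- anchors; attr(x, "quantile_type") <- type
    x
  } else {
    structure(scaled, q_low = q[1L], q_high = q[2L], anchors = anchors,
              quantile_type = type, names = names(x))
  }
}

#' @export
print.score_vector <- function(x, ...) {
  cat("score_vector: ", nrow(x), " samples, ", attr(x, "n_genes_used"),
      " genes used (", attr(x, "n_genes_missing"), " missing)",
      if (!is.null(x$scaled)) ", rescaled", "\n", sep = "")
  invisible(x)
}

#' Write / read a signature as CSV
#'
#' Columns \code{variant}, \code{symbol}, \code{entrez}, \code{weight},
#' \code{log2fc}; a list of variants is stacked into one file.
#'
#' @param sigs a \code{gene_signature} or named list of them.
#' @param path output path.
#' @return \code{path} invisibly (write); named list of signatures (read).
#' @export
write_signatures <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  rows <- do.call(rbind, lapply(sigs, function(s)
    cbind(variant = attr(s, "variant"), as.data.frame(s))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(entrez = "character"))
  out <- lapply(split(df, df$variant), function(d)
    gene_signature(d$symbol, d$weight, d$entrez, d$log2fc,
                   variant = d$variant[1L]))
  out[unique(df$variant)]
}
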