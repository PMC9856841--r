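#' Per-gene two-group t-test with fold changes
#'
#' Two-sided Student t-test (pooled variance by default, Welch optional) per
#' gene between two arms of a log2-scale expression matrix. The log2 fold
#' change is mean(treatment) - mean(reference) where the reference arm is
#' the first level of \code{groups}; linear fold change is its base-2
#' antilog. No multiple-testing correction is applied to the p-values used
#' downstream — the filter cascade deliberately works on nominal p — but a
#' Benjamini-Hochberg column (\code{padj}) is included for users.
#'
#' @param expr an \code{\link{expr_matrix}} (log2 values).
#' @param groups vector of length \code{ncol(expr)} with exactly two levels;
#'   the first level is the reference (control) arm, the second the
#'   treatment/overexpression arm.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return a \code{data.frame} of class \code{"de_table"}: \code{symbol},
#'   \code{entrez}, \code{mean_a}, \code{mean_b}, \code{log2fc},
#'   \code{fc_linear}, \code{t}, \code{df}, \code{p_value}, \code{padj},
#'   \code{direction}. Genes constant across all samples get \code{p = 1}
#'   with a warning.
#' @export
de_ttest <- function(expr, groups, var_equal = TRUE) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(expr))
    stop("`groups` must have one label per sample")
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  na <- sum(groups == levels(groups)[1L])
  nb <- sum(groups == levels(groups)[2L])
  if (na < 2L || nb < 2L) stop("each group needs >= 2 samples")

  a <- expr[, groups == levels(groups)[1L], drop = FALSE]
  b <- expr[, groups == levels(groups)[2L], drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  var_a <- apply(a, 1L, stats::var)
  var_b <- apply(b, 1L, stats::var)

  if (var_equal) {
    sp2 <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(expr))
  } else {
    se <- sqrt(var_a / na + var_b / nb)
    df <- (var_a / na + var_b / nb)^2 /
      ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
  }
  tstat <- (mean_b - mean_a) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  flat <- is.nan(tstat)                 # constant across all samples: 0/0
  if (any(flat)) {
    warning(sum(flat), " constant gene(s): p set to 1")
    tstat[flat] <- 0
    p[flat] <- 1
  }
  p[is.infinite(tstat)] <- 0            # zero within-group variance, nonzero shift
  log2fc <- mean_b - mean_a
  entrez <- attr(expr, "entrez")
  out <- data.frame(
    symbol = rownames(expr),
    entrez = if (is.null(entrez)) NA_character_ else entrez,
    mean_a = mean_a, mean_b = mean_b,
    log2fc = log2fc, fc_linear = 2^log2fc,
    t = tstat, df = df, p_value = p,
    padj = stats::p.adjust(p, "BH"),
    direction = ifelse(log2fc > 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Signature-gene filter cascade
#'
#' Shortlists genes for the signature: keep a gene if it is nominally
#' significant AND its fold change passes the primary threshold in either
#' direction (ratio \eqn{\ge} fc_thresh or \eqn{\le} 1/fc_thresh), OR if its
#' fold change passes the larger rescue threshold regardless of p-value.
#' Inequalities on p are strict (p < 0.05, not \eqn{\le}).
#'
#' @param de a \code{de_table} from \code{\link{de_ttest}}.
#' @param p_thresh nominal p-value threshold (default 0.05).
#' @param fc_thresh primary linear fold-change threshold (default 2).
#' @param rescue_fc rescue fold-change threshold applied without regard to
#'   p (default 4).
#' @return the kept rows of \code{de}, same class, with a logical
#'   \code{rescued} column marking genes kept only by the rescue branch.
#' @export
filter_signature_genes <- function(de, p_thresh = 0.05, fc_thresh = 2,
                                   rescue_fc = 4) {
  if (!nrow(de)) stop("empty DE table")
  if (p_thresh <= 0 || fc_thresh <= 0 || rescue_fc <= 0)
    stop("thresholds must be positive")
  beyond <- function(fc, thr) fc >= thr | fc <= 1 / thr
  primary <- de$p_value < p_thresh & beyond(de$fc_linear, fc_thresh)
  rescue <- beyond(de$fc_linear, rescue_fc)
  keep <- primary | rescue
  out <- de[keep, , drop = FALSE]
  out$rescued <- (rescue & !primary)[keep]
  rownames(out) <- NULL
  out
}

#' Volcano table
#'
#' Tabulates each gene's log2 fold change against \eqn{-\log_{10} p}, with a
#' significance flag identical to membership in
#' \code{\link{filter_signature_genes}} under the same thresholds.
#'
#' @inheritParams filter_signature_genes
#' @param cap upper bound for \eqn{-\log_{10} p} (applies at p = 0).
#' @return data.frame: \code{symbol}, \code{log2fc}, \code{neg_log10_p},
#'   \code{significant}.
#' @export
volcano_table <- function(de, p_thresh = 0.05, fc_thresh = 2, rescue_fc = 4,
                          cap = 300) {
  kept <- filter_signature_genes(de, p_thresh, fc_thresh, rescue_fc)$symbol
  data.frame(symbol = de$symbol,
             log2fc = de$log2fc,
             neg_log10_p = pmin(-log10(de$p_value), cap),
             significant = de$symbol %in% kept,
             stringsAsFactors = FALSE)
}

#' PCA quality control of samples
#'
#' Principal components of the samples after per-gene centering (no
#' scaling), as routinely used to check that the two arms of an experiment
#' separate on the leading components.
#'
#' @param expr an \code{\link{expr_matrix}} with >= 3 samples.
#' @param k number of components to return coordinates for.
#' @return list of class \code{"pca_qc"}: \code{coords} (samples x k),
#'   \code{variance_fraction} (all components, non-increasing, sums to 1).
#' @export
pca_qc <- function(expr, k = 2L) {
  if (ncol(expr) < 3L) stop("PCA QC needs >= 3 samples")
  pc <- stats::prcomp(t(unclass(expr)), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  vf <- x$variance_fraction
  cat("PCA QC: ", nrow(x$coords), " samples; PC1 ",
      sprintf("%.1f%%", 100 * vf[1L]), ", PC2 ",
      sprintf("%.1f%%", 100 * vf[2L]), " of variance\n", sep = "")
  invisible(x)
}
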