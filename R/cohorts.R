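#' Evaluate signature(s) on a survival cohort
#'
#' Full per-cohort pipeline: map each signature onto the expression matrix,
#' compute module scores, rescale them to the cohort's own 2.5%/97.5%
#' quantile anchors, dichotomize by each requested cutoff method, and fit
#' the univariate Cox model. One result row per (variant, method).
#'
#' @param expr an \code{\link{expr_matrix}} for the cohort.
#' @param clinical data.frame with \code{sample}, \code{time}, \code{event}
#'   (see \code{\link{read_clinical}}).
#' @param sigs a \code{\link{gene_signature}} or named list of them (e.g.
#'   from \code{\link{build_signatures}}).
#' @param cutoff cutoff method(s), \code{"optimal"} and/or \code{"median"}.
#' @param dataset label recorded in the result rows.
#' @param eps,p_method,n_perm,seed forwarded to the optimal-cutpoint search.
#' @return data.frame of class \code{"cohort_result"}: \code{dataset},
#'   \code{variant}, \code{method}, \code{cutpoint}, \code{hazard_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{wald_p}, \code{logrank_p},
#'   \code{n}, \code{n_events}, \code{n_genes_used}.
#' @export
evaluate_signature_on_cohort <- function(expr, clinical, sigs,
                                         cutoff = c("optimal", "median"),
                                         dataset = "cohort", eps = 0.1,
                                         p_method = "approximation",
                                         n_perm = 1000L, seed = NULL) {
  cutoff <- match.arg(cutoff, several.ok = TRUE)
  if (inherits(sigs, "gene_signature"))
    sigs <- stats::setNames(list(sigs), attr(sigs, "variant"))
  common <- intersect(colnames(expr), clinical$sample)
  if (length(common) < 20L)
    stop("only ", length(common), " overlapping samples (need >= 20)")
  expr <- expr_matrix(unclass(expr)[, common, drop = FALSE],
                      entrez = attr(expr, "entrez"))
  clin <- clinical[match(common, clinical$sample), , drop = FALSE]

  rows <- list()
  for (v in names(sigs)) {
    sc <- rescale_scores(module_score(expr, sigs[[v]]))
    for (m in cutoff) {
      g <- dichotomize(sc$scaled, method = m, time = clin$time,
                       event = clin$event, eps = eps, p_method = p_method,
                       n_perm = n_perm, seed = seed)
      cx <- cox_hr(clin$time, clin$event, g)
      rows[[paste(v, m)]] <- data.frame(
        dataset = dataset, variant = v, method = m,
        cutpoint = attr(g, "cutpoint"),
        hazard_ratio = cx$hazard_ratio,
        ci_low = cx$ci95[1L], ci_high = cx$ci95[2L],
        wald_p = cx$wald_p, logrank_p = cx$logrank_p,
        n = cx$n, n_events = cx$n_events,
        n_genes_used = attr(sc, "n_genes_used"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_result", "data.frame")
  out
}

#' Assemble a forest-plot table across cohorts
#'
#' Stacks per-cohort results into one table ordered by dataset, then
#' variant, then cutoff method — the layout of a multi-cohort forest plot.
#' No meta-analytic pooling is performed: cohorts remain independent.
#'
#' @param results a \code{cohort_result} or list of them.
#' @return a single ordered \code{cohort_result} data.frame.
#' @export
forest_table <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results)) stop("no results to assemble")
  out <- do.call(rbind, results)
  out <- out[order(out$dataset, out$variant, out$method), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_result", "data.frame")
  out
}

#' Compare signature scores between two race groups
#'
#' Two-sided Wilcoxon rank-sum test (default; Student t optional) of the
#' scaled module scores between exactly two race groups, with per-group
#' medians and interquartile ranges for box-plot reproduction. The rank-sum
#' p is invariant under any common monotone transform of the scores.
#'
#' @param scores numeric scaled scores.
#' @param race group labels, exactly two levels with n >= 2 each.
#' @param test \code{"wilcoxon"} (default) or \code{"ttest"}.
#' @param variant signature label recorded in the output.
#' @return data.frame of class \code{"race_comparison"}: one row per group
#'   with \code{n}, \code{median}, \code{iqr_low}, \code{iqr_high}, plus the
#'   shared \code{statistic} and \code{p}.
#' @export
race_difference <- function(scores, race, test = c("wilcoxon", "ttest"),
                            variant = NA_character_) {
  test <- match.arg(test)
  race <- as.factor(race)
  if (nlevels(race) != 2L) stop("exactly two race groups are required")
  if (any(table(race) < 2L)) stop("each race group needs >= 2 subjects")
  s1 <- scores[race == levels(race)[1L]]
  s2 <- scores[race == levels(race)[2L]]
  ht <- if (test == "wilcoxon")
    suppressWarnings(stats::wilcox.test(s1, s2, alternative = "two.sided"))
  else stats::t.test(s1, s2)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  q1 <- qs(s1); q2 <- qs(s2)
  out <- data.frame(
    variant = variant,
    group = levels(race),
    n = c(length(s1), length(s2)),
    median = c(q1[2L], q2[2L]),
    iqr_low = c(q1[1L], q2[1L]),
    iqr_high = c(q1[3L], q2[3L]),
    test = test,
    statistic = unname(ht$statistic),
    p = ht$p.value,
    stringsAsFactors = FALSE)
  class(out) <- c("race_comparison", "data.frame")
  out
}
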