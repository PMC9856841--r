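#' Fit a score-stratified survival model
#'
#' The central model of the package: a continuous per-patient signature
#' score is dichotomized into low/high groups — at the optimal cutpoint
#' selected by maximally selected rank statistics, at the median, or both —
#' and the prognostic value of the split is estimated by a univariate Cox
#' proportional-hazards fit (hazard ratio of high vs low, Wald test) with
#' Kaplan-Meier curves and a log-rank test per split.
#'
#' @param formula a formula \code{Surv(time, event) ~ score} with a single
#'   numeric score term on the right-hand side.
#' @param data data frame in which the formula is evaluated.
#' @param cutoff cutoff method(s): any of \code{"optimal"},
#'   \code{"median"}; both by default.
#' @param eps admissible-cutpoint restriction for the optimal method (each
#'   side keeps at least this fraction of subjects).
#' @param p_method adjusted-p method for the optimal cutpoint
#'   (\code{"approximation"} or \code{"permutation"}).
#' @param n_perm permutations for \code{p_method = "permutation"}.
#' @param ties Cox tie handling.
#' @param seed seed for the permutation null (ignored otherwise).
#' @return an object of class \code{"sigsurv"}: a list with one element per
#'   cutoff method, each holding \code{groups}, \code{cutpoint},
#'   \code{maxstat} (optimal only), \code{cox} (a \code{\link{cox_hr}}),
#'   and \code{km} (curve table); plus \code{score}, \code{time},
#'   \code{event}, \code{call}.
#' @examples
#' set.seed(1)
#' d <- data.frame(time = rexp(120), event = rbinom(120, 1, 0.8),
#'                 score = rnorm(120))
#' fit <- sigsurv(survival::Surv(time, event) ~ score, d)
#' fit
#' coef(fit)
#' @seealso \code{\link{maxstat_cutpoint}}, \code{\link{cox_hr}},
#'   \code{\link{evaluate_signature_on_cohort}}
#' @export
sigsurv <- function(formula, data, cutoff = c("optimal", "median"),
                    eps = 0.1, p_method = c("approximation", "permutation"),
                    n_perm = 1000L, ties = c("breslow", "efron"),
                    seed = NULL) {
  cutoff <- match.arg(cutoff, several.ok = TRUE)
  p_method <- match.arg(p_method)
  ties <- match.arg(ties)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y)) stop("left-hand side must be a survival::Surv object")
  if (ncol(mf) != 2L) stop("right-hand side must be a single score term")
  time <- unname(y[, 1L]); event <- unname(y[, 2L])
  score <- mf[[2L]]
  if (!is.numeric(score)) stop("the score must be numeric")

  fits <- list()
  for (m in cutoff) {
    g <- dichotomize(score, method = m, time = time, event = event,
                     eps = eps, p_method = p_method, n_perm = n_perm,
                     seed = seed)
    cx <- cox_hr(time, event, g, ties = ties)
    fits[[m]] <- list(groups = g,
                      cutpoint = attr(g, "cutpoint"),
                      maxstat = attr(g, "maxstat"),
                      cox = cx,
                      km = km_estimate(time, event, g))
  }
  structure(list(fits = fits, score = score, time = time, event = event,
                 cutoff = cutoff, score_var = all.vars(formula[[3L]])[1L],
                 call = match.call()),
            class = "sigsurv")
}

#' @export
print.sigsurv <- function(x, digits = 3L, ...) {
  cat("Score-stratified survival fit (n = ", length(x$time),
      ", events = ", sum(x$event), ")\n\n", sep = "")
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    cat(sprintf("  %-8s cutpoint %s: HR = %s [%s, %s], Wald p = %s\n",
                m, format(f$cutpoint, digits = digits),
                format(f$cox$hazard_ratio, digits = digits),
                format(f$cox$ci95[1L], digits = digits),
                format(f$cox$ci95[2L], digits = digits),
                format(f$cox$wald_p, digits = digits)))
  }
  invisible(x)
}

#' @export
summary.sigsurv <- function(object, ...) {
  rows <- lapply(names(object$fits), function(m) {
    f <- object$fits[[m]]
    data.frame(method = m, cutpoint = f$cutpoint,
               n_low = sum(f$groups == "low"),
               n_high = sum(f$groups == "high"),
               hazard_ratio = f$cox$hazard_ratio,
               ci_low = f$cox$ci95[1L], ci_high = f$cox$ci95[2L],
               wald_p = f$cox$wald_p, logrank_p = f$cox$logrank_p,
               maxstat_p = if (!is.null(f$maxstat)) f$maxstat$p_adjusted else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.sigsurv", "data.frame")
  out
}

#' @export
print.summary.sigsurv <- function(x, ...) {
  cat("Cutoff-stratified hazard ratios (high vs low):\n")
  print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' @export
coef.sigsurv <- function(object, ...) {
  vapply(object$fits, function(f) f$cox$beta, numeric(1L))
}

#' Predict low/high group membership for new scores
#' @param object a \code{\link{sigsurv}} fit.
#' @param newdata numeric scores, or a data frame containing the score
#'   column used in the fit.
#' @param method which stored cutoff to apply (default: the first fitted).
#' @param ... unused.
#' @return factor with levels \code{low}, \code{high}.
#' @export
predict.sigsurv <- function(object, newdata, method = NULL, ...) {
  if (is.null(method)) method <- names(object$fits)[1L]
  method <- match.arg(method, names(object$fits))
  s <- if (is.data.frame(newdata)) newdata[[object$score_var]]
       else as.numeric(newdata)
  if (is.null(s)) stop("newdata lacks score column '", object$score_var, "'")
  cut <- object$fits[[method]]$cutpoint
  factor(ifelse(s <= cut, "low", "high"), levels = c("low", "high"))
}

#' @export
residuals.sigsurv <- function(object, method = NULL,
                              type = c("martingale", "deviance", "score",
                                       "schoenfeld"), ...) {
  type <- match.arg(type)
  if (is.null(method)) method <- names(object$fits)[1L]
  method <- match.arg(method, names(object$fits))
  stats::residuals(object$fits[[method]]$cox$fit, type = type)
}

#' Kaplan-Meier plot of a stratified fit
#'
#' Base-graphics step curves of the low and high groups, one panel per
#' fitted cutoff method, annotated with the hazard ratio and Wald p.
#'
#' @param x a \code{\link{sigsurv}} fit.
#' @param col two colors (low, high).
#' @param ... passed to \code{plot}.
#' @export
plot.sigsurv <- function(x, col = c("#1f77b4", "#d62728"), ...) {
  nm <- names(x$fits)
  old <- graphics::par(mfrow = c(1, length(nm)))
  on.exit(graphics::par(old))
  for (m in nm) {
    f <- x$fits[[m]]
    plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
         xlab = "time", ylab = "survival",
         main = sprintf("%s cutoff: HR %.2f, p %.3g", m,
                        f$cox$hazard_ratio, f$cox$wald_p), ...)
    for (i in seq_along(levels(f$groups))) {
      g <- levels(f$groups)[i]
      k <- f$km[f$km$group == g, , drop = FALSE]
      graphics::lines(stats::stepfun(k$time, c(1, k$survival)), do.points = FALSE,
                      col = col[i], lwd = 2)
    }
    graphics::legend("topright", legend = levels(f$groups), col = col,
                     lwd = 2, bty = "n")
  }
  invisible(x)
}

#' @export
nobs.sigsurv <- function(object, ...) length(object$time)
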