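#' Kaplan-Meier curves per group
#'
#' Product-limit estimates with at-risk counts at every event/censoring
#' time, one curve per group, via \code{\link[survival]{survfit}}.
#'
#' @param time positive follow-up times (one unit per cohort).
#' @param event 1 = event, 0 = censored.
#' @param group group labels (a single group if omitted).
#' @return data.frame: \code{group}, \code{time}, \code{survival},
#'   \code{n_risk}, \code{n_event}. Each curve is non-increasing and starts
#'   at 1 before the first event.
#' @export
km_estimate <- function(time, event, group = NULL) {
  .check_surv(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  if (any(table(factor(group)) == 0L) || length(group) != length(time))
    stop("every group needs >= 1 subject")
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group)))
  grp <- if (is.null(fit$strata)) rep(levels(factor(group))[1L], length(fit$time))
         else rep(sub("^g=", "", names(fit$strata)), fit$strata)
  data.frame(group = grp, time = fit$time, survival = fit$surv,
             n_risk = fit$n.risk, n_event = fit$n.event,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Hand-tabulated observed-minus-expected log-rank statistic over event
#' times, with the usual hypergeometric variance. Returns both the
#' chi-square form and the signed standardized form used by the cutpoint
#' search (positive z means more events than expected in the first group).
#'
#' @inheritParams km_estimate
#' @param group two-level group labels.
#' @return list: \code{statistic} (chi-square, 1 df), \code{p}, \code{z}
#'   (signed, first level vs second), \code{observed}, \code{expected}.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  group <- as.factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0L))
    stop("exactly two non-empty groups are required")
  if (sum(event) == 0L) stop("no events: log-rank test undefined")
  g1 <- group == levels(group)[1L]
  dt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) stop("log-rank variance is zero")
  z <- (o1 - e1) / sqrt(v)
  list(statistic = z^2, p = stats::pchisq(z^2, 1L, lower.tail = FALSE),
       z = z, observed = o1, expected = e1)
}

# log-rank (Savage) scores a_i = event_i - Nelson-Aalen cumulative hazard at
# the subject's observed time; the building block of the maxstat search
logrank_scores <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) stop("no events")
  nrisk <- vapply(dt, function(t) sum(time >= t), numeric(1L))
  d <- vapply(dt, function(t) sum(time == t & event == 1), numeric(1L))
  H <- cumsum(d / nrisk)
  event - c(0, H)[findInterval(time, dt) + 1L]
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Finds the score value whose induced low/high split maximizes the
#' standardized two-group log-rank statistic, in the rank-score formulation:
#' with log-rank scores \eqn{a_i} and a candidate cutpoint \eqn{\mu}, the
#' statistic of the split is
#' \deqn{T_\mu = \frac{S_\mu - n_{low}\bar a}{\sqrt{\frac{n_{low} n_{high}}
#'   {n(n-1)} \sum_i (a_i - \bar a)^2}}, \quad
#'   S_\mu = \sum_{i: x_i \le \mu} a_i,}
#' and the selected cutpoint maximizes \eqn{|T_\mu|} over all distinct score
#' values whose split leaves at least a fraction \code{eps} of subjects on
#' each side (ties broken toward the smallest \eqn{\mu}). Because the
#' maximum is taken over many correlated splits, the naive p-value of the
#' best split is anti-conservative; the returned \code{p_adjusted} corrects
#' for the selection either by the improved-Bonferroni-type approximation
#' for the maximum of an Ornstein-Uhlenbeck-type process over the candidate
#' range, or by a seeded permutation null that reruns the full maximization
#' on score-permuted data. The search depends on scores only through their
#' ranks, so any strictly monotone transform gives the same partition and
#' statistic.
#'
#' @inheritParams km_estimate
#' @param scores numeric marker per subject (>= 2 distinct values, n >= 10).
#' @param eps minimum fraction of subjects on each side of an admissible
#'   cutpoint (default 0.1).
#' @param method \code{"approximation"} (default, analytic) or
#'   \code{"permutation"}.
#' @param n_perm permutations when \code{method = "permutation"}.
#' @param seed seed for the permutation null.
#' @return object of class \code{"maxstat_cut"}: \code{cutpoint},
#'   \code{statistic} (max \eqn{|T|}), \code{z} (signed statistic at the
#'   cutpoint; negative means fewer events than expected in the low group),
#'   \code{p_adjusted}, \code{p_unadjusted}, \code{method}, \code{range}
#'   (admissible quantile fractions), \code{n_low}, \code{n_high}, and the
#'   full \code{candidates} table (\code{mu}, \code{n_low}, \code{z}).
#' @references Lausen, B. and Schumacher, M. (1992) Maximally selected rank
#'   statistics. Biometrics 48, 73-85. Hothorn, T. and Lausen, B. (2003) On
#'   the exact distribution of maximally selected rank statistics. CSDA 43,
#'   121-137.
#' @export
maxstat_cutpoint <- function(time, event, scores, eps = 0.1,
                             method = c("approximation", "permutation"),
                             n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  .check_surv(time, event)
  n <- length(scores)
  if (n < 10L) stop("need >= 10 subjects")
  if (length(unique(scores)) < 2L) stop("all scores identical")
  if (sum(event) < 1L) stop("need >= 1 event")
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")

  a <- logrank_scores(time, event)
  ord <- order(scores)
  a_s <- a[ord]; x_s <- scores[ord]
  abar <- mean(a); ssq <- sum((a - abar)^2)
  if (ssq <= 0) stop("degenerate log-rank scores")

  k <- seq_len(n - 1L)
  # candidate split after position k requires x_s[k] < x_s[k+1]
  boundary <- x_s[k] < x_s[k + 1L]
  admissible <- boundary & (k / n >= eps) & (k / n <= 1 - eps)
  if (!any(admissible)) stop("no admissible cutpoint under eps = ", eps)

  z_all <- (cumsum(a_s)[k] - k * abar) /
    sqrt(k * (n - k) / (n * (n - 1)) * ssq)
  kc <- k[admissible]
  zc <- z_all[admissible]
  best <- which.max(abs(zc))           # ties: first = smallest mu
  M <- abs(zc[best])
  p_unadj <- 2 * stats::pnorm(-M)

  if (method == "approximation") {
    p_adj <- .p_maxstat_approx(M, eps, 1 - eps)
    p_adj <- min(1, max(p_adj, p_unadj))
  } else {
    if (!is.null(seed)) set.seed(seed)
    m_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      ap <- sample(a_s)
      zp <- (cumsum(ap)[kc] - kc * abar) /
        sqrt(kc * (n - kc) / (n * (n - 1)) * ssq)
      m_perm[b] <- max(abs(zp))
    }
    p_adj <- (1 + sum(m_perm >= M)) / (n_perm + 1)
  }

  structure(list(cutpoint = x_s[kc[best]], statistic = M, z = zc[best],
                 p_adjusted = p_adj, p_unadjusted = p_unadj, method = method,
                 range = c(eps, 1 - eps),
                 n_low = kc[best], n_high = n - kc[best],
                 candidates = data.frame(mu = x_s[kc], n_low = kc, z = zc)),
            class = "maxstat_cut")
}

# Lausen & Schumacher (1992) improved-Bonferroni-type approximation for
# P(max |T| > b) over the candidate quantile range (eps1, eps2)
.p_maxstat_approx <- function(b, eps1, eps2) {
  if (b <= 0) return(1)
  db <- stats::dnorm(b)
  4 * db / b + db * (b - 1 / b) *
    log((eps2 * (1 - eps1)) / ((1 - eps2) * eps1))
}

#' @export
print.maxstat_cut <- function(x, ...) {
  cat("Maximally selected rank statistic\n")
  cat(sprintf("  cutpoint %.6g  (n_low %d, n_high %d)\n",
              x$cutpoint, x$n_low, x$n_high))
  cat(sprintf("  M = %.4f, adjusted p = %.4g (%s)\n",
              x$statistic, x$p_adjusted, x$method))
  invisible(x)
}

#' Dichotomize scores into low/high groups
#'
#' Splits a continuous score at the optimal survival cutpoint (delegating to
#' \code{\link{maxstat_cutpoint}}) or at the empirical median. Subjects with
#' score \eqn{\le} cutpoint are labeled \code{"low"} (half-open convention:
#' ties go to the low group).
#'
#' @param scores numeric scores, non-constant.
#' @param method \code{"optimal"} or \code{"median"}.
#' @param time,event survival data, required for \code{method = "optimal"}.
#' @param eps,p_method,n_perm,seed passed to \code{\link{maxstat_cutpoint}}
#'   for the optimal method (\code{p_method} is its \code{method}
#'   argument); ignored for the median split.
#' @return factor with levels \code{low}, \code{high}; attributes
#'   \code{cutpoint}, \code{cutoff_method}, and for the optimal method the
#'   full \code{maxstat} object.
#' @export
dichotomize <- function(scores, method = c("optimal", "median"),
                        time = NULL, event = NULL, eps = 0.1,
                        p_method = c("approximation", "permutation"),
                        n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  if (length(unique(scores)) < 2L) stop("constant scores cannot be dichotomized")
  if (method == "optimal") {
    if (is.null(time) || is.null(event))
      stop("optimal cutoff requires survival data")
    ms <- maxstat_cutpoint(time, event, scores, eps = eps, method = p_method,
                           n_perm = n_perm, seed = seed)
    cut <- ms$cutpoint
  } else {
    cut <- stats::median(scores)
    if (!any(scores > cut)) stop("median split leaves the high group empty")
    ms <- NULL
  }
  g <- factor(ifelse(scores <= cut, "low", "high"), levels = c("low", "high"))
  structure(g, cutpoint = cut, cutoff_method = method, maxstat = ms)
}

#' Univariate Cox hazard ratio for a binary stratification
#'
#' Proportional-hazards fit of the high-vs-low indicator by Newton-Raphson
#' on the partial likelihood (\code{\link[survival]{coxph}}), Breslow tie
#' handling by default. Reports the hazard ratio of the high group relative
#' to the low group with a 95% Wald interval and p-value, plus the log-rank
#' p of the same split. Monotone partial likelihood (complete separation of
#' event histories) is reported with a warning and a capped coefficient.
#'
#' @inheritParams km_estimate
#' @param group factor with levels \code{low}, \code{high} (coerced).
#' @param ties tie handling, \code{"breslow"} (default) or \code{"efron"}.
#' @return list of class \code{"cox_hr"}: \code{hazard_ratio}, \code{ci95},
#'   \code{wald_p}, \code{logrank_p}, \code{beta}, \code{se}, \code{n},
#'   \code{n_events}, and the underlying \code{fit}.
#' @export
cox_hr <- function(time, event, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .check_surv(time, event)
  group <- factor(group, levels = if (all(group %in% c("low", "high")))
    c("low", "high") else sort(unique(as.character(group))))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(tapply(event, group, sum) < 1L))
    stop("each group needs >= 1 event")

  dat <- data.frame(time = time, event = event, group = group)
  mono <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = dat,
                    ties = ties, control = survival::coxph.control(iter.max = 50L)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        mono <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  if (mono || abs(beta) > 15) {
    warning("monotone partial likelihood: coefficient capped")
    beta <- sign(beta) * min(abs(beta), 15)
  }
  lr <- logrank_test(time, event, group)
  structure(list(hazard_ratio = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(beta / se)),
                 logrank_p = lr$p,
                 beta = beta, se = se,
                 n = length(time), n_events = sum(event),
                 fit = fit),
            class = "cox_hr")
}

#' @export
print.cox_hr <- function(x, ...) {
  cat(sprintf("HR (high vs low) = %.3f  [%.3f, %.3f]  Wald p = %.3g  (n = %d, events = %d)\n",
              x$hazard_ratio, x$ci95[1L], x$ci95[2L], x$wald_p, x$n, x$n_events))
  invisible(x)
}

.check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}
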