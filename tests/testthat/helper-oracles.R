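# Independent oracles used across test files. These deliberately avoid the
# package's internal code paths: scores, statistics and splits are computed
# by direct summation / enumeration.

# Maximally selected rank statistic by exhaustive enumeration of admissible
# splits, with log-rank scores accumulated gene-by-gene, subject-by-subject.
brute_maxstat <- function(time, event, scores, eps = 0.1) {
  n <- length(scores)
  dt <- sort(unique(time[event == 1]))
  H <- numeric(length(dt))
  for (j in seq_along(dt))
    H[j] <- sum(time == dt[j] & event == 1) / sum(time >= dt[j])
  H <- cumsum(H)
  a <- vapply(seq_len(n), function(i) {
    k <- sum(dt <= time[i])
    event[i] - if (k > 0) H[k] else 0
  }, numeric(1))
  abar <- mean(a)
  ssq <- sum((a - abar)^2)
  mus <- sort(unique(scores))
  mus <- mus[-length(mus)]
  best <- NULL
  for (mu in mus) {
    low <- scores <= mu
    nl <- sum(low)
    if (nl / n < eps || nl / n > 1 - eps) next
    z <- (sum(a[low]) - nl * abar) /
      sqrt(nl * (n - nl) / (n * (n - 1)) * ssq)
    if (is.null(best) || abs(z) > best$M + 1e-12)
      best <- list(mu = mu, M = abs(z))
  }
  best
}

# random right-censored survival sample with at least one event
random_surv <- function(n, event_rate = 0.1, censor_rate = 0.03) {
  te <- rexp(n, event_rate)
  tc <- rexp(n, censor_rate)
  list(time = pmin(te, tc), event = as.integer(te <= tc))
}

# small fully-specified signature for cohort simulations
toy_signature <- function(n_genes = 10L, n_up = 5L) {
  gene_signature(symbol = sprintf("SG%02d", seq_len(n_genes)),
                 weight = c(rep(1, n_up), rep(-1, n_genes - n_up)),
                 entrez = as.character(seq_len(n_genes)),
                 log2fc = c(rep(1.5, n_up), rep(-1.5, n_genes - n_up)),
                 variant = "Sig")
}

# expand a directional signature into the four variants via the filter-table
# route, as build_signatures would from a real DE run
variants_from_signature <- function(sig) {
  de <- data.frame(symbol = sig$symbol, entrez = sig$entrez,
                   log2fc = sig$log2fc, fc_linear = 2^sig$log2fc,
                   p_value = 0.001,
                   direction = ifelse(sig$weight > 0, "up", "down"),
                   stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  build_signatures(de)
}
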