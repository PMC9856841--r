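#' Simulate a two-arm xenograft-style expression experiment
#'
#' Emulates a small two-arm RNA-seq-like design (control vs overexpression,
#' typically 3 animals per arm) directly on the log2 scale: per-gene
#' baselines are Gaussian around \code{baseline_mean}, a planted fraction of
#' genes carries a mean shift in the treatment arm, and independent Gaussian
#' noise of SD \code{noise_sd} is added per observation. Planted absolute
#' log2 fold changes are drawn from a Gamma distribution with mean
#' \code{log2fc_effect} (CV 25%), so every planted gene has a well-defined
#' sign while effect sizes vary realistically across genes.
#'
#' @param n_genes number of genes.
#' @param n_per_arm samples per arm (>= 2; default 3, the usual xenograft
#'   design).
#' @param frac_de fraction of genes with a planted effect, in [0, 1].
#' @param frac_up_of_de fraction of planted genes that are upregulated.
#' @param log2fc_effect mean planted |log2FC| (> 0).
#' @param noise_sd per-observation log2 SD (> 0).
#' @param baseline_mean mean log2 baseline expression.
#' @param baseline_sd SD of per-gene baselines.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with \code{expr} (an \code{\link{expr_matrix}}, columns
#'   \code{EV_*} then \code{LV_*}) and \code{truth}, a data.frame with
#'   per-gene \code{symbol}, \code{entrez}, \code{is_de}, \code{direction}
#'   (\code{"up"}/\code{"down"}/\code{NA}) and \code{log2fc_true}.
#' @export
simulate_xenograft <- function(n_genes, n_per_arm = 3L, frac_de = 0.1,
                               frac_up_of_de = 0.5, log2fc_effect = 2,
                               noise_sd = 0.5, baseline_mean = 8,
                               baseline_sd = 2, seed = NULL) {
  if (n_per_arm < 2L) stop("n_per_arm must be >= 2")
  if (frac_de < 0 || frac_de > 1 || frac_up_of_de < 0 || frac_up_of_de > 1)
    stop("fractions must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (log2fc_effect <= 0) stop("log2fc_effect must be positive")
  if (!is.null(seed)) set.seed(seed)

  sym <- sprintf("G%05d", seq_len(n_genes))
  entrez <- as.character(100000L + seq_len(n_genes))
  n_de <- round(n_genes * frac_de)
  n_up <- round(n_de * frac_up_of_de)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
  direction <- rep(NA_character_, n_genes)
  if (n_de > 0) direction[seq_len(n_de)] <- c(rep("up", n_up), rep("down", n_de - n_up))

  log2fc_true <- numeric(n_genes)
  if (n_de > 0) {
    effect <- stats::rgamma(n_de, shape = 16, rate = 16 / log2fc_effect)
    log2fc_true[seq_len(n_de)] <- ifelse(direction[seq_len(n_de)] == "up", effect, -effect)
  }

  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  n_samp <- 2L * n_per_arm
  arm_shift <- outer(log2fc_true, c(rep(0, n_per_arm), rep(1, n_per_arm)))
  m <- base + arm_shift + matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd),
                                 n_genes, n_samp)
  dimnames(m) <- list(sym, c(paste0("EV_", seq_len(n_per_arm)),
                             paste0("LV_", seq_len(n_per_arm))))
  truth <- data.frame(symbol = sym, entrez = entrez, is_de = is_de,
                      direction = direction, log2fc_true = log2fc_true,
                      stringsAsFactors = FALSE)
  list(expr = expr_matrix(m, entrez = entrez),
       groups = rep(c("EV", "LV"), each = n_per_arm),
       truth = truth)
}

#' Simulate a human-style survival cohort with score-dependent hazard
#'
#' Generates per-patient log2 expression for the genes of a truth signature
#' (plus unrelated background genes), computes each patient's true module
#' score, rescales it to the cohort's 2.5%/97.5% quantiles, and draws event
#' times from an exponential proportional-hazards model with rate
#' \code{baseline_hazard * exp(beta * scaled_score)}. Censoring is an
#' independent exponential(\code{censor_rate}) clock; \code{censor_rate = 0}
#' means complete follow-up. An optional race label shifts signature-gene
#' expression of one group additively, so any race effect reaches survival
#' only through the score.
#'
#' @param n_patients cohort size (>= 20).
#' @param signature_truth a \code{\link{gene_signature}} defining the true
#'   prognostic module.
#' @param beta log hazard per unit of scaled score.
#' @param baseline_hazard events per unit time at scaled score 0 (> 0).
#' @param censor_rate rate of the independent censoring clock (>= 0).
#' @param race_fractions named fractions summing to 1 (default an even
#'   white/black split).
#' @param race_score_shift additive log2 shift applied to signature-gene
#'   expression of \code{shift_group}.
#' @param shift_group race label receiving the shift (default the last name
#'   of \code{race_fractions}).
#' @param n_background unrelated genes added to the matrix.
#' @param seed integer seed.
#' @return list with \code{expr} (\code{\link{expr_matrix}}),
#'   \code{clinical} (data.frame: sample, time, event, race) and
#'   \code{true_score} (scaled, the linear predictor's covariate).
#' @export
simulate_cohort <- function(n_patients, signature_truth, beta = 0,
                            baseline_hazard = 0.1, censor_rate = 0.02,
                            race_fractions = c(white = 0.5, black = 0.5),
                            race_score_shift = 0, shift_group = NULL,
                            n_background = 100L, seed = NULL) {
  if (n_patients < 20L) stop("n_patients must be >= 20")
  if (!inherits(signature_truth, "gene_signature") || nrow(signature_truth) == 0L)
    stop("signature_truth must be a non-empty gene_signature")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (abs(sum(race_fractions) - 1) > 1e-8) stop("race fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)

  sig_sym <- signature_truth$symbol
  sig_entrez <- signature_truth$entrez
  n_sig <- length(sig_sym)
  bg_sym <- sprintf("BG%05d", seq_len(n_background))
  sym <- c(sig_sym, bg_sym)
  entrez <- c(if (is.null(sig_entrez)) rep(NA_character_, n_sig) else sig_entrez,
              rep(NA_character_, n_background))

  samples <- sprintf("P%04d", seq_len(n_patients))
  race <- sample(names(race_fractions), n_patients, replace = TRUE,
                 prob = race_fractions)
  if (is.null(shift_group)) shift_group <- names(race_fractions)[length(race_fractions)]

  base <- stats::rnorm(length(sym), 8, 1)
  m <- base + matrix(stats::rnorm(length(sym) * n_patients, 0, 1),
                     length(sym), n_patients)
  if (race_score_shift != 0)
    m[seq_len(n_sig), race == shift_group] <-
      m[seq_len(n_sig), race == shift_group] + race_score_shift
  dimnames(m) <- list(sym, samples)
  expr <- expr_matrix(m, entrez = entrez)

  raw <- as.numeric(crossprod(m[seq_len(n_sig), , drop = FALSE],
                              signature_truth$weight)) / n_sig
  scaled <- rescale_scores(stats::setNames(raw, samples))

  rate <- baseline_hazard * exp(beta * as.numeric(scaled))
  t_event <- stats::rexp(n_patients, rate)
  t_cens <- if (censor_rate > 0) stats::rexp(n_patients, censor_rate) else rep(Inf, n_patients)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(sample = samples, time = time, event = event,
                         race = race, stringsAsFactors = FALSE)
  list(expr = expr, clinical = clinical, true_score = as.numeric(scaled))
}

#' Orthotopic tumor volume from caliper diameters
#'
#' Standard xenograft formula \eqn{V = W^2 L / 2} with \eqn{W} the smaller
#' and \eqn{L} the larger diameter; mis-ordered arguments are swapped rather
#' than rejected, so the result is orientation-invariant. Vectorized.
#'
#' @param width_mm,length_mm caliper diameters in mm (> 0).
#' @return volume in mm^3.
#' @examples
#' tumor_volume(2, 4)   # 8
#' tumor_volume(3, 3)   # 13.5
#' @export
tumor_volume <- function(width_mm, length_mm) {
  if (any(!is.finite(width_mm)) || any(!is.finite(length_mm)) ||
      any(width_mm <= 0) || any(length_mm <= 0))
    stop("tumor diameters must be positive and finite")
  w <- pmin(width_mm, length_mm)
  l <- pmax(width_mm, length_mm)
  w * w * l / 2
}

#' Relative expression by the 2^-ddCt method
#'
#' Quantifies target-gene expression in a test sample relative to a control
#' sample, each normalized to a reference gene (e.g. RPLP0):
#' \eqn{\Delta\Delta Ct = (Cq_{target,test} - Cq_{ref,test}) -
#' (Cq_{target,ctrl} - Cq_{ref,ctrl})}, fold = \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param cq_target_test,cq_ref_test,cq_target_ctrl,cq_ref_ctrl threshold
#'   cycle (Cq) values; finite. Vectorized.
#' @return fold change (positive; 1 when all four Cq are equal).
#' @examples
#' ddct_fold(20, 18, 24, 18)   # ddCt = -4, fold = 16
#' @export
ddct_fold <- function(cq_target_test, cq_ref_test, cq_target_ctrl, cq_ref_ctrl) {
  cq <- cbind(cq_target_test, cq_ref_test, cq_target_ctrl, cq_ref_ctrl)
  if (any(!is.finite(cq))) stop("all Cq values must be finite")
  ddct <- (cq_target_test - cq_ref_test) - (cq_target_ctrl - cq_ref_ctrl)
  2^(-ddct)
}
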