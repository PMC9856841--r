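test_that("Kaplan-Meier estimate matches the product-limit construction", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: flat at 1
  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km$survival == 1))

  # duplicating every subject leaves the curve unchanged
  set.seed(5)
  s <- random_surv(40)
  k1 <- km_estimate(s$time, s$event)
  k2 <- km_estimate(rep(s$time, 2), rep(s$event, 2))
  expect_equal(k2$survival, k1$survival)
  expect_equal(k2$time, k1$time)
})

test_that("KM curves are monotone and group at-risk counts add up", {
  set.seed(8)
  s <- random_surv(80)
  g <- rep(c("low", "high"), 40)
  km <- km_estimate(s$time, s$event, g)
  for (gr in unique(km$group))
    expect_true(all(diff(km$survival[km$group == gr]) <= 1e-12))
  pooled <- km_estimate(s$time, s$event)
  ev_t <- pooled$time[pooled$n_event > 0]
  for (t0 in ev_t[c(1, 5, 10)]) {
    nr <- sum(s$time >= t0)
    expect_equal(sum(s$time[g == "low"] >= t0) + sum(s$time[g == "high"] >= t0), nr)
    expect_equal(pooled$n_risk[pooled$time == t0], nr)
  }
  expect_error(km_estimate(c(1, 2), c(1, 0), "a"), "group")
})

test_that("log-rank test agrees with survdiff and with a hand tabulation", {
  # 6 subjects, hand tabulation over event times:
  # group A: (1,1) (3,1) (5,0); group B: (2,1) (4,1) (6,1)
  # t=1: n=6 nA=3 d=1 dA=1 -> e=0.5  v=(1)(.5)(.5)(5/5)=0.25
  # t=2: n=5 nA=2 d=1 dA=0 -> e=0.4  v=(.4)(.6)(4/4)=0.24
  # t=3: n=4 nA=2 d=1 dA=1 -> e=0.5  v=0.25
  # t=4: n=3 nA=1 d=1 dA=0 -> e=1/3  v=(1/3)(2/3)=2/9
  # t=6: n=1 nA=0 d=1 dA=0 -> e=0    v=0
  # O=2, E=0.5+0.4+0.5+1/3=1.7333, V=0.25+0.24+0.25+2/9=0.96222
  time <- 1:6; event <- c(1, 1, 1, 1, 0, 1)
  grp <- c("A", "B", "A", "B", "A", "B")
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 1.7333333, tolerance = 1e-6)
  expect_equal(lr$statistic, (2 - 1.7333333)^2 / 0.9622222, tolerance = 1e-6)

  set.seed(10)
  s <- random_surv(60)
  g <- sample(c("x", "y"), 60, replace = TRUE)
  lr <- logrank_test(s$time, s$event, g)
  sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
  expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-9)
  expect_equal(lr$p, unname(1 - pchisq(sd$chisq, 1)), tolerance = 1e-9)
  # symmetry under relabeling
  lr2 <- logrank_test(s$time, s$event, ifelse(g == "x", "y", "x"))
  expect_equal(lr2$statistic, lr$statistic)

  # identical (time, event) multisets in both groups
  lr0 <- logrank_test(rep(1:4, 2), rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "no events")
})

test_that("maxstat search equals brute-force enumeration of admissible splits", {
  set.seed(14)
  for (r in 1:12) {
    n <- sample(12:30, 1)
    s <- random_surv(n)
    if (sum(s$event) < 1) next
    scores <- rnorm(n)
    ms <- maxstat_cutpoint(s$time, s$event, scores)
    bf <- brute_maxstat(s$time, s$event, scores)
    expect_equal(ms$cutpoint, bf$mu, tolerance = 1e-12)
    expect_equal(ms$statistic, bf$M, tolerance = 1e-10)
  }
})

test_that("maxstat recovers a survival-disjoint planted partition", {
  # low scores all die early; high scores are all alive at end of follow-up
  set.seed(18)
  time <- c(1:10, 101:110)
  event <- c(rep(1, 10), rep(0, 10))
  scores <- c(sort(rnorm(10)), sort(rnorm(10)) + 50)
  ms <- maxstat_cutpoint(time, event, scores)
  expect_equal(ms$n_low, 10)
  expect_equal(ms$cutpoint, max(scores[1:10]))
  # M equals the standardized statistic of that very split, enumerated
  bf <- brute_maxstat(time, event, scores)
  expect_equal(ms$statistic, bf$M)
})

test_that("maxstat is invariant under strictly monotone score transforms", {
  set.seed(19)
  s <- random_surv(50)
  scores <- rnorm(50)
  m1 <- maxstat_cutpoint(s$time, s$event, scores)
  m2 <- maxstat_cutpoint(s$time, s$event, exp(scores))
  expect_equal(m2$statistic, m1$statistic, tolerance = 1e-12)
  expect_equal(m2$n_low, m1$n_low)
  expect_equal(m2$cutpoint, exp(m1$cutpoint))
})

test_that("maxstat dominates the median split and its adjusted p the naive p", {
  set.seed(23)
  for (r in 1:5) {
    s <- random_surv(60)
    scores <- rnorm(60)
    ms <- maxstat_cutpoint(s$time, s$event, scores)
    g <- dichotomize(scores, "median")
    med_z <- abs(ms$candidates$z[ms$candidates$n_low == sum(g == "low")])
    expect_gte(ms$statistic, med_z)
    expect_gte(ms$p_adjusted, ms$p_unadjusted)
  }
})

test_that("maxstat validates its inputs", {
  s <- random_surv(30)
  expect_error(maxstat_cutpoint(s$time, s$event, rep(1, 30)), "identical")
  expect_error(maxstat_cutpoint(s$time[1:5], s$event[1:5], rnorm(5)), ">= 10")
  expect_error(maxstat_cutpoint(s$time, rep(0, 30), rnorm(30)), "event")
  # every split leaves < eps on one side: scores concentrated at one value
  sc <- c(rep(0, 29), 1)
  expect_error(maxstat_cutpoint(s$time, s$event, sc), "admissible")
})

test_that("permutation and approximation p-values agree on moderate data", {
  set.seed(30)
  s <- random_surv(120)
  scores <- rnorm(120)
  pa <- maxstat_cutpoint(s$time, s$event, scores)$p_adjusted
  pp <- maxstat_cutpoint(s$time, s$event, scores, method = "permutation",
                         n_perm = 999, seed = 4)$p_adjusted
  expect_lt(abs(pa - pp), 0.1)
  # seeded permutation is reproducible
  pp2 <- maxstat_cutpoint(s$time, s$event, scores, method = "permutation",
                          n_perm = 999, seed = 4)$p_adjusted
  expect_identical(pp, pp2)
})

test_that("dichotomize applies the half-open low convention and delegates", {
  g <- dichotomize(c(1, 2, 3, 4), "median")
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g <- dichotomize(c(1, 2, 2, 3), "median")
  expect_equal(as.character(g), c("low", "low", "low", "high"))
  expect_error(dichotomize(rep(1, 5), "median"), "constant")

  set.seed(33)
  s <- random_surv(40)
  scores <- rnorm(40)
  g <- dichotomize(scores, "optimal", time = s$time, event = s$event)
  ms <- attr(g, "maxstat")
  expect_s3_class(ms, "maxstat_cut")
  expect_equal(as.character(g), ifelse(scores <= ms$cutpoint, "low", "high"))
  expect_equal(sum(g == "low"), ms$n_low)
})

test_that("Cox HR matches coxph and is invariant to time rescaling", {
  set.seed(40)
  s <- random_surv(150)
  g <- dichotomize(rnorm(150), "median")
  cx <- cox_hr(s$time, s$event, g)
  ref <- survival::coxph(survival::Surv(s$time, s$event) ~ g, ties = "breslow")
  expect_equal(cx$beta, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(cx$hazard_ratio, unname(exp(coef(ref))), tolerance = 1e-10)
  cx2 <- cox_hr(s$time * 365.25, s$event, g)
  expect_equal(cx2$hazard_ratio, cx$hazard_ratio, tolerance = 1e-8)
  expect_equal(cx2$wald_p, cx$wald_p, tolerance = 1e-8)
})

test_that("Cox score test at beta = 0 equals the log-rank chi-square", {
  set.seed(44)
  time <- round(rexp(100, 0.1), 6)      # continuous: no ties
  event <- rbinom(100, 1, 0.8)
  g <- rep(c("low", "high"), 50)
  fit <- survival::coxph(survival::Surv(time, event) ~ g)
  lr <- logrank_test(time, event, g)
  expect_equal(unname(fit$score), lr$statistic, tolerance = 1e-6)
})

test_that("complete separation yields a monotone-likelihood warning", {
  time <- c(1:10, 101:110)
  event <- rep(1, 20)
  g <- rep(c("low", "high"), each = 10)
  expect_warning(cx <- cox_hr(time, event, g), "monotone")
  expect_true(is.finite(cx$hazard_ratio))
  expect_error(cox_hr(1:10, c(rep(1, 5), rep(0, 5)),
                      rep(c("low", "high"), each = 5)),
               ">= 1 event")
})

test_that("the sigsurv fit object and its methods are coherent", {
  sig <- toy_signature()
  co <- simulate_cohort(200, sig, beta = log(0.4), seed = 50)
  d <- data.frame(time = co$clinical$time, event = co$clinical$event,
                  score = co$true_score)
  fit <- sigsurv(survival::Surv(time, event) ~ score, d)
  expect_s3_class(fit, "sigsurv")
  expect_named(fit$fits, c("optimal", "median"))
  expect_equal(nobs(fit), 200)

  sm <- summary(fit)
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$hazard_ratio > 0))
  expect_true(all(sm$ci_low < sm$hazard_ratio & sm$hazard_ratio < sm$ci_high))
  expect_equal(unname(coef(fit)), log(sm$hazard_ratio), tolerance = 1e-12)

  # prediction reproduces the training split for each stored cutoff
  for (m in c("optimal", "median"))
    expect_equal(predict(fit, d, method = m), fit$fits[[m]]$groups,
                 ignore_attr = TRUE)
  expect_length(residuals(fit), 200)
  expect_output(print(fit), "HR")
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))

  # maximum statistic dominates the median split by construction
  ms <- fit$fits$optimal$maxstat
  n_low_med <- sum(fit$fits$median$groups == "low")
  expect_gte(ms$statistic,
             abs(ms$candidates$z[ms$candidates$n_low == n_low_med]))
})
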