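test_that("KM without censoring is the empirical survival staircase", {
  set.seed(3)
  tt <- sort(runif(11, 1, 40))
  km <- km_estimate(tt, rep(TRUE, 11))
  expect_equal(km$curve$surv, (11 - seq_len(11)) / 11)
  expect_equal(km$curve$time, tt)
  # all censored: flat at 1, median undefined
  flat <- km_estimate(tt, rep(FALSE, 11))
  expect_true(all(flat$curve$surv == 1))
  expect_true(is.na(flat$median))
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("KM curves are non-increasing, start at 1, and match the hand oracle", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    tt <- round(runif(n, 0, 30), 1)          # force ties
    ev <- runif(n) < 0.7
    if (!any(ev)) ev[1] <- TRUE
    km <- km_estimate(tt, ev)
    expect_true(all(diff(c(1, km$curve$surv)) <= 1e-12))
    expect_true(all(km$curve$surv >= 0 & km$curve$surv <= 1))
    oracle <- hand_km(tt, ev)
    got <- km$curve[km$curve$n_event > 0, ]
    expect_equal(got$surv, oracle$curve$surv, tolerance = 1e-12)
    expect_equal(km$median, oracle$median)
  }
})

test_that("the published 25-patient outcome set has median PFS 9.6 months", {
  d <- example_pfs_cohort()
  km <- km_estimate(d$pfs_months, d$progressed)
  expect_equal(km$n, 25L)
  expect_equal(km$n_events, 18L)
  # every event precedes the earliest censoring, so S(t) = (25 - k)/25
  expect_equal(km$curve$surv[km$curve$n_event > 0],
               (25 - cumsum(km$curve$n_event[km$curve$n_event > 0])) / 25)
  expect_equal(km$median, 9.6)
})

test_that("inverse KM complements the event flag and is an involution", {
  inv <- inverse_km_followup(c(12, 24, 36), c(TRUE, FALSE, FALSE))
  expect_equal(inv$median, 24)  # hand product-limit: S drops to 1/2 at 24
  d <- example_pfs_cohort()
  twice <- inverse_km_followup(d$pfs_months, !d$progressed)
  direct <- km_estimate(d$pfs_months, d$progressed)
  expect_equal(twice$curve, direct$curve)
  # all event-free: inverse KM is the all-events staircase
  inv2 <- inverse_km_followup(c(3, 6, 9), rep(FALSE, 3))
  expect_equal(inv2$curve$surv, c(2, 1, 0) / 3)
})

test_that("median dichotomization applies the <=-median tie rule", {
  s <- dichotomize_at_median(c(1, 2, 3, 4))
  expect_equal(as.character(s$labels), c("low", "low", "high", "high"))
  expect_equal(s$cut, 2.5)
  # odd n: the value equal to the median goes low
  s5 <- dichotomize_at_median(c(10, 20, 30, 40, 50))
  expect_equal(as.character(s5$labels[3]), "low")
  expect_equal(s5$n_low, 3L)
  expect_error(dichotomize_at_median(c(5, 5, 5, 5)), "degenerate")
  expect_error(dichotomize_at_median(c(1, 2, 3)), "at least 4")
})

test_that("log-rank equals the hand hypergeometric computation", {
  # 6-subject fixture: A events at 1, 2, 3; B events at 4, 5, censored 6
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  group <- rep(c("A", "B"), each = 3)
  got <- logrank_test(time, event, group)
  oracle <- hand_logrank(time, event, group)
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  expect_equal(unname(got$observed), oracle$observed)
  expect_equal(unname(got$expected), oracle$expected, tolerance = 1e-12)
})

test_that("log-rank is symmetric in the labels with p in [0, 1]", {
  set.seed(17)
  time <- c(rexp(10, 0.1), rexp(10, 0.25))
  event <- runif(20) < 0.8
  group <- rep(c("A", "B"), each = 10)
  a <- logrank_test(time, event, group)
  b <- logrank_test(time, event, rev(group))
  expect_equal(a$statistic, b$statistic)
  expect_gte(a$p_value, 0); expect_lte(a$p_value, 1)
  # identical groups: statistic 0, p 1 (duplicate every subject)
  same <- logrank_test(rep(time[1:10], 2), rep(event[1:10], 2),
                       rep(c("A", "B"), each = 10))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(1:6, rep(FALSE, 6), rep(c("A", "B"), 3)),
               "zero events")
})

test_that("log-rank p agrees with a permutation oracle on 20 subjects", {
  # clearly separated groups: in this regime the 1-df chi-square reference
  # tracks the exact permutation null to well inside +/- 0.01 (for
  # moderate p at n = 20 the asymptotic approximation alone deviates by
  # 0.01-0.03, so agreement there is not expected at this sample size)
  set.seed(25)
  time <- round(c(rexp(10, 1 / 5), rexp(10, 1 / 18)), 1)
  event <- rep(TRUE, 20)
  group <- rep(c("A", "B"), each = 10)
  p_chisq <- logrank_test(time, event, group)$p_value
  p_perm <- permutation_logrank_p(time, event, group,
                                  n_perm = 10000, seed = 99)
  expect_lt(abs(p_chisq - p_perm), 0.01)
})

test_that("a strong adverse covariate makes the low group's curve dominate", {
  # generator with a strong adverse log-hazard (+1.5 per SD of interim
  # SUV_mean): the below-median group's KM curve lies on or above the
  # above-median group's everywhere, strictly somewhere, in >= 18/20 seeds
  dominated <- 0L
  for (s in 1:20) {
    co <- generate_cohort(cohort_config(
      include_tacs = FALSE, include_vois = FALSE,
      hazard_coefs = c(suv_mean_interim = 1.5), seed = 50000 + s))
    pat <- co$patients
    split <- dichotomize_at_median(pat$suv_mean_interim)
    lo <- split$labels == "low"
    km_lo <- km_estimate(pat$pfs_months[lo], pat$progressed[lo])
    km_hi <- km_estimate(pat$pfs_months[!lo], pat$progressed[!lo])
    s_lo <- stats::stepfun(km_lo$curve$time, c(1, km_lo$curve$surv))
    s_hi <- stats::stepfun(km_hi$curve$time, c(1, km_hi$curve$surv))
    grid <- sort(unique(c(km_lo$curve$time, km_hi$curve$time)))
    grid <- grid[grid <= min(max(pat$pfs_months[lo]),
                             max(pat$pfs_months[!lo]))]
    if (all(s_lo(grid) >= s_hi(grid)) && any(s_lo(grid) > s_hi(grid)))
      dominated <- dominated + 1L
  }
  expect_gte(dominated, 18L)
})

test_that("the survival screen reports cuts, groups and skips degeneracies", {
  set.seed(23)
  n <- 20
  pat <- data.frame(patient_id = seq_len(n),
                    pfs_months = rexp(n, 1 / 10),
                    progressed = runif(n) < 0.8,
                    suv_mean_interim = rlnorm(n, log(6), 0.3),
                    K1_interim = rep(0.2, n),                 # degenerate
                    FD_interim = c(rep(NA, 15), rnorm(5, 1.2, 0.1)))
  out <- suppressWarnings(
    survival_screen(pat, c("suv_mean", "K1", "FD"), "interim"))
  expect_equal(nrow(out), 3L)
  ok <- out[out$parameter == "suv_mean", ]
  expect_false(ok$skipped)
  expect_equal(ok$n_low + ok$n_high, n)
  expect_equal(ok$cut_value, stats::median(pat$suv_mean_interim))
  expect_true(out$skipped[out$parameter == "K1"])       # degenerate split
  expect_true(out$skipped[out$parameter == "FD"])       # > half missing
  expect_warning(survival_screen(pat, "K1", "interim"), "skipped")
})

test_that("under the null the screen's p-values are approximately uniform", {
  # reduced-rep calibration: hazard unrelated to the parameter
  set.seed(41)
  pvals <- replicate(120, {
    n <- 24
    pat <- data.frame(pfs_months = rexp(n, 1 / 10),
                      progressed = runif(n) < 0.8,
                      x_interim = rnorm(n))
    survival_screen(pat, "x", "interim")$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.15)  # rejection rate near nominal
})
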