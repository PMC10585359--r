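# Temporal discrepancy statistics on the monthly grid.

md <- doubleread::dr_month_days

# a series with explicit months: inclusion at m months, events at k
# follow-up months, follow-up ending at f months
mk_series <- function(incl_m, fu_m, ev_m) {
  trial_series(inclusion_day = incl_m * md,
               followup_day = fu_m * md,
               events = data.frame(K = ev_m * md))
}

test_that("rate_over_time counts cumulative events over cumulative accrual", {
  s <- mk_series(rep(0, 10), rep(6, 10),
                 c(1, 1, 2, rep(NA, 7)))
  rc <- rate_over_time(s, "K")
  expect_equal(rc$rate[rc$month == 0], 0)
  expect_equal(rc$rate[rc$month == 2], 0.3)
  expect_equal(rc$rate[rc$month == 6], 0.3)
  # monotone numerator/denominator, CI bracketing
  expect_true(all(diff(rc$n_discrepant) >= 0))
  expect_true(all(diff(rc$n_included) >= 0))
  expect_true(all(rc$low <= rc$rate & rc$rate <= rc$high))

  none <- mk_series(rep(0, 5), rep(3, 5), rep(NA, 5))
  expect_true(all(rate_over_time(none, "K")$rate == 0))

  all1 <- mk_series(rep(0, 4), rep(2, 4), rep(1, 4))
  rc2 <- rate_over_time(all1, "K")
  expect_true(all(rc2$rate[rc2$month >= 1] == 1))
})

test_that("staggered accrual enters the denominator at the inclusion month", {
  s <- mk_series(c(0, 0, 3, 3), rep(4, 4), c(1, NA, NA, NA))
  rc <- rate_over_time(s, "K")
  expect_equal(rc$n_included[rc$month == 1], 2L)
  expect_equal(rc$n_included[rc$month == 3], 4L)
  expect_equal(rc$rate[rc$month == 2], 0.5)
  expect_equal(rc$rate[rc$month == 3], 0.25)
})

test_that("prop_disc_by_followup distributes events and sums to 100", {
  s <- mk_series(rep(0, 6), rep(6, 6), c(1, 1, 2, 4, NA, NA))
  pr <- prop_disc_by_followup(s, "K")
  expect_equal(pr$percent, c(50, 25, 0, 25))
  expect_equal(sum(pr$percent), 100)

  first <- mk_series(rep(0, 3), rep(5, 3), c(1, 1, 1))
  expect_equal(prop_disc_by_followup(first, "K")$percent, 100)

  empty <- mk_series(rep(0, 3), rep(5, 3), rep(NA, 3))
  expect_equal(nrow(prop_disc_by_followup(empty, "K")), 0L)
})

test_that("p_disc_by_followup estimates the per-interval hazard", {
  s <- mk_series(0, 1, 1)
  hz <- p_disc_by_followup(s, "K")
  expect_equal(hz$p_disc, 1)

  none <- mk_series(rep(0, 4), rep(3, 4), rep(NA, 4))
  expect_true(all(p_disc_by_followup(none, "K")$p_disc == 0))

  # risk set excludes patients already discrepant: events {1,2} of 2
  two <- mk_series(c(0, 0), c(3, 3), c(1, 2))
  hz2 <- p_disc_by_followup(two, "K")
  expect_equal(hz2$p_disc[1:2], c(0.5, 1))

  # constant simulated hazard 0.1 is recovered at large n
  set.seed(5)
  n <- 5000
  ev <- rgeom(n, 0.1) + 1
  fu <- rep(8, n)
  ev[ev > fu] <- NA
  s3 <- mk_series(rep(0, n), fu, ev)
  hz3 <- p_disc_by_followup(s3, "K")
  expect_true(all(abs(hz3$p_disc[1:8] - 0.1) < 0.02))
  expect_true(all(hz3$low <= hz3$p_disc & hz3$p_disc <= hz3$high))
})

test_that("expected_rate reproduces closed forms in both modes", {
  # single cohort, full survival, hazard 0.1 for three intervals
  nv <- expected_rate(accrual = 10, surv = 1, pdisc = rep(0.1, 3), mode = "naive")
  hz <- expected_rate(accrual = 10, surv = 1, pdisc = rep(0.1, 3), mode = "hazard")
  expect_equal(nv$expected_rate[nv$month == 3], 0.3)
  expect_equal(hz$expected_rate[hz$month == 3], 1 - 0.9^3)
  expect_true(all(expected_rate(10, 1, rep(0, 4))$expected_rate == 0))
  expect_error(expected_rate(10, c(0.5, 0.9), rep(0.1, 2)), "non-increasing")
  expect_error(expected_rate(10, 1, c(0.5, 1.2)), "\\[0,1\\]")

  # two staggered cohorts weight by accrual: at month 1 the first cohort
  # has one interval of exposure (0.5), the second none
  e <- expected_rate(accrual = c(3, 1), surv = 1, pdisc = rep(0.5, 2),
                     mode = "naive")
  expect_equal(e$expected_rate[e$month == 1], (3 * 0.5 + 1 * 0) / 4)
  expect_equal(e$expected_rate[e$month == 2], (3 * 1 + 1 * 0.5) / 4)
})

test_that("followup_percentile is the empirical inverse-CDF quantile", {
  s <- mk_series(rep(0, 100), 1:100, rep(NA, 100))
  expect_equal(followup_percentile(s, 0.95), 95)
  expect_equal(followup_percentile(s, 1), 100)
  same <- mk_series(rep(0, 5), rep(7, 5), rep(NA, 5))
  expect_equal(followup_percentile(same, 0.95), 7)
})

test_that("end_of_trial_rates pools counts over cohorts with exact CIs", {
  mk_kt <- function(n, k) {
    f <- c(rep(TRUE, k), rep(FALSE, n - k))
    data.frame(patient_id = as.character(seq_len(n)), pdd = f, dopd = f,
               bor = f, dofr = f, pdd_day = NA_real_, dopd_day = NA_real_,
               bor_day = NA_real_, dofr_day = NA_real_,
               bor_reader1 = "SD", bor_reader2 = "SD",
               followup_day = 100, stringsAsFactors = FALSE)
  }
  out <- end_of_trial_rates(list(T1 = mk_kt(100, 10), T2 = mk_kt(50, 20)))
  pooled <- out[out$trial == "Pooled" & out$kod == "PDD", ]
  expect_equal(pooled$n_discrepant, 30)
  expect_equal(pooled$n, 150)
  expect_equal(pooled$percent, 20.0)
  zero <- end_of_trial_rates(mk_kt(10, 0))
  expect_true(all(zero$percent == 0 & zero$low == 0))
})

test_that("trial_series rejects events outside the on-study interval", {
  expect_error(trial_series(0, 2 * md, data.frame(K = 5 * md)),
               "outside")
  expect_error(trial_series(c(0, 0), c(-1, 3), data.frame(K = c(NA, NA))),
               "negative")
})
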