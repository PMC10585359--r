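# Synthetic double-read trial generator.

test_that("trial_design validates and presets carry the published layouts", {
  d <- trial_design()
  expect_s3_class(d, "dr_trial_design")
  expect_error(trial_design(responder_fraction = 1.5), "\\[0, 1\\]")
  expect_error(trial_design(visit_weeks = 0), "> 0")
  expect_error(trial_design(n_patients = 0), "at least one")

  t1 <- trial_preset("trial1")
  expect_equal(t1$n_patients, 333L)
  expect_equal(c(t1$visit_weeks, t1$visit_weeks_late, t1$switch_week), c(6, 12, 54))
  t3 <- trial_preset("trial3")
  expect_equal(t3$n_patients, 243L)
  expect_equal(t3$visit_weeks, 8)
  t5 <- trial_preset("trial5")
  expect_equal(t5$n_patients, 379L)
  expect_equal(c(t5$visit_weeks, t5$visit_weeks_late, t5$switch_week), c(6, 9, 48))
  expect_error(trial_preset("trial9"))
})

test_that("schedule_days implements the period switch", {
  d <- trial_design(visit_weeks = 6, visit_weeks_late = 12, switch_week = 54,
                    max_visits = 12L)
  s <- schedule_days(d)
  expect_equal(s[1:9], 7 * c(6, 12, 18, 24, 30, 36, 42, 48, 54))
  expect_equal(s[10] - s[9], 7 * 12)   # slows down after week 54
  flat <- schedule_days(trial_design(visit_weeks = 8, visit_weeks_late = 8,
                                     switch_week = Inf, max_visits = 5L))
  expect_equal(flat, 7 * 8 * (1:5))
})

test_that("simulate_trial is seed-deterministic and structurally valid", {
  d <- trial_design(n_patients = 60, seed = 14)
  a <- simulate_trial(d)
  b <- simulate_trial(d)
  expect_identical(a$lesions, b$lesions)
  expect_identical(a$truth, b$truth)
  expect_silent(validate_lesion_table(a$lesions))

  # invariants: constant organ/category per (patient, reader, lesion);
  # no visits after follow-up end; new lesions never at baseline
  les <- a$lesions
  key <- paste(les$patient_id, les$reader_id, les$lesion_id)
  stable <- tapply(paste(les$organ, les$category != "NEW"), key,
                   function(x) length(unique(x)) == 1L)
  expect_true(all(stable))
  tru <- a$truth
  last <- tapply(les$visit_index, les$patient_id, max)
  expect_true(all(last <= tru$fu_visits[match(names(last), tru$patient_id)]))

  # at most 5 TLs, at most 2 per organ, none in BRAIN
  tl0 <- les[les$category == "TL" & les$visit_index == 0, ]
  per <- table(paste(tl0$patient_id, tl0$reader_id))
  expect_true(all(per <= 5))
  per_org <- table(paste(tl0$patient_id, tl0$reader_id, tl0$organ))
  expect_true(all(per_org <= 2))
  expect_false(any(tl0$organ == "BRAIN"))
})

test_that("degenerate readers produce zero KoD rates", {
  d <- trial_design(n_patients = 60, seed = 3,
                    measurement_cv = 0, measurement_visit_cv = 0,
                    reader_trend_sd = 0, selection_ranking_sd = 0,
                    selection_overlap = 1, ntl_record_prob = 1,
                    tl_count_disagreement = 0,
                    new_lesion_detection_disagreement = 0,
                    ntl_status_disagreement = 0, lesion_jitter = 0)
  tr <- simulate_trial(d)
  kt <- kod_table(build_timelines(tr$lesions))
  expect_gt(nrow(kt), 0)
  expect_equal(sum(kt$pdd) + sum(kt$dopd) + sum(kt$bor) + sum(kt$dofr), 0L)
})

test_that("simulated cohorts satisfy the KoD ordering invariants", {
  d <- trial_design(n_patients = 250, seed = 8)
  tr <- simulate_trial(d)
  kt <- kod_table(build_timelines(tr$lesions))
  expect_gte(sum(kt$dopd), sum(kt$pdd))        # DOPD encompasses PDD
  expect_true(all(!kt$pdd | kt$dopd))
})

test_that("recover_parameters closes the loop with the engineered channel", {
  d <- trial_design(n_patients = 1500, seed = 21, kod_hazard = 0.1,
                    accrual_months = 6, accrual_quantized = TRUE)
  tr <- simulate_trial(d, emit_lesions = FALSE)
  expect_null(tr$lesions)
  rp <- recover_parameters(tr)
  expect_equal(sum(rp$accrual), 1500)
  expect_true(all(diff(rp$surv) <= 1e-12))
  # visit-bearing months show the engineered per-visit hazard
  hz <- p_disc_by_followup(rp$series, "ENG")
  visit_months <- unique(ceiling(schedule_days(d) / dr_month_days))
  est <- hz$p_disc[hz$interval %in% visit_months & hz$n_at_risk > 200]
  expect_true(all(abs(est - 0.1) < 0.04))

  # zero hazard: nothing recovered
  d0 <- trial_design(n_patients = 100, seed = 5, kod_hazard = 0)
  rp0 <- recover_parameters(simulate_trial(d0, emit_lesions = FALSE))
  expect_true(all(rp0$pdisc == 0))
})

test_that("uniform accrual is recovered flat within binomial noise", {
  d <- trial_design(n_patients = 2400, seed = 31, accrual_months = 12,
                    accrual_quantized = TRUE)
  tr <- simulate_trial(d, emit_lesions = FALSE)
  rp <- recover_parameters(tr)
  counts <- rp$accrual[1:12]
  expect_equal(sum(counts), 2400)
  expect_true(all(abs(counts - 200) < 5 * sqrt(2400 * (1 / 12) * (11 / 12))))
})

test_that("lower selection overlap raises TL organ mismatch", {
  prev <- vapply(c(1, 0.2), function(ov) {
    d <- trial_design(n_patients = 250, seed = 17, selection_overlap = ov,
                      selection_ranking_sd = 0.2)
    f <- baseline_features(simulate_trial(d)$lesions)
    mean(f$tl_not_all_same_organs)
  }, 1)
  expect_gt(prev[2], prev[1])
})

test_that("more measurement noise does not lower the BOR discrepancy rate", {
  # all other reader-disagreement channels muted so the knob is isolated
  rates <- vapply(c(0.01, 0.3), function(cv) {
    out <- 0
    for (s in 1:3) {
      d <- trial_design(n_patients = 250, seed = s, measurement_cv = cv,
                        reader_trend_sd = 0, selection_ranking_sd = 0,
                        selection_overlap = 1, ntl_record_prob = 1,
                        tl_count_disagreement = 0,
                        new_lesion_detection_disagreement = 0,
                        ntl_status_disagreement = 0)
      kt <- kod_table(build_timelines(simulate_trial(d)$lesions))
      out <- out + mean(kt$bor) / 3
    }
    out
  }, 1)
  expect_gte(rates[2], rates[1])
})
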