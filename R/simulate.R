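# Synthetic double-read trial generator.
#
# Emulates the operational anatomy of a double-read BICR lung trial:
# staggered accrual, a per-trial visit schedule (weekly periods, with a
# later slow-down), a latent per-patient lesion pool drawn from a
# lung-primary organ prevalence pattern, a true disease course (responder
# shrinkage, discrete per-visit progression hazard, independent dropout),
# and two readers who share the latent pool but select target lesions with
# imperfect overlap, measure with multiplicative log-normal noise, and can
# disagree on new-lesion detection and non-target status.  Ground truth is
# emitted alongside the lesion table, including an "engineered"
# discrepancy channel: an independent per-visit Bernoulli hazard whose
# realization supports exact calibration of the temporal estimators.

.default_organ_prevalence <- c(
  LUNG = 0.42, LYMPH_NODE_MEDIASTINAL = 0.14, LYMPH_NODE_HILAR = 0.06,
  LIVER = 0.11, ADRENAL = 0.08, BONE = 0.08, PLEURA = 0.04, BRAIN = 0.03,
  KIDNEY = 0.02, SPLEEN = 0.015, OTHER = 0.015)

#' Construct a simulated trial design
#'
#' Returns the full knob set of the generator with lung-trial-like
#' defaults.  Probabilities are per visit; diameters in mm; trial time in
#' days.  The same seed yields an identical trial.
#'
#' @param n_patients Cohort size.
#' @param visit_weeks Early visit period (weeks).
#' @param visit_weeks_late Late visit period (weeks); equal to
#'   `visit_weeks` for a constant schedule.
#' @param switch_week Week after which the late period applies.
#' @param accrual_months Accrual window (months since first patient in);
#'   0 = everyone included on day 0.
#' @param accrual_shape `"uniform"` or `"ramp"` (linearly increasing rate).
#' @param accrual_quantized Include patients exactly at month boundaries
#'   (used by the monthly-grid calibration checks); default FALSE.
#' @param max_visits Hard cap on follow-up visits.
#' @param responder_fraction Fraction of patients with true response.
#' @param response_onset_p Geometric parameter of the true response onset
#'   visit (mean onset = 1 + (1-p)/p visits).
#' @param response_velocity Exponential rate of approach to the latent
#'   best-change level (per visit).
#' @param response_depth_mean,response_depth_sd Fractional SOD nadir of
#'   objective responders (0.5 = 50% shrinkage), truncated below at 0.1.
#' @param nonresponder_depth_mean,nonresponder_depth_sd Latent best-change
#'   level of non-responders (minor shrinkage/growth continuum, truncated
#'   to `[0.4, 1.1]`).
#' @param progression_hazard Per-visit probability of true progression.
#' @param pd_mode_probs Mixture over what drives a progression:
#'   target-lesion growth, a new lesion only, or unequivocal NTL
#'   progression only.
#' @param dropout_hazard Per-visit probability of non-PD dropout.
#' @param post_pd_visits Scans available after true progression.
#' @param growth_rate Per-visit fractional SOD growth after progression.
#' @param lesion_rate Mean number of extra lesions beyond the first
#'   (pool size = 1 + negative binomial).
#' @param lesion_dispersion Negative-binomial size parameter of the pool
#'   (smaller = more between-patient spread).
#' @param lesion_jitter Per-lesion-per-visit multiplicative noise (sdlog).
#' @param lesion_response_sd Between-lesion heterogeneity (sdlog) of the
#'   response depth within a patient.
#' @param dissociated_prob Probability of a dissociated response: each
#'   lesion independently responds or not, decoupling the readers'
#'   target-lesion subsets.
#' @param lesion_growth_sd Between-lesion heterogeneity (sdlog) of the
#'   post-progression growth rate.
#' @param selection_overlap Probability reader 2 preferentially keeps one
#'   of reader 1's target lesions when eligible.
#' @param selection_ranking_sd Idiosyncratic (per-reader) noise on the
#'   size-based candidate ranking (sdlog).
#' @param tl_count_pref Distribution of the number of TLs a reader
#'   habitually tracks (probabilities for 1..5; RECIST caps at 5).
#' @param tl_count_disagreement Probability the second reader tracks a
#'   different number of TLs than the first.
#' @param measurement_cv Persistent per-reader-per-lesion measurement
#'   bias (sdlog): readers measure the same lesion consistently but
#'   differently from each other (axis choice, margin convention).
#' @param measurement_visit_cv Visit-to-visit measurement wobble within a
#'   reader (sdlog), much smaller than the between-reader component.
#' @param reader_trend_sd Reader-level change damping/exaggeration
#'   (sdlog of the exponent applied to the true size ratio): conservative
#'   measurers under-track change and call thresholds late or never.
#' @param new_lesion_prob Probability a new lesion accompanies progression.
#' @param new_lesion_detection_disagreement Per-reader probability of
#'   missing a new lesion at its first visit (detected one visit later).
#' @param ntl_record_prob Probability a reader records a given non-target
#'   lesion at all (NTL listing is discretionary in practice).
#' @param ntl_pd_prob Probability unequivocal NTL progression accompanies
#'   true progression.
#' @param ntl_status_disagreement Probability one reader's NTL-progression
#'   call is flipped.
#' @param kod_hazard Engineered per-visit discrepancy hazard (independent
#'   channel in the ground truth); 0 disables it.
#' @param organ_prevalence Named sampling weights for lesion organs
#'   (`BRAIN` is always followed as NTL).
#' @param seed Integer seed.
#' @return Object of class `dr_trial_design`.
#' @export
trial_design <- function(n_patients = 300L,
                         visit_weeks = 6, visit_weeks_late = 12,
                         switch_week = 54,
                         accrual_months = 12, accrual_shape = c("uniform", "ramp"),
                         accrual_quantized = FALSE,
                         max_visits = 24L,
                         responder_fraction = 0.75,
                         response_onset_p = 0.65,
                         response_velocity = 0.6,
                         response_depth_mean = 0.62, response_depth_sd = 0.15,
                         nonresponder_depth_mean = 0.78,
                         nonresponder_depth_sd = 0.18,
                         progression_hazard = 0.10,
                         pd_mode_probs = c(growth = 0.5, new = 0.35, ntl = 0.15),
                         dropout_hazard = 0.05,
                         post_pd_visits = 1L,
                         growth_rate = 0.7,
                         lesion_rate = 4,
                         lesion_dispersion = 1.2,
                         lesion_jitter = 0.07,
                         lesion_response_sd = 0.4,
                         dissociated_prob = 0.5,
                         lesion_growth_sd = 0.30,
                         selection_overlap = 0.4,
                         selection_ranking_sd = 0.5,
                         tl_count_pref = c(0.1, 0.4, 0.25, 0.15, 0.1),
                         tl_count_disagreement = 1,
                         measurement_cv = 0.20,
                         measurement_visit_cv = 0.08,
                         reader_trend_sd = 0.35,
                         new_lesion_prob = 0.5,
                         new_lesion_detection_disagreement = 0.45,
                         ntl_record_prob = 0.75,
                         ntl_pd_prob = 0.2,
                         ntl_status_disagreement = 0.2,
                         kod_hazard = 0,
                         organ_prevalence = .default_organ_prevalence,
                         seed = 1L) {
  d <- as.list(environment())
  d$accrual_shape <- match.arg(accrual_shape)
  probs <- c(responder_fraction, response_onset_p, progression_hazard,
             dropout_hazard, selection_overlap, new_lesion_prob,
             new_lesion_detection_disagreement, ntl_pd_prob,
             ntl_status_disagreement, kod_hazard)
  if (any(probs < 0 | probs > 1)) stop("trial_design: probabilities must lie in [0, 1]")
  if (visit_weeks <= 0 || visit_weeks_late <= 0) stop("trial_design: visit periods must be > 0")
  if (n_patients < 1) stop("trial_design: need at least one patient")
  structure(d, class = "dr_trial_design")
}

#' Presets mirroring the five analysed trial layouts
#'
#' Cohort size and visit schedule per trial (Trial 1: 333 patients,
#' 6-weekly then 12-weekly after week 54; Trial 2: 493, 6 then 12 after 48;
#' Trial 3: 243, 8-weekly; Trial 4: 276, 8 then 12 after week 152;
#' Trial 5: 379, 6 then 9 after 48), neutral defaults elsewhere.
#'
#' @param trial_name One of `"trial1"` ... `"trial5"`.
#' @param ... Overrides forwarded to [trial_design()].
#' @return A `dr_trial_design`.
#' @export
trial_preset <- function(trial_name = c("trial1", "trial2", "trial3",
                                        "trial4", "trial5"), ...) {
  trial_name <- match.arg(trial_name)
  args <- switch(trial_name,
    trial1 = list(n_patients = 333L, visit_weeks = 6, visit_weeks_late = 12, switch_week = 54),
    trial2 = list(n_patients = 493L, visit_weeks = 6, visit_weeks_late = 12, switch_week = 48),
    trial3 = list(n_patients = 243L, visit_weeks = 8, visit_weeks_late = 8,  switch_week = Inf),
    trial4 = list(n_patients = 276L, visit_weeks = 8, visit_weeks_late = 12, switch_week = 152),
    trial5 = list(n_patients = 379L, visit_weeks = 6, visit_weeks_late = 9,  switch_week = 48))
  do.call(trial_design, utils::modifyList(args, list(...)))
}

#' Visit days implied by a design's schedule
#'
#' @param design A `dr_trial_design`.
#' @return Numeric vector of days since baseline for visits
#'   `1..max_visits`.
#' @export
schedule_days <- function(design) {
  w <- 0; days <- numeric(design$max_visits)
  for (v in seq_len(design$max_visits)) {
    per <- if (w >= design$switch_week) design$visit_weeks_late else design$visit_weeks
    w <- w + per
    days[v] <- w * 7
  }
  days
}

.sim_patient <- function(design, sched, pid, organs_pool) {
  md <- dr_month_days
  # inclusion
  aw <- design$accrual_months * md
  incl <- if (aw <= 0) 0
    else if (design$accrual_quantized)
      floor(if (design$accrual_shape == "ramp") sqrt(runif(1)) * design$accrual_months
            else runif(1) * design$accrual_months) * md
    else if (design$accrual_shape == "ramp") sqrt(runif(1)) * aw
    else runif(1) * aw

  # latent lesion pool: overdispersed burden (many oligometastatic
  # patients, a tail of heavily disseminated ones)
  n_les <- 1L + stats::rnbinom(1, size = design$lesion_dispersion,
                               mu = design$lesion_rate)
  organ <- sample(names(organs_pool), n_les, replace = TRUE, prob = organs_pool)
  nodal <- grepl("^LYMPH_NODE", organ)
  base_d <- ifelse(nodal, exp(rnorm(n_les, log(14), 0.35)),
            ifelse(organ == "LUNG", exp(rnorm(n_les, log(24), 0.50)),
                   exp(rnorm(n_les, log(14), 0.55))))

  # true course: every patient drifts toward a latent best-change level
  # (waterfall continuum); objective responders sit below the -30% line,
  # non-responders shrink or grow mildly, with borderline mass near -30%
  responder <- runif(1) < design$responder_fraction
  onset <- 1L + rgeom(1, design$response_onset_p)
  depth <- if (responder)
    max(0.1, rnorm(1, design$response_depth_mean, design$response_depth_sd))
  else
    min(1.1, max(0.4, rnorm(1, design$nonresponder_depth_mean,
                            design$nonresponder_depth_sd)))
  pd_raw <- rgeom(1, max(design$progression_hazard, 1e-12)) + 1L
  pd_visit <- if (design$progression_hazard > 0 && pd_raw <= design$max_visits) pd_raw else NA_integer_
  # what drives the progression: target-lesion growth, a new lesion only,
  # or unequivocal NTL progression only (new-lesion-driven PDs dominate
  # reader disagreement in lung trials)
  pd_mode <- if (is.na(pd_visit)) NA_character_
    else sample(c("growth", "new", "ntl"), 1, prob = design$pd_mode_probs)
  drop_raw <- rgeom(1, max(design$dropout_hazard, 1e-12)) + 1L
  drop_visit <- if (design$dropout_hazard > 0 && drop_raw <= design$max_visits) drop_raw else NA_integer_
  fu_v <- min(design$max_visits,
              if (is.na(pd_visit)) Inf else pd_visit + design$post_pd_visits,
              if (is.na(drop_visit)) Inf else drop_visit)
  fu_v <- as.integer(fu_v)
  visits <- seq_len(fu_v)

  # per-lesion multiplier trajectories: lesions respond and progress with
  # heterogeneous depth/velocity, so readers tracking different TL sets see
  # persistently different burden curves (dissociated-response lite)
  if (runif(1) < design$dissociated_prob) {
    # dissociated response: each lesion independently responds or not,
    # so readers tracking different lesion subsets can reach
    # categorically different calls
    les_resp <- runif(n_les) < design$responder_fraction
    depth_l <- ifelse(les_resp,
                      pmax(0.1, rnorm(n_les, design$response_depth_mean,
                                      design$response_depth_sd)),
                      pmin(1.1, pmax(0.4, rnorm(n_les, design$nonresponder_depth_mean,
                                                design$nonresponder_depth_sd))))
  } else {
    depth_l <- pmin(1.15, depth * exp(rnorm(n_les, 0, design$lesion_response_sd)))
  }
  growth_l <- design$growth_rate * exp(rnorm(n_les, 0, design$lesion_growth_sd))
  mult <- matrix(1, n_les, fu_v)
  for (v in visits[visits >= onset])
    mult[, v] <- depth_l + (1 - depth_l) * exp(-design$response_velocity * (v - onset + 1))
  if (!is.na(pd_visit) && pd_visit <= fu_v && pd_mode == "growth") {
    pre <- if (pd_visit > 1) mult[, pd_visit - 1] else rep(1, n_les)
    for (v in pd_visit:fu_v)
      mult[, v] <- pre * (1 + growth_l)^(v - pd_visit + 1)
  }

  # engineered discrepancy channel (independent of everything else)
  eng_day <- NA_real_
  if (design$kod_hazard > 0) {
    hit <- which(runif(fu_v) < design$kod_hazard)
    if (length(hit)) eng_day <- sched[hit[1]]
  }

  # per-reader baseline measurement and TL selection; the measurement
  # error is a persistent reader-lesion bias plus small visit-level wobble
  tl_eligible <- !(organ == "BRAIN")
  # how many TLs get tracked is partly case-driven (shared draw) and
  # partly reader habit (independent redraw with tl_count_disagreement)
  n_target_shared <- sample(1:5, 1, prob = design$tl_count_pref)
  sel <- vector("list", 2)
  base_obs <- matrix(0, n_les, 2)
  reader_bias <- matrix(rnorm(n_les * 2, 0, design$measurement_cv), n_les, 2)
  # reader-level change damping/exaggeration: a conservative measurer
  # tracks size change sub-proportionally and crosses thresholds late
  reader_gamma <- exp(rnorm(2, 0, design$reader_trend_sd))
  for (r in 1:2) {
    obs <- round(base_d * exp(reader_bias[, r] +
                              rnorm(n_les, 0, design$measurement_visit_cv)))
    base_obs[, r] <- obs
    meas <- tl_eligible & ifelse(nodal, obs >= 15, obs >= 10)
    # readers rank candidates by size with idiosyncratic preference and
    # select only as many TLs as they habitually track (mean ~2.3, max 5)
    pref <- obs * exp(rnorm(n_les, 0, design$selection_ranking_sd))
    n_target <- if (r == 2 && runif(1) < design$tl_count_disagreement)
      sample(1:5, 1, prob = design$tl_count_pref) else n_target_shared
    cand <- order(-pref)
    cand <- cand[meas[cand]]
    pick <- integer()
    if (r == 2 && length(sel[[1]])) {
      # bias toward the first reader's set: obvious lesions get picked twice
      keep <- intersect(sel[[1]], cand)
      keep <- keep[runif(length(keep)) < design$selection_overlap]
      for (j in c(keep, setdiff(cand, keep))) {
        if (length(pick) >= min(n_target, 5L)) break
        if (sum(organ[pick] == organ[j]) >= 2L) next
        pick <- c(pick, j)
      }
    } else {
      for (j in cand) {
        if (length(pick) >= min(n_target, 5L)) break
        if (sum(organ[pick] == organ[j]) >= 2L) next
        pick <- c(pick, j)
      }
    }
    sel[[r]] <- pick
  }

  # NTL progression and new-lesion events, per progression mode
  ntl_pd <- !is.na(pd_visit) && pd_visit <= fu_v &&
    (identical(pd_mode, "ntl") ||
     (identical(pd_mode, "growth") && runif(1) < design$ntl_pd_prob))
  ntl_pd_flip <- runif(1) < design$ntl_status_disagreement
  ntl_pd_reader <- c(TRUE, TRUE)
  if (ntl_pd && ntl_pd_flip) ntl_pd_reader[sample(2, 1)] <- FALSE
  has_new <- !is.na(pd_visit) && pd_visit <= fu_v &&
    (identical(pd_mode, "new") ||
     (identical(pd_mode, "growth") && runif(1) < design$new_lesion_prob))
  new_detect <- c(NA_integer_, NA_integer_)
  if (has_new) {
    for (r in 1:2) {
      u <- runif(1)
      if (u < design$new_lesion_detection_disagreement) {
        if (runif(1) < 0.85) next             # persistent miss
        dv <- pd_visit + 1L                   # seen one visit later
      } else dv <- pd_visit
      new_detect[r] <- if (dv <= fu_v) as.integer(dv) else NA_integer_
    }
  }

  # lesion truth over visits (baseline col 1, then visits)
  jit <- matrix(exp(rnorm(n_les * (fu_v + 1), 0, design$lesion_jitter)), n_les)
  true_d <- base_d * jit * cbind(1, mult)

  # emit rows per reader; non-TL lesions are recorded as NTLs only with
  # probability ntl_record_prob (per reader, fixed across visits)
  out <- list()
  for (r in 1:2) {
    is_tl <- seq_len(n_les) %in% sel[[r]]
    seen <- is_tl | runif(n_les) < design$ntl_record_prob
    if (!any(seen)) next  # reader records no disease at all
    for (vi in 0:fu_v) {
      td <- true_d[, vi + 1]
      obs <- if (vi == 0) base_obs[, r]
        else round(base_d * (td / base_d)^reader_gamma[r] *
                   exp(reader_bias[, r] +
                       rnorm(n_les, 0, design$measurement_visit_cv)))
      gone <- td < 3
      obs[gone & !nodal] <- 0
      obs[nodal] <- pmax(obs[nodal], 2)
      status <- rep("PRESENT", n_les)
      status[gone] <- "ABSENT"
      if (ntl_pd && vi > 0 && vi >= pd_visit && ntl_pd_reader[r] && any(seen & !is_tl))
        status[which(seen & !is_tl)[1]] <- "UNEQUIVOCAL_PROGRESSION"
      out[[length(out) + 1L]] <- list(
        patient_id = rep(pid, sum(seen)),
        reader_id = rep(paste0("R", r), sum(seen)),
        lesion_id = paste0(pid, "_L", which(seen)),
        organ = organ[seen],
        category = ifelse(is_tl[seen], "TL", "NTL"),
        is_lymph_node = nodal[seen],
        visit_index = rep(vi, sum(seen)),
        visit_day = rep(if (vi == 0) 0 else sched[vi], sum(seen)),
        diameter_mm = ifelse(is_tl[seen], pmax(obs[seen], 0), NA_real_),
        ntl_status = ifelse(is_tl[seen], NA_character_, status[seen]))
    }
    if (has_new && !is.na(new_detect[r])) {
      for (vi in new_detect[r]:fu_v) {
        out[[length(out) + 1L]] <- list(
          patient_id = pid, reader_id = paste0("R", r),
          lesion_id = paste0(pid, "_NEW"), organ = "OTHER",
          category = "NEW", is_lymph_node = FALSE,
          visit_index = vi, visit_day = sched[vi],
          diameter_mm = round(8 * 1.2^(vi - new_detect[r])),
          ntl_status = NA_character_)
      }
    }
  }
  list(rows = out,
       truth = list(patient_id = pid, inclusion_day = incl,
                    responder = responder,
                    onset_visit = if (responder) onset else NA_integer_,
                    pd_visit = pd_visit, drop_visit = drop_visit,
                    fu_visits = fu_v, fu_day = sched[fu_v],
                    new_lesion = has_new, ntl_pd = ntl_pd,
                    engineered_day = eng_day, n_lesions = n_les))
}

#' Simulate a double-read trial
#'
#' Draws a full synthetic cohort under a [trial_design()]: a two-reader
#' lesion-level table (the input of [build_timelines()]) plus a
#' ground-truth table.  Deterministic given `design$seed`.
#'
#' @param design A `dr_trial_design`.
#' @param emit_lesions Emit the lesion-level table (set FALSE to generate
#'   ground truth only, e.g. for large calibration runs); default TRUE.
#' @return List of class `dr_trial`: `lesions` (data frame or NULL),
#'   `truth` (data frame, one row per patient), `design`.
#' @export
simulate_trial <- function(design, emit_lesions = TRUE) {
  stopifnot(inherits(design, "dr_trial_design"))
  set.seed(design$seed)
  sched <- schedule_days(design)
  org <- design$organ_prevalence
  if (!length(org) || any(org < 0) || sum(org) <= 0)
    stop("simulate_trial: invalid organ prevalence table")
  org <- org / sum(org)

  pats <- vector("list", design$n_patients)
  truths <- vector("list", design$n_patients)
  for (i in seq_len(design$n_patients)) {
    p <- .sim_patient(design, sched, sprintf("P%04d", i), org)
    pats[[i]] <- if (emit_lesions) p$rows else NULL
    truths[[i]] <- p$truth
  }
  truth <- do.call(rbind, lapply(truths, function(t)
    as.data.frame(t, stringsAsFactors = FALSE)))

  lesions <- NULL
  if (emit_lesions) {
    blocks <- unlist(pats, recursive = FALSE)
    cols <- names(blocks[[1]])
    lesions <- as.data.frame(
      lapply(structure(cols, names = cols), function(cn)
        unlist(lapply(blocks, `[[`, cn), use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  structure(list(lesions = lesions, truth = truth, design = design),
            class = "dr_trial")
}

#' Recover empirical accrual, survival and discrepancy-hazard series
#'
#' Estimates the three components of the expected-rate decomposition from
#' a simulated cohort on the monthly grid: `accrual` (patients first
#' included per month), `surv` (fraction of patients still evaluated in
#' each follow-up interval), and `pdisc` (per-interval discrepancy
#' probability of the requested channel).
#'
#' @param trial A `dr_trial`.
#' @param channel `"engineered"` (default) or a column of determination
#'   days supplied via `events`.
#' @param events Optional data frame of per-patient determination days
#'   (overrides `channel`).
#' @return List: `accrual`, `surv`, `pdisc`, `series` (the underlying
#'   [trial_series()]).
#' @export
recover_parameters <- function(trial, channel = "engineered", events = NULL) {
  truth <- trial$truth
  if (is.null(events)) {
    if (channel != "engineered") stop("unknown channel: ", channel)
    events <- data.frame(ENG = truth$engineered_day)
  }
  ser <- trial_series(truth$inclusion_day, truth$fu_day, events,
                      patient_id = truth$patient_id)
  m_max <- max(ser$inclusion_month)
  accrual <- vapply(0:m_max, function(m) sum(ser$inclusion_month == m), 0L)
  K <- max(ser$fu_end_interval)
  surv <- vapply(seq_len(K), function(k) mean(ser$fu_end_interval >= k), 1)
  hz <- p_disc_by_followup(ser, names(events)[1])
  pdisc <- numeric(K)
  pdisc[hz$interval] <- hz$p_disc
  list(accrual = accrual, surv = surv, pdisc = pdisc, series = ser)
}
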