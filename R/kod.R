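# Extraction of the four kinds of inter-reader discrepancy (KoD) from a
# pair of reader timelines:
#
#   PDD  - progressive disease declared: only one reader ever declares PD.
#   DOPD - date of progressive disease: one reader has no PD, or both
#          declare PD at different dates (so DOPD encompasses PDD).
#   BOR  - best overall response differs (ordering CR > PR > SD > PD,
#          without response confirmation).
#   DOFR - date of first response: one reader has no CR/PR, or the first
#          CR/PR dates differ.

#' Derive per-reader endpoints from one response timeline
#'
#' Scans a reader's ordered post-baseline responses and returns the best
#' timepoint response (BOR, ordering CR > PR > SD > PD; NE never best),
#' the first-response visit (first CR or PR), and the first-PD visit.
#' Baseline (visit 0) rows, if present, are ignored.
#'
#' @param timeline Data frame with columns `visit_index`, `visit_day`,
#'   `overall` for one patient and one reader.
#' @param patient_id,reader_id Optional identifiers copied to the output.
#' @return List of class `dr_endpoints`: `bor`, `dofr` (visit index or NA),
#'   `dofr_day`, `pd_declared`, `dopd` (visit index or NA), `dopd_day`,
#'   `last_day` (last evaluable visit day), `n_visits`.
#' @export
derive_endpoints <- function(timeline, patient_id = NA, reader_id = NA) {
  tl <- timeline[order(timeline$visit_index), , drop = FALSE]
  tl <- tl[tl$visit_index > 0, , drop = FALSE]
  ev <- tl[tl$overall %in% names(.response_rank), , drop = FALSE]
  if (nrow(ev) == 0L) {
    warning("all-NE timeline: endpoints not evaluable")
    return(structure(list(patient_id = patient_id, reader_id = reader_id,
                          bor = "NE", dofr = NA_integer_, dofr_day = NA_real_,
                          pd_declared = FALSE, dopd = NA_integer_,
                          dopd_day = NA_real_, last_day = NA_real_,
                          n_visits = 0L),
                     class = "dr_endpoints"))
  }
  bor <- ev$overall[which.max(.response_rank[ev$overall])]
  i_resp <- which(ev$overall %in% c("CR", "PR"))[1]
  i_pd <- which(ev$overall == "PD")[1]
  structure(list(
    patient_id = patient_id, reader_id = reader_id, bor = bor,
    dofr = if (is.na(i_resp)) NA_integer_ else as.integer(ev$visit_index[i_resp]),
    dofr_day = if (is.na(i_resp)) NA_real_ else as.numeric(ev$visit_day[i_resp]),
    pd_declared = !is.na(i_pd),
    dopd = if (is.na(i_pd)) NA_integer_ else as.integer(ev$visit_index[i_pd]),
    dopd_day = if (is.na(i_pd)) NA_real_ else as.numeric(ev$visit_day[i_pd]),
    last_day = max(as.numeric(ev$visit_day)),
    n_visits = nrow(ev)
  ), class = "dr_endpoints")
}

#' @export
print.dr_endpoints <- function(x, ...) {
  cat(sprintf("BOR=%s DOFR=%s PD declared=%s DOPD=%s (last evaluable day %s)\n",
              x$bor, ifelse(is.na(x$dofr), "NA", x$dofr),
              ifelse(x$pd_declared, "YES", "NO"),
              ifelse(is.na(x$dopd), "NA", x$dopd),
              format(x$last_day)))
  invisible(x)
}

#' Extract the four KoD flags from two readers' endpoints
#'
#' Applies the four discrepancy definitions to a pair of endpoint sets for
#' the same patient.  The result is symmetric in the two readers, and
#' `pdd = TRUE` implies `dopd = TRUE` on every input.
#'
#' @param a,b `dr_endpoints` for the same patient, different readers.
#' @return List of class `dr_kod` with logical flags `pdd`, `dopd`, `bor`,
#'   `dofr` and, per flagged KoD, the determination day (see
#'   [determination_time()]); `NA` determination days for unflagged KoDs.
#' @param rule Determination-day attribution rule for one-sided events,
#'   `"end_of_followup"` (default) or `"earlier_event"`.
#' @export
extract_kods <- function(a, b, rule = c("end_of_followup", "earlier_event")) {
  rule <- match.arg(rule)
  if (!identical(a$patient_id, b$patient_id))
    stop("extract_kods: endpoints refer to different patients")
  # A reader with an all-NE follow-up cannot be compared.
  if (a$bor == "NE" || b$bor == "NE")
    stop("extract_kods: a reader has no evaluable follow-up; drop the patient from KoD denominators")

  pdd <- xor(a$pd_declared, b$pd_declared)
  dopd <- pdd || (a$pd_declared && b$pd_declared && a$dopd_day != b$dopd_day)
  bor <- a$bor != b$bor
  a_resp <- !is.na(a$dofr); b_resp <- !is.na(b$dofr)
  dofr <- xor(a_resp, b_resp) ||
    (a_resp && b_resp && a$dofr_day != b$dofr_day)

  flags <- list(pdd = pdd, dopd = dopd, bor = bor, dofr = dofr)
  det <- lapply(dr_kod_names, function(k)
    determination_time(a, b, k, flags = flags, rule = rule))
  names(det) <- tolower(dr_kod_names)
  structure(c(list(patient_id = a$patient_id), flags,
              list(determination_day = det)), class = "dr_kod")
}

#' Determination day of a flagged KoD
#'
#' The earliest day (since the patient's baseline) at which the discrepancy
#' is logically determinable: when both readers have the event at different
#' dates, the later of the two event days; when only one reader has the
#' event (and for BOR), the end of the common follow-up (last evaluable day
#' shared by both readers) under the default `"end_of_followup"` rule, or
#' the flagged reader's event day under `"earlier_event"`.
#'
#' @param a,b `dr_endpoints` for the same patient.
#' @param kod_name One of `"PDD"`, `"DOPD"`, `"BOR"`, `"DOFR"`.
#' @param flags Optional precomputed flag list (internal use).
#' @param rule `"end_of_followup"` (default) or `"earlier_event"`.
#' @return Day since baseline, or `NA` when the KoD is not flagged.
#' @export
determination_time <- function(a, b, kod_name,
                               rule = c("end_of_followup", "earlier_event"),
                               flags = NULL) {
  rule <- match.arg(rule)
  kod_name <- match.arg(toupper(kod_name), dr_kod_names)
  end_fu <- min(a$last_day, b$last_day)
  if (is.null(flags)) {
    k <- extract_kods(a, b, rule = rule)
    flags <- k[c("pdd", "dopd", "bor", "dofr")]
  }
  if (!isTRUE(flags[[tolower(kod_name)]])) return(NA_real_)
  one_sided_day <- function(day_a, day_b) {
    if (rule == "end_of_followup") end_fu
    else min(day_a, day_b, na.rm = TRUE)
  }
  switch(kod_name,
    PDD = one_sided_day(a$dopd_day, b$dopd_day),
    DOPD = if (a$pd_declared && b$pd_declared) max(a$dopd_day, b$dopd_day)
           else one_sided_day(a$dopd_day, b$dopd_day),
    BOR = end_fu,
    DOFR = if (!is.na(a$dofr_day) && !is.na(b$dofr_day))
             max(a$dofr_day, b$dofr_day)
           else one_sided_day(a$dofr_day, b$dofr_day))
}

#' Per-patient KoD table from a response-level table
#'
#' Runs [derive_endpoints()] per reader and [extract_kods()] per patient on
#' a response table covering exactly two readers per patient.  Patients with
#' no post-baseline evaluable visit for either reader are dropped (the
#' analysis includes only patients with at least one follow-up visit).
#'
#' @param responses Data frame with `patient_id`, `reader_id`,
#'   `visit_index`, `visit_day`, `overall`.
#' @param rule Determination-day rule, see [determination_time()].
#' @return Data frame, one row per comparable patient: the four logical
#'   flags, their determination days, per-reader BORs, and the common
#'   follow-up end day (`followup_day`).
#' @export
kod_table <- function(responses, rule = c("end_of_followup", "earlier_event")) {
  rule <- match.arg(rule)
  responses$patient_id <- as.character(responses$patient_id)
  sp <- split(responses, responses$patient_id)
  rows <- lapply(sp, function(df) {
    rd <- sort(unique(df$reader_id))
    if (length(rd) != 2L) return(NULL)
    e <- lapply(rd, function(r) {
      tl <- df[df$reader_id == r, , drop = FALSE]
      if (!any(tl$visit_index > 0 & tl$overall %in% names(.response_rank)))
        return(NULL)
      suppressWarnings(derive_endpoints(tl, patient_id = df$patient_id[1], reader_id = r))
    })
    if (is.null(e[[1]]) || is.null(e[[2]])) return(NULL)
    k <- extract_kods(e[[1]], e[[2]], rule = rule)
    data.frame(
      patient_id = df$patient_id[1],
      pdd = k$pdd, dopd = k$dopd, bor = k$bor, dofr = k$dofr,
      pdd_day = k$determination_day$pdd, dopd_day = k$determination_day$dopd,
      bor_day = k$determination_day$bor, dofr_day = k$determination_day$dofr,
      bor_reader1 = e[[1]]$bor, bor_reader2 = e[[2]]$bor,
      followup_day = min(e[[1]]$last_day, e[[2]]$last_day),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(), pdd = logical(),
                      dopd = logical(), bor = logical(), dofr = logical(),
                      pdd_day = numeric(), dopd_day = numeric(),
                      bor_day = numeric(), dofr_day = numeric(),
                      bor_reader1 = character(), bor_reader2 = character(),
                      followup_day = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
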