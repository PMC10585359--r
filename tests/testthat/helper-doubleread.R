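# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately re-derive results from first principles (direct
# transcription of the discrepancy definitions and RECIST thresholds) and
# share no code with the package internals they check.

mk_timeline <- function(responses, days = NULL, visit_index = NULL) {
  n <- length(responses)
  if (is.null(visit_index)) visit_index <- seq_len(n)
  if (is.null(days)) days <- visit_index * 42
  data.frame(visit_index = visit_index, visit_day = days,
             overall = responses, stringsAsFactors = FALSE)
}

mk_responses <- function(patient_id, r1, r2, days = NULL) {
  n <- length(r1)
  if (is.null(days)) days <- seq_len(n) * 42
  rbind(
    data.frame(patient_id = patient_id, reader_id = "R1",
               visit_index = seq_len(n), visit_day = days, overall = r1,
               stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id, reader_id = "R2",
               visit_index = seq_len(n), visit_day = days, overall = r2,
               stringsAsFactors = FALSE))
}

# One lesion-table row; defaults give a plain measurable non-nodal TL.
lesion_row <- function(patient_id = "P1", reader_id = "R1", lesion_id = "L1",
                       organ = "LUNG", category = "TL",
                       is_lymph_node = FALSE, visit_index = 0L,
                       visit_day = visit_index * 42, diameter_mm = 20,
                       ntl_status = NA_character_) {
  data.frame(patient_id = patient_id, reader_id = reader_id,
             lesion_id = lesion_id, organ = organ, category = category,
             is_lymph_node = is_lymph_node, visit_index = visit_index,
             visit_day = visit_day, diameter_mm = diameter_mm,
             ntl_status = ntl_status, stringsAsFactors = FALSE)
}

# Independent oracle: per-reader endpoints from a response sequence
# (transcribed directly from the endpoint definitions).
oracle_endpoints <- function(overall, days = seq_along(overall) * 42) {
  rank <- c(CR = 4, PR = 3, SD = 2, PD = 1)
  ev <- overall %in% names(rank)
  stopifnot(any(ev))
  bor <- names(rank)[which.max(vapply(names(rank), function(r)
    if (any(overall[ev] == r)) rank[[r]] else 0, 1))]
  ir <- which(overall %in% c("CR", "PR"))[1]
  ip <- which(overall == "PD")[1]
  list(bor = bor,
       dofr_day = if (is.na(ir)) NA_real_ else days[ir],
       pd = !is.na(ip),
       dopd_day = if (is.na(ip)) NA_real_ else days[ip],
       last_day = max(days[ev]))
}

# Independent oracle: the four KoD flags from two endpoint sets
# (transcribed from the quoted discrepancy definitions).
oracle_kods <- function(a, b) {
  pdd <- (a$pd && !b$pd) || (!a$pd && b$pd)
  dopd <- pdd || (a$pd && b$pd && a$dopd_day != b$dopd_day)
  bor <- a$bor != b$bor
  ar <- !is.na(a$dofr_day); br <- !is.na(b$dofr_day)
  dofr <- (ar && !br) || (!ar && br) || (ar && br && a$dofr_day != b$dofr_day)
  c(pdd = pdd, dopd = dopd, bor = bor, dofr = dofr)
}

# Independent oracle: RECIST target response from raw numbers.
oracle_target_response <- function(sod, base, nadir, cr_ok = FALSE) {
  if (sod - nadir >= 0.2 * nadir && sod - nadir >= 5) return("PD")
  if (cr_ok) return("CR")
  if (sod <= 0.7 * base) return("PR")
  "SD"
}
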