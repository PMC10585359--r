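# RECIST 1.1 response derivation from lesion-level double reads.
#
# The engine consumes a long-format lesion table (one row per reader,
# patient, lesion and visit) and emits one overall timepoint response per
# reader, patient and visit.  Rules follow RECIST 1.1: target-lesion (TL)
# response from the sum of diameters (SOD) against baseline (response) and
# nadir (progression), non-target (NTL) status assessed qualitatively, any
# new lesion forcing PD.  PD takes precedence whenever thresholds conflict.

.lesion_cols <- c("patient_id", "reader_id", "lesion_id", "organ", "category",
                  "is_lymph_node", "visit_index", "visit_day", "diameter_mm",
                  "ntl_status")

#' Validate a lesion-level observation table
#'
#' Checks the column contract of the long-format lesion table consumed by
#' [build_timelines()]: required columns, controlled categories
#' (`TL`/`NTL`/`NEW`), no `NEW` rows at baseline, non-negative diameters.
#'
#' @param lesions Data frame of lesion observations.
#' @return The table, invisibly, after validation.
#' @export
validate_lesion_table <- function(lesions) {
  missing <- setdiff(.lesion_cols, names(lesions))
  if (length(missing))
    stop("lesion table is missing columns: ", paste(missing, collapse = ", "))
  if (!all(lesions$category %in% c("TL", "NTL", "NEW")))
    stop("lesion category must be TL, NTL or NEW")
  if (any(lesions$category == "NEW" & lesions$visit_index == 0))
    stop("NEW lesions cannot appear at baseline (visit_index 0)")
  d <- lesions$diameter_mm
  if (any(!is.na(d) & d < 0)) stop("diameter_mm must be >= 0")
  if (any(lesions$visit_index < 0)) stop("visit_index must be >= 0")
  invisible(lesions)
}

#' Sum of diameters of target lesions
#'
#' Arithmetic sum of `diameter_mm` over the supplied target-lesion rows
#' (one reader, one patient, one visit).  Disappeared non-nodal TLs are
#' recorded with diameter 0 and contribute 0; nodal TLs always contribute
#' their measured short axis.  An empty set is the no-measurable-disease
#' case: the sum is 0 and the `no_measurable` attribute is set.
#'
#' @param observations Data frame of TL rows sharing patient/reader/visit.
#' @return Sum in mm, with attribute `no_measurable` (logical).
#' @export
sum_of_diameters <- function(observations) {
  if (nrow(observations) == 0L)
    return(structure(0, no_measurable = TRUE))
  if (!all(observations$category == "TL"))
    stop("sum_of_diameters expects target-lesion rows only")
  structure(sum(observations$diameter_mm), no_measurable = FALSE)
}

#' Target-lesion response at one visit
#'
#' RECIST 1.1 thresholds: PD when the SOD increases by at least 20% over the
#' nadir with an absolute increase of at least 5 mm; CR when every non-nodal
#' TL has disappeared and every nodal TL has a short axis below 10 mm; PR
#' when the SOD has decreased by at least 30% from baseline; SD otherwise.
#' PD takes precedence over CR and PR.
#'
#' @param sod_t SOD at the visit (mm); vectorized.
#' @param sod_baseline Baseline SOD (mm), must be > 0.
#' @param sod_nadir Smallest SOD observed up to (and excluding) the visit.
#' @param all_nonnodal_absent All non-nodal TLs recorded as disappeared.
#' @param all_nodal_below_10mm All nodal TLs measure < 10 mm short axis.
#' @return Character vector in `CR`, `PR`, `SD`, `PD`.
#' @export
target_response <- function(sod_t, sod_baseline, sod_nadir,
                            all_nonnodal_absent = FALSE,
                            all_nodal_below_10mm = FALSE) {
  if (any(sod_baseline <= 0, na.rm = TRUE))
    stop("target_response: baseline SOD must be > 0 (no-measurable disease is handled upstream)")
  pd <- (sod_t - sod_nadir >= 0.2 * sod_nadir) & (sod_t - sod_nadir >= 5)
  cr <- all_nonnodal_absent & all_nodal_below_10mm
  pr <- sod_t <= 0.7 * sod_baseline
  out <- rep("SD", length(sod_t))
  out[pr] <- "PR"
  out[cr] <- "CR"
  out[pd] <- "PD"  # PD trumps
  out
}

#' Overall timepoint response from TL response, NTL status and new lesions
#'
#' Encodes the RECIST 1.1 integration table.  A new lesion or PD in either
#' component forces PD.  CR requires CR (or absence of disease) in both
#' components.  Patients with NTL-only disease can reach CR, PD or
#' non-CR/non-PD; the latter is mapped to `SD` so that timelines share one
#' response scale.
#'
#' @param tl TL response (`CR`,`PR`,`SD`,`PD`,`NE`) or `NA` when the reader
#'   selected no TLs; vectorized.
#' @param ntl NTL status (`CR`, `NON_CR_NON_PD`, `PD`, `NE`) or `NA` when the
#'   reader recorded no NTLs.
#' @param new_lesion Logical: any new lesion recorded at or before the visit.
#' @return Character vector in `CR`, `PR`, `SD`, `PD`, `NE`.
#' @export
overall_response <- function(tl, ntl, new_lesion = FALSE) {
  k <- max(length(tl), length(ntl), length(new_lesion))
  tl <- rep_len(as.character(tl), k)
  ntl <- rep_len(as.character(ntl), k)
  new_lesion <- rep_len(new_lesion, k)
  if (any(is.na(tl) & is.na(ntl)))
    stop("overall_response: no disease recorded (both components absent)")

  out <- character(k)
  ntl_ok <- is.na(ntl) | ntl == "CR"          # compatible with overall CR
  ntl_nonpd <- is.na(ntl) | ntl %in% c("CR", "NON_CR_NON_PD", "NE")

  # TL-bearing patients
  has_tl <- !is.na(tl)
  out[has_tl & tl == "CR" & ntl_ok] <- "CR"
  out[has_tl & tl == "CR" & !ntl_ok & ntl %in% c("NON_CR_NON_PD", "NE")] <- "PR"
  out[has_tl & tl == "PR" & ntl_nonpd] <- "PR"
  out[has_tl & tl == "SD" & ntl_nonpd] <- "SD"
  out[has_tl & tl == "NE" & ntl_nonpd] <- "NE"

  # NTL-only patients
  out[!has_tl & ntl == "CR"] <- "CR"
  out[!has_tl & ntl == "NON_CR_NON_PD"] <- "SD"
  out[!has_tl & ntl == "NE"] <- "NE"

  # PD trumps everything
  pd <- new_lesion | (!is.na(tl) & tl == "PD") | (!is.na(ntl) & ntl == "PD")
  out[pd] <- "PD"
  out
}

#' Build per-reader response timelines from a lesion table
#'
#' Derives one overall response per (patient, reader, post-baseline visit).
#' The SOD nadir is tracked per reader independently (baseline included,
#' non-evaluable visits skipped).  A patient-visit with no records for a
#' reader is emitted as `NE`.  Readers without a baseline read are excluded
#' with a warning.
#'
#' @param lesions Lesion observation table (see [validate_lesion_table()]).
#' @return Data frame with columns `patient_id`, `reader_id`, `visit_index`,
#'   `visit_day`, `overall`, sorted by patient, reader, visit.
#' @export
build_timelines <- function(lesions) {
  validate_lesion_table(lesions)
  if (nrow(lesions) == 0L)
    return(data.frame(patient_id = character(), reader_id = character(),
                      visit_index = integer(), visit_day = numeric(),
                      overall = character(), stringsAsFactors = FALSE))

  lesions$patient_id <- as.character(lesions$patient_id)
  lesions$reader_id <- as.character(lesions$reader_id)

  # Patient-level visit grid (shared by both readers: same scans were read).
  grid <- unique(lesions[, c("patient_id", "visit_index", "visit_day")])
  grid <- aggregate(visit_day ~ patient_id + visit_index, grid, max)

  readers <- unique(lesions[, c("patient_id", "reader_id")])
  visits <- merge(readers, grid, by = "patient_id")

  # Drop (patient, reader) pairs with no baseline read.
  pr_key <- function(p, r) paste(p, r, sep = "\r")
  base_rows <- lesions[lesions$visit_index == 0L, ]
  has_base <- unique(pr_key(base_rows$patient_id, base_rows$reader_id))
  vkey <- pr_key(visits$patient_id, visits$reader_id)
  if (!all(vkey %in% has_base)) {
    bad <- unique(vkey[!(vkey %in% has_base)])
    warning(sprintf("%d (patient, reader) pair(s) lack a baseline read and were excluded", length(bad)))
    visits <- visits[vkey %in% has_base, ]
  }
  if (nrow(visits) == 0L)
    return(data.frame(patient_id = character(), reader_id = character(),
                      visit_index = integer(), visit_day = numeric(),
                      overall = character(), stringsAsFactors = FALSE))

  prv <- function(p, r, v) paste(p, r, v, sep = "\r")
  key_v <- prv(visits$patient_id, visits$reader_id, visits$visit_index)

  tl <- lesions[lesions$category == "TL", ]
  ntl <- lesions[lesions$category == "NTL", ]
  new <- lesions[lesions$category == "NEW", ]

  # --- TL aggregates per (patient, reader, visit) ---
  if (nrow(tl)) {
    ktl <- prv(tl$patient_id, tl$reader_id, tl$visit_index)
    sod <- rowsum(tl$diameter_mm, ktl)
    n_tl <- rowsum(rep(1L, nrow(tl)), ktl)
    nn <- tl[!tl$is_lymph_node, ]
    nod <- tl[tl$is_lymph_node, ]
    max_nonnodal <- if (nrow(nn)) tapply(nn$diameter_mm, prv(nn$patient_id, nn$reader_id, nn$visit_index), max) else numeric()
    max_nodal <- if (nrow(nod)) tapply(nod$diameter_mm, prv(nod$patient_id, nod$reader_id, nod$visit_index), max) else numeric()
  } else {
    sod <- n_tl <- matrix(numeric(), dimnames = list(character(), NULL))
    max_nonnodal <- max_nodal <- numeric()
  }

  # --- NTL aggregates ---
  if (nrow(ntl)) {
    kntl <- prv(ntl$patient_id, ntl$reader_id, ntl$visit_index)
    ntl_n <- rowsum(rep(1L, nrow(ntl)), kntl)
    ntl_pd <- rowsum(as.integer(!is.na(ntl$ntl_status) & ntl$ntl_status == "UNEQUIVOCAL_PROGRESSION"), kntl)
    ntl_absent <- rowsum(as.integer(!is.na(ntl$ntl_status) & ntl$ntl_status == "ABSENT"), kntl)
  } else {
    ntl_n <- ntl_pd <- ntl_absent <- matrix(numeric(), dimnames = list(character(), NULL))
  }

  # --- first NEW lesion per (patient, reader) ---
  if (nrow(new)) {
    first_new <- tapply(new$visit_index, pr_key(new$patient_id, new$reader_id), min)
  } else first_new <- numeric()

  # Baseline disease composition per (patient, reader).
  kb <- prv(visits$patient_id, visits$reader_id, 0L)
  base_ntl_n <- as.numeric(ntl_n[match(kb, rownames(ntl_n))]); base_ntl_n[is.na(base_ntl_n)] <- 0
  base_sod <- as.numeric(sod[match(kb, rownames(sod))])
  base_tl_n <- as.numeric(n_tl[match(kb, rownames(n_tl))]); base_tl_n[is.na(base_tl_n)] <- 0
  has_tl_disease <- base_tl_n > 0 & !is.na(base_sod) & base_sod > 0
  has_ntl_disease <- base_ntl_n > 0

  # Per-visit TL quantities aligned to the visit grid.
  v_sod <- as.numeric(sod[match(key_v, rownames(sod))])
  v_ntl_n <- as.numeric(ntl_n[match(key_v, rownames(ntl_n))]); v_ntl_n[is.na(v_ntl_n)] <- 0
  v_ntl_pd <- as.numeric(ntl_pd[match(key_v, rownames(ntl_pd))]); v_ntl_pd[is.na(v_ntl_pd)] <- 0
  v_ntl_absent <- as.numeric(ntl_absent[match(key_v, rownames(ntl_absent))]); v_ntl_absent[is.na(v_ntl_absent)] <- 0
  v_maxnn <- as.numeric(max_nonnodal[match(key_v, names(max_nonnodal))])
  v_maxnod <- as.numeric(max_nodal[match(key_v, names(max_nodal))])
  v_first_new <- as.numeric(first_new[match(pr_key(visits$patient_id, visits$reader_id), names(first_new))])

  ord <- order(visits$patient_id, visits$reader_id, visits$visit_index)
  visits <- visits[ord, ]
  key_pr <- pr_key(visits$patient_id, visits$reader_id)
  v_sod <- v_sod[ord]; v_ntl_n <- v_ntl_n[ord]; v_ntl_pd <- v_ntl_pd[ord]
  v_ntl_absent <- v_ntl_absent[ord]; v_maxnn <- v_maxnn[ord]; v_maxnod <- v_maxnod[ord]
  v_first_new <- v_first_new[ord]
  map_pr <- match(key_pr, key_pr[!duplicated(key_pr)])
  row_kb <- prv(visits$patient_id, visits$reader_id, 0L)
  has_tl_d <- has_tl_disease[match(row_kb, kb)]
  has_ntl_d <- has_ntl_disease[match(row_kb, kb)]

  # Nadir: running minimum of prior non-NE SODs (baseline included), per reader.
  sod_for_nadir <- v_sod
  nadir <- numeric(nrow(visits))
  run <- Inf
  for (i in seq_len(nrow(visits))) {
    if (i == 1L || map_pr[i] != map_pr[i - 1L]) run <- Inf
    nadir[i] <- run
    if (!is.na(sod_for_nadir[i])) run <- min(run, sod_for_nadir[i])
  }

  # Component responses.
  tl_resp <- rep(NA_character_, nrow(visits))
  idx_tl <- which(has_tl_d)
  bl_sod_row <- base_sod[match(prv(visits$patient_id, visits$reader_id, 0L), kb)]
  if (length(idx_tl)) {
    ne <- is.na(v_sod[idx_tl])
    ev <- idx_tl[!ne]
    tl_resp[idx_tl[ne]] <- "NE"
    if (length(ev)) {
      tl_resp[ev] <- target_response(
        sod_t = v_sod[ev],
        sod_baseline = bl_sod_row[ev],
        sod_nadir = pmin(nadir[ev], bl_sod_row[ev]),
        all_nonnodal_absent = ifelse(is.na(v_maxnn[ev]), TRUE, v_maxnn[ev] <= 0),
        all_nodal_below_10mm = ifelse(is.na(v_maxnod[ev]), TRUE, v_maxnod[ev] < 10)
      )
    }
  }

  ntl_resp <- rep(NA_character_, nrow(visits))
  idx_ntl <- which(has_ntl_d)
  if (length(idx_ntl)) {
    ntl_resp[idx_ntl] <- ifelse(
      v_ntl_n[idx_ntl] == 0, "NE",
      ifelse(v_ntl_pd[idx_ntl] > 0, "PD",
             ifelse(v_ntl_absent[idx_ntl] == v_ntl_n[idx_ntl], "CR", "NON_CR_NON_PD")))
  }

  new_flag <- !is.na(v_first_new) & visits$visit_index >= v_first_new

  keep <- visits$visit_index > 0L & (has_tl_d | has_ntl_d)
  out <- visits[keep, c("patient_id", "reader_id", "visit_index", "visit_day")]
  out$overall <- overall_response(tl_resp[keep], ntl_resp[keep], new_flag[keep])
  rownames(out) <- NULL
  out
}
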