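# Baseline-derived risk factors for inter-reader discrepancy.
#
# All features are computed from the two readers' baseline (visit 0)
# selections only: relative burden difference (Delta Burden), organ-overlap
# flags for TLs and NTLs, the reader-specific SOD proportion (SPropSOD,
# reconstructed definition), absence of measurable disease, absence of lung
# TLs, and selection of an infrequent disease location.

#' Relative baseline burden difference between two readers
#'
#' `|SOD1 - SOD2| / (SOD1 + SOD2)`: 0 when the baseline sums of diameters
#' agree, 1 when one reader measured no burden at all.  Symmetric in the
#' readers and invariant under a common rescaling.
#'
#' @param sod1,sod2 Baseline sums of diameters (mm), vectorized.
#' @return Value in `[0, 1]`; `NA` when both SODs are 0.
#' @export
delta_burden <- function(sod1, sod2) {
  tot <- sod1 + sod2
  out <- abs(sod1 - sod2) / tot
  out[tot <= 0] <- NA_real_
  out
}

#' Organ-overlap flags for the two readers' baseline selections
#'
#' Comparison is at the organ-code level: `tl_not_all_same_organs` when the
#' two TL organ sets differ; `all_tls_different_organs` when they are
#' disjoint and both non-empty; `ntl_not_all_same_organs` analogous for
#' NTLs.
#'
#' @param tl_organs_1,tl_organs_2 Character vectors of TL organ codes.
#' @param ntl_organs_1,ntl_organs_2 NTL organ codes.
#' @return Named logical vector with the three flags.
#' @export
organ_overlap_flags <- function(tl_organs_1, tl_organs_2,
                                ntl_organs_1 = character(),
                                ntl_organs_2 = character()) {
  s1 <- unique(tl_organs_1); s2 <- unique(tl_organs_2)
  n1 <- unique(ntl_organs_1); n2 <- unique(ntl_organs_2)
  c(tl_not_all_same_organs = !setequal(s1, s2),
    all_tls_different_organs =
      length(s1) > 0 && length(s2) > 0 && length(intersect(s1, s2)) == 0,
    ntl_not_all_same_organs = !setequal(n1, n2))
}

#' Reader-specific SOD proportion (SPropSOD)
#'
#' Reconstructed definition: the fraction of the two readers' combined
#' baseline SOD contributed by organs selected as TL-bearing by only one of
#' the readers.  0 when the readers selected TLs in the same organs; 1 when
#' their organ sets are disjoint.
#'
#' @param per_organ_sod_1,per_organ_sod_2 Named numeric vectors (organ ->
#'   summed TL diameter in mm) for the two readers.
#' @return Value in `[0, 1]`, `NA` when the combined SOD is 0.
#' @export
sprop_sod <- function(per_organ_sod_1, per_organ_sod_2) {
  tot <- sum(per_organ_sod_1) + sum(per_organ_sod_2)
  if (tot <= 0) return(NA_real_)
  only1 <- setdiff(names(per_organ_sod_1), names(per_organ_sod_2))
  only2 <- setdiff(names(per_organ_sod_2), names(per_organ_sod_1))
  (sum(per_organ_sod_1[only1]) + sum(per_organ_sod_2[only2])) / tot
}

#' Infrequent-location flag
#'
#' TRUE when any organ selected by either reader has cohort prevalence
#' strictly below the cutoff; organs absent from the frequency table count
#' as prevalence 0.
#'
#' @param organs_any_reader Character vector of organs selected by either
#'   reader (TL or NTL).
#' @param frequency_table Named numeric vector of cohort prevalences.
#' @param cutoff Prevalence cutoff (default 0.05).
#' @return Logical.
#' @export
infrequent_location <- function(organs_any_reader, frequency_table,
                                cutoff = 0.05) {
  if (!length(organs_any_reader)) return(FALSE)
  prev <- frequency_table[organs_any_reader]
  prev[is.na(prev)] <- 0
  any(prev < cutoff)
}

#' Per-patient baseline feature table from a lesion table
#'
#' Computes every baseline risk-factor feature per patient from the
#' baseline (visit 0) slice of a two-reader lesion table.  The cohort organ
#' frequency table for the infrequent-location flag is computed from the
#' same cohort (prevalence of each organ among patients where any reader
#' selected it as a TL).
#'
#' @param lesions Lesion observation table covering exactly two readers.
#' @param infrequent_cutoff Prevalence cutoff, default 0.05.
#' @return Data frame, one row per patient, with the feature columns of
#'   `BaselineFeatures` plus per-reader baseline SODs.
#' @export
baseline_features <- function(lesions, infrequent_cutoff = 0.05) {
  validate_lesion_table(lesions)
  base <- lesions[lesions$visit_index == 0, , drop = FALSE]
  base$patient_id <- as.character(base$patient_id)
  readers <- sort(unique(base$reader_id))
  if (length(readers) != 2L)
    stop("baseline_features: the lesion table must cover exactly two readers")

  sp <- split(base, base$patient_id)

  # Cohort organ prevalence over TL selections (any reader).
  tl_organs_by_pat <- lapply(sp, function(df)
    unique(df$organ[df$category == "TL"]))
  all_org <- unique(unlist(tl_organs_by_pat))
  freq <- vapply(all_org, function(o)
    mean(vapply(tl_organs_by_pat, function(x) o %in% x, TRUE)), 1)
  names(freq) <- all_org

  rows <- lapply(names(sp), function(pid) {
    df <- sp[[pid]]
    per_reader <- lapply(readers, function(r) df[df$reader_id == r, , drop = FALSE])
    tl <- lapply(per_reader, function(d) d[d$category == "TL", , drop = FALSE])
    ntl <- lapply(per_reader, function(d) d[d$category == "NTL", , drop = FALSE])
    sods <- vapply(tl, function(d) sum(d$diameter_mm), 1)
    per_organ <- lapply(tl, function(d) {
      if (!nrow(d)) return(structure(numeric(), names = character()))
      tapply(d$diameter_mm, d$organ, sum)
    })
    ov <- organ_overlap_flags(tl[[1]]$organ, tl[[2]]$organ,
                              ntl[[1]]$organ, ntl[[2]]$organ)
    no_disease <- vapply(per_reader, nrow, 1L) == 0L
    non_measurable <- vapply(tl, nrow, 1L) == 0L & !no_disease
    data.frame(
      patient_id = pid,
      no_disease_one_reader = any(no_disease),
      non_measurable_one_reader = any(non_measurable),
      tl_not_all_same_organs = unname(ov["tl_not_all_same_organs"]),
      all_tls_different_organs = unname(ov["all_tls_different_organs"]),
      ntl_not_all_same_organs = unname(ov["ntl_not_all_same_organs"]),
      delta_burden = delta_burden(sods[1], sods[2]),
      no_lung_tl_one_reader = any(vapply(tl, function(d) !any(d$organ == "LUNG"), TRUE)),
      sprop_sod = sprop_sod(per_organ[[1]], per_organ[[2]]),
      infrequent_location = infrequent_location(
        unique(c(tl[[1]]$organ, tl[[2]]$organ)), freq, infrequent_cutoff),
      sod_reader1 = sods[1], sod_reader2 = sods[2],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.binary_features <- c("no_disease_one_reader", "non_measurable_one_reader",
                      "tl_not_all_same_organs", "all_tls_different_organs",
                      "ntl_not_all_same_organs", "no_lung_tl_one_reader",
                      "infrequent_location")
.continuous_features <- c("delta_burden", "sprop_sod")

#' Univariate risk-factor screen against one KoD
#'
#' Binary features are cross-tabulated against the KoD flag and summarized
#' by the odds ratio with Woolf interval (Haldane-Anscombe 0.5 correction
#' when a cell is empty, flagged); continuous features are compared between
#' discrepant and non-discrepant patients by the Wilcoxon rank-sum test,
#' with an optional best-case dichotomization via [optimize_threshold()].
#'
#' @param features Output of [baseline_features()].
#' @param kods Output of [kod_table()].
#' @param kod_name One of `PDD`, `DOPD`, `BOR`, `DOFR`.
#' @param optimize_continuous Also report optimized-threshold odds ratios
#'   for the continuous features (best case, not unbiased); default TRUE.
#' @return Data frame, one row per feature: `feature`, `type`, `prevalence`
#'   (binary only), `or`, `or_low`, `or_high`, `p`, `corrected`,
#'   `threshold` (continuous, optimized).
#' @export
univariate_screen <- function(features, kods, kod_name,
                              optimize_continuous = TRUE) {
  kod_name <- match.arg(toupper(kod_name), dr_kod_names)
  flag_col <- c(PDD = "pdd", DOPD = "dopd", BOR = "bor", DOFR = "dofr")[[kod_name]]
  m <- merge(features, kods[, c("patient_id", flag_col)], by = "patient_id")
  y <- m[[flag_col]]
  if (length(unique(y)) < 2L)
    stop("univariate_screen: KoD flag is constant in this cohort")

  rows <- list()
  for (f in .binary_features) {
    x <- m[[f]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      rows[[f]] <- data.frame(feature = f, type = "binary",
                              prevalence = mean(x, na.rm = TRUE),
                              or = NA_real_, or_low = NA_real_,
                              or_high = NA_real_, p = NA_real_,
                              corrected = FALSE, threshold = NA_real_,
                              note = "degenerate feature",
                              stringsAsFactors = FALSE)
      next
    }
    ok <- !is.na(x)
    orr <- odds_ratio(sum(x[ok] & y[ok]), sum(x[ok] & !y[ok]),
                      sum(!x[ok] & y[ok]), sum(!x[ok] & !y[ok]))
    rows[[f]] <- data.frame(feature = f, type = "binary",
                            prevalence = mean(x[ok]), or = orr$or,
                            or_low = orr$low, or_high = orr$high,
                            p = orr$p.value, corrected = orr$corrected,
                            threshold = NA_real_, note = "",
                            stringsAsFactors = FALSE)
  }
  for (f in .continuous_features) {
    x <- m[[f]]
    ok <- !is.na(x)
    if (sum(ok & y) == 0 || sum(ok & !y) == 0 || length(unique(x[ok])) < 2L) {
      rows[[f]] <- data.frame(feature = f, type = "continuous",
                              prevalence = NA_real_, or = NA_real_,
                              or_low = NA_real_, or_high = NA_real_,
                              p = NA_real_, corrected = FALSE,
                              threshold = NA_real_,
                              note = "degenerate feature",
                              stringsAsFactors = FALSE)
      next
    }
    w <- wilcoxon_rank_sum(x[ok & y], x[ok & !y])
    thr <- or_at <- NA_real_
    lo <- hi <- NA_real_; corr <- FALSE
    if (optimize_continuous) {
      opt <- optimize_threshold(x[ok], y[ok])
      thr <- opt$threshold; or_at <- opt$or
      lo <- opt$low; hi <- opt$high; corr <- opt$corrected
    }
    rows[[f]] <- data.frame(feature = f, type = "continuous",
                            prevalence = NA_real_, or = or_at, or_low = lo,
                            or_high = hi, p = w$p.value, corrected = corr,
                            threshold = thr, note = "optimized threshold (best case)",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$kod <- kod_name
  rownames(out) <- NULL
  out
}

#' Best-case dichotomization threshold for a continuous feature
#'
#' Scans a grid of candidate thresholds and returns the one maximizing the
#' odds ratio of `feature > threshold` against the flag.  Ties resolve to
#' the smallest threshold.  The result is a best case, not an unbiased
#' association estimate.  Infinite (perfectly separating) odds ratios are
#' capped at `or_cap` and flagged.
#'
#' @param x Continuous feature values.
#' @param flag Logical KoD flags.
#' @param grid Candidate thresholds; defaults to the feature's unique
#'   midpoints (up to 101 quantile-spaced points).
#' @param or_cap Cap for infinite odds ratios, default 1e6.
#' @return List: `threshold`, `or`, `low`, `high`, `p`, `corrected`,
#'   `capped`; `NA` threshold when no grid point yields a valid table.
#' @export
optimize_threshold <- function(x, flag, grid = NULL, or_cap = 1e6) {
  ok <- !is.na(x) & !is.na(flag)
  x <- x[ok]; flag <- flag[ok]
  if (length(unique(x)) < 2L) stop("optimize_threshold: need >= 2 distinct values")
  if (is.null(grid)) {
    u <- sort(unique(x))
    mids <- (u[-1] + u[-length(u)]) / 2
    grid <- if (length(mids) > 101) unique(quantile(mids, seq(0, 1, length.out = 101), names = FALSE)) else mids
  }
  best <- NULL
  for (thr in sort(grid)) {
    z <- x > thr
    if (!any(z) || all(z)) next
    a <- sum(z & flag); b <- sum(z & !flag)
    c_ <- sum(!z & flag); d <- sum(!z & !flag)
    orr <- odds_ratio(a, b, c_, d)
    if (is.na(orr$or)) next
    val <- min(orr$or, or_cap)
    if (is.null(best) || val > best$or + 1e-12) {
      best <- list(threshold = thr, or = val, low = orr$low, high = orr$high,
                   p = orr$p.value, corrected = orr$corrected,
                   capped = orr$or > or_cap)
    }
  }
  if (is.null(best))
    return(list(threshold = NA_real_, or = NA_real_, low = NA_real_,
                high = NA_real_, p = NA_real_, corrected = FALSE,
                capped = FALSE))
  best
}
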