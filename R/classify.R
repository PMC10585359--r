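# Discordance-prediction harness: baseline feature matrix -> repeated
# stratified 80:20 cross-validation -> AUC / Acc / Se / Sp / PPV / NPV with
# percentile-bootstrap intervals over the repetition metrics.  Accuracy is
# flagged when McNemar's test on the pooled confusion matrix indicates a
# significant assessment imbalance.

#' Build a labeled feature matrix for one KoD
#'
#' Joins the baseline feature table with the per-patient KoD flags,
#' converts binary features to 0/1 and imputes missing continuous features
#' by the cohort median (flagged via the `imputed` attribute).
#'
#' @param features Output of [baseline_features()].
#' @param kods Output of [kod_table()].
#' @param kod_name KoD used as the label.
#' @return List of class `dr_design`: `X` (numeric matrix), `y` (0/1),
#'   `patient_id`.
#' @export
build_feature_matrix <- function(features, kods, kod_name) {
  kod_name <- match.arg(toupper(kod_name), dr_kod_names)
  flag_col <- c(PDD = "pdd", DOPD = "dopd", BOR = "bor", DOFR = "dofr")[[kod_name]]
  m <- merge(features, kods[, c("patient_id", flag_col)], by = "patient_id")
  if (nrow(m) == 0L) stop("build_feature_matrix: no common patients")
  if (nrow(m) < 10L) stop("build_feature_matrix: fewer than 10 patients")
  y <- as.numeric(m[[flag_col]])
  if (length(unique(y)) < 2L)
    stop("build_feature_matrix: single-class labels")
  cols <- c(.binary_features, .continuous_features)
  X <- sapply(cols, function(f) as.numeric(m[[f]]))
  imputed <- character()
  for (f in .continuous_features) {
    miss <- is.na(X[, f])
    if (any(miss)) {
      X[miss, f] <- median(X[!miss, f])
      imputed <- c(imputed, f)
    }
  }
  structure(list(X = X, y = y, patient_id = m$patient_id, kod = kod_name),
            class = "dr_design", imputed = imputed)
}

.fit_model <- function(model, X, y) {
  switch(model,
         forest = forest_fit(X, y),
         feedforward = ff_grid_search(X, y))
}

.confusion_metrics <- function(truth, pred) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  c(acc = (tp + tn) / (tp + tn + fp + fn),
    se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    fp = fp, fn = fn, tp = tp, tn = tn)
}

#' Repeated stratified 80:20 cross-validated classification
#'
#' Repeats a stratified 80:20 train/test split, fits the requested model on
#' the training part and scores the held-out part.  Point estimates are the
#' means over repetitions (percent scale); intervals are percentile
#' bootstraps over the repetition metrics.  The class threshold is 0.5 (AUC
#' is threshold-free).  Accuracy is accompanied by the McNemar p-value on
#' the pooled confusion matrix and flagged when the test indicates a
#' significant imbalance bias.
#'
#' @param design A `dr_design` from [build_feature_matrix()].
#' @param model `"forest"` or `"feedforward"`.
#' @param reps Number of split repetitions, default 50.
#' @param train_frac Training fraction, default 0.8.
#' @param seed Integer seed; the full run is reproducible given the seed.
#' @param boot_B Bootstrap resamples for the metric intervals, default 500.
#' @return Object of class `dr_class_report`: per-metric point estimates
#'   and intervals (percent scale), `mcnemar_p`, `acc_flagged`, pooled
#'   confusion counts, `n_train`, `n_test`.
#' @export
crossval_classify <- function(design, model = c("forest", "feedforward"),
                              reps = 50L, train_frac = 0.8, seed = 1L,
                              boot_B = 500L) {
  model <- match.arg(model)
  X <- design$X; y <- design$y
  set.seed(seed)
  n <- length(y)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("crossval_classify: need both classes")
  per_rep <- matrix(NA_real_, reps, 6,
                    dimnames = list(NULL, c("auc", "acc", "se", "sp", "ppv", "npv")))
  pooled <- data.frame(truth = numeric(), pred = numeric())
  n_tr <- n_te <- NA_integer_
  for (r in seq_len(reps)) {
    for (attempt in 1:10) {
      tr <- c(sample(pos, round(train_frac * length(pos))),
              sample(neg, round(train_frac * length(neg))))
      te <- setdiff(seq_len(n), tr)
      if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) break
      if (attempt == 10) stop("crossval_classify: could not form a two-class split")
    }
    fit <- .fit_model(model, X[tr, , drop = FALSE], y[tr])
    sc <- predict(fit, X[te, , drop = FALSE])
    pr <- as.numeric(sc > 0.5)
    cm <- .confusion_metrics(y[te], pr)
    per_rep[r, ] <- c(auc_score(y[te], sc), cm[c("acc", "se", "sp", "ppv", "npv")])
    pooled <- rbind(pooled, data.frame(truth = y[te], pred = pr))
    n_tr <- length(tr); n_te <- length(te)
  }
  pooled_cm <- .confusion_metrics(pooled$truth, pooled$pred)
  mc <- mcnemar_test(pooled_cm[["fp"]], pooled_cm[["fn"]])
  metric <- function(col) {
    v <- per_rep[, col]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      return(c(est = 100 * mean(v), low = NA_real_, high = NA_real_))
    ci <- bootstrap_ci(v, mean, B = boot_B)
    c(est = 100 * ci$estimate, low = 100 * ci$low, high = 100 * ci$high)
  }
  mets <- sapply(colnames(per_rep), metric)
  structure(list(
    kod = design$kod, model = model, metrics = t(mets),
    mcnemar_p = mc$p.value, acc_flagged = mc$p.value < 0.05,
    confusion = pooled_cm[c("tp", "fp", "fn", "tn")],
    per_rep = per_rep, n_train = n_tr, n_test = n_te, reps = reps
  ), class = "dr_class_report")
}

#' @export
print.dr_class_report <- function(x, ...) {
  cat(sprintf("Discordance prediction: %s, model = %s (%d x %d/%d split)\n",
              x$kod, x$model, x$reps, x$n_train, x$n_test))
  m <- x$metrics
  for (i in rownames(m))
    cat(sprintf("  %-4s %5.1f [%5.1f; %5.1f]\n", toupper(i),
                m[i, "est"], m[i, "low"], m[i, "high"]))
  cat(sprintf("  McNemar p = %.3f%s\n", x$mcnemar_p,
              if (x$acc_flagged) " (accuracy flagged: imbalance bias)" else ""))
  invisible(x)
}

#' Recursive feature elimination under cross-validated AUC
#'
#' Iteratively drops the feature with the lowest forest importance (fit on
#' the full data) and evaluates each nested subset by a short repeated
#' cross-validation; returns the subset with the best AUC.
#'
#' @param design A `dr_design`.
#' @param model Model used for evaluation (default `"forest"`).
#' @param reps Cross-validation repetitions per subset, default 10.
#' @param seed Integer seed.
#' @return List: `best_features`, `best_auc`, `path` (data frame of subset
#'   size vs AUC), `ranking` (features in elimination order, first dropped
#'   first).
#' @export
recursive_feature_elimination <- function(design, model = "forest",
                                          reps = 10L, seed = 1L) {
  X <- design$X; y <- design$y
  feats <- colnames(X)
  if (length(feats) < 2L)
    return(list(best_features = feats, best_auc = NA_real_,
                path = data.frame(), ranking = character()))
  set.seed(seed)
  current <- feats
  dropped <- character()
  path <- list()
  while (length(current) >= 1L) {
    sub <- design
    sub$X <- X[, current, drop = FALSE]
    rep_seed <- sample.int(.Machine$integer.max / 2, 1)
    rpt <- crossval_classify(sub, model = model, reps = reps,
                             seed = rep_seed, boot_B = 100L)
    path[[length(path) + 1L]] <- data.frame(
      n_features = length(current), auc = rpt$metrics["auc", "est"],
      features = paste(current, collapse = "+"), stringsAsFactors = FALSE)
    if (length(current) == 1L) break
    fit <- forest_fit(X[, current, drop = FALSE], y)
    worst <- names(which.min(fit$importance))
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  path <- do.call(rbind, path)
  best <- path[which.max(path$auc), ]
  list(best_features = strsplit(best$features, "+", fixed = TRUE)[[1]],
       best_auc = best$auc, path = path, ranking = dropped)
}
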