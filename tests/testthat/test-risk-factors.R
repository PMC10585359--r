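# Baseline risk-factor features and the univariate screen.

test_that("delta_burden is the symmetric relative SOD difference", {
  expect_equal(delta_burden(50, 50), 0)
  expect_equal(delta_burden(60, 40), 0.2)
  expect_equal(delta_burden(37, 0), 1)
  expect_true(is.na(delta_burden(0, 0)))
  # symmetry and scale invariance
  set.seed(2)
  a <- runif(50, 1, 100); b <- runif(50, 1, 100)
  expect_equal(delta_burden(a, b), delta_burden(b, a))
  expect_equal(delta_burden(3 * a, 3 * b), delta_burden(a, b))
  expect_true(all(delta_burden(a, b) >= 0 & delta_burden(a, b) <= 1))
})

test_that("organ_overlap_flags compares organ sets, not lesions", {
  f <- organ_overlap_flags(c("LUNG", "LIVER"), c("LUNG", "ADRENAL"))
  expect_true(f[["tl_not_all_same_organs"]])
  expect_false(f[["all_tls_different_organs"]])
  g <- organ_overlap_flags("LIVER", "ADRENAL")
  expect_true(g[["tl_not_all_same_organs"]] && g[["all_tls_different_organs"]])
  h <- organ_overlap_flags(c("LUNG", "LUNG"), "LUNG", "LIVER", "LIVER")
  expect_false(h[["tl_not_all_same_organs"]])
  expect_false(h[["ntl_not_all_same_organs"]])
})

test_that("sprop_sod measures the reader-specific SOD fraction", {
  expect_equal(sprop_sod(c(LUNG = 50), c(LUNG = 50)), 0)
  expect_equal(sprop_sod(c(LUNG = 50), c(LIVER = 50)), 1)
  expect_equal(sprop_sod(c(LUNG = 50), c(LUNG = 30, LIVER = 20)), 0.2)
  expect_true(is.na(sprop_sod(structure(numeric(), names = character()),
                              structure(numeric(), names = character()))))
})

test_that("infrequent_location uses strict inequality against the cutoff", {
  freq <- c(LUNG = 0.8, LIVER = 0.3, SPLEEN = 0.05, KIDNEY = 0.01)
  expect_false(infrequent_location(c("LUNG", "LIVER"), freq))
  expect_true(infrequent_location("KIDNEY", freq))
  expect_true(infrequent_location("UNKNOWN_ORGAN", freq))   # treated as 0
  expect_false(infrequent_location("SPLEEN", freq, cutoff = 0.05))  # at cutoff
})

test_that("baseline_features derives the per-patient feature table", {
  tab <- rbind(
    # patient A: same organs, different burden
    lesion_row("A", "R1", "L1", "LUNG", diameter_mm = 60),
    lesion_row("A", "R2", "L1", "LUNG", diameter_mm = 40),
    # patient B: disjoint TL organs, one reader without lung TL
    lesion_row("B", "R1", "L1", "LIVER", diameter_mm = 30),
    lesion_row("B", "R2", "L2", "LUNG", diameter_mm = 30),
    # patient C: one reader NTL-only
    lesion_row("C", "R1", "L1", "LUNG", diameter_mm = 25),
    lesion_row("C", "R2", "L1", "LUNG", category = "NTL",
               diameter_mm = NA, ntl_status = "PRESENT"))
  f <- baseline_features(tab)
  A <- f[f$patient_id == "A", ]; B <- f[f$patient_id == "B", ]
  C <- f[f$patient_id == "C", ]
  expect_equal(A$delta_burden, 0.2)
  expect_false(A$tl_not_all_same_organs)
  expect_true(B$tl_not_all_same_organs && B$all_tls_different_organs)
  expect_true(B$no_lung_tl_one_reader)
  expect_equal(B$sprop_sod, 1)
  expect_true(C$non_measurable_one_reader)
  # implication invariant
  expect_true(all(!f$all_tls_different_organs | f$tl_not_all_same_organs))
})

test_that("univariate_screen reproduces hand-computed odds ratios", {
  n <- 45
  feats <- data.frame(
    patient_id = as.character(1:n),
    no_disease_one_reader = FALSE,
    non_measurable_one_reader = rep(c(TRUE, FALSE), c(15, 30)),
    tl_not_all_same_organs = rep(c(TRUE, FALSE, TRUE), c(10, 20, 15)),
    all_tls_different_organs = FALSE,
    ntl_not_all_same_organs = TRUE,
    delta_burden = seq(0, 1, length.out = n),
    no_lung_tl_one_reader = FALSE,
    sprop_sod = rep(0.5, n),
    infrequent_location = FALSE,
    stringsAsFactors = FALSE)
  kods <- data.frame(patient_id = as.character(1:n),
                     pdd = FALSE, dopd = FALSE,
                     bor = rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 5, 5, 25)),
                     dofr = FALSE, stringsAsFactors = FALSE)
  sc <- univariate_screen(feats, kods, "BOR", optimize_continuous = FALSE)
  # non_measurable: flagged 15 with 10 BOR+, unflagged 30 with 5 BOR+
  want <- (10 * 25) / (5 * 5)
  expect_equal(sc$or[sc$feature == "non_measurable_one_reader"], want)
  # degenerate features are reported, not dropped
  expect_match(sc$note[sc$feature == "no_disease_one_reader"], "degenerate")
  expect_match(sc$note[sc$feature == "sprop_sod"], "degenerate")
  # continuous feature gets a rank-sum p
  expect_true(is.finite(sc$p[sc$feature == "delta_burden"]))
  expect_error(univariate_screen(feats, transform(kods, bor = TRUE), "BOR"),
               "constant")
})

test_that("type-I error of the screen is calibrated under the null", {
  set.seed(77)
  n <- 120
  p_vals <- replicate(400, {
    x <- runif(n) < 0.4
    y <- runif(n) < 0.3
    odds_ratio(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))$p.value
  })
  # Wald p on an OR screen: rejection rate should sit near 5%
  expect_lt(abs(mean(p_vals < 0.05) - 0.05), 0.025)
})

test_that("optimize_threshold recovers a constructed split and stays flat on noise", {
  set.seed(12)
  x <- runif(300)
  flag <- x > 0.3
  got <- optimize_threshold(x, flag)
  expect_lt(abs(got$threshold - 0.3), 0.05)
  expect_true(got$corrected)     # separation hits the zero-cell correction
  expect_gt(got$or, 1000)

  # independent feature: no threshold produces a large OR
  flag2 <- runif(300) < 0.3
  got2 <- optimize_threshold(x, flag2, grid = seq(0.1, 0.9, by = 0.1))
  expect_lt(got2$or, 3)
  expect_error(optimize_threshold(rep(1, 10), flag2[1:10]), "distinct")
})
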