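# RECIST 1.1 response derivation.

test_that("sum_of_diameters sums TLs and flags no-measurable disease", {
  obs <- rbind(lesion_row(diameter_mm = 23), lesion_row(lesion_id = "L2", diameter_mm = 31))
  expect_equal(as.numeric(sum_of_diameters(obs)), 54)
  five <- do.call(rbind, lapply(1:5, function(i)
    lesion_row(lesion_id = paste0("L", i), diameter_mm = 10)))
  expect_equal(as.numeric(sum_of_diameters(five)), 50)
  empty <- sum_of_diameters(lesion_row()[0, ])
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "no_measurable"))
  expect_error(sum_of_diameters(lesion_row(category = "NTL")), "target-lesion")
})

test_that("target_response applies the threshold rules with PD precedence", {
  expect_equal(target_response(54, 54, 54), "SD")
  expect_equal(target_response(37, 54, 54), "PR")    # 31.5% decrease
  expect_equal(target_response(30, 54, 24), "PD")    # +25% and +6 mm over nadir
  # 20% over nadir but < 5 mm absolute: not PD
  expect_equal(target_response(24, 30, 20), "SD")
  # CR only when everything is gone; PD still trumps a nominal CR flag
  expect_equal(target_response(5, 54, 54, TRUE, TRUE), "CR")
  expect_equal(target_response(30, 54, 10, TRUE, TRUE), "PD")
  expect_error(target_response(10, 0, 10), "baseline SOD")
})

test_that("target_response matches the brute-force oracle on random inputs", {
  set.seed(31)
  for (i in 1:200) {
    base <- runif(1, 10, 100)
    nadir <- runif(1, 5, base)
    sod <- runif(1, 0, 120)
    got <- target_response(sod, base, min(nadir, base))
    expect_identical(got, oracle_target_response(sod, base, min(nadir, base)))
  }
})

test_that("overall_response encodes the integration table", {
  expect_equal(overall_response("PR", "NON_CR_NON_PD", FALSE), "PR")
  expect_equal(overall_response("CR", "NON_CR_NON_PD", FALSE), "PR")
  expect_equal(overall_response("CR", "CR", FALSE), "CR")
  expect_equal(overall_response("CR", NA, FALSE), "CR")
  expect_equal(overall_response("SD", "NON_CR_NON_PD", TRUE), "PD")
  expect_equal(overall_response("SD", "PD", FALSE), "PD")
  expect_equal(overall_response("PD", "CR", FALSE), "PD")
  expect_equal(overall_response("NE", "NON_CR_NON_PD", FALSE), "NE")
  # NTL-only disease maps non-CR/non-PD to SD
  expect_equal(overall_response(NA, "NON_CR_NON_PD", FALSE), "SD")
  expect_equal(overall_response(NA, "CR", FALSE), "CR")
  expect_error(overall_response(NA, NA, FALSE), "no disease")
})

test_that("build_timelines derives per-reader timelines deterministically", {
  mk_patient <- function(reader, d2 = 20) rbind(
    lesion_row(reader_id = reader, visit_index = 0L, diameter_mm = 20),
    lesion_row(reader_id = reader, visit_index = 1L, diameter_mm = 20),
    lesion_row(reader_id = reader, visit_index = 2L, diameter_mm = d2),
    lesion_row(reader_id = reader, lesion_id = "N1", category = "NTL",
               organ = "LIVER", visit_index = 0L, diameter_mm = NA,
               ntl_status = "PRESENT"),
    lesion_row(reader_id = reader, lesion_id = "N1", category = "NTL",
               organ = "LIVER", visit_index = 1L, diameter_mm = NA,
               ntl_status = "PRESENT"),
    lesion_row(reader_id = reader, lesion_id = "N1", category = "NTL",
               organ = "LIVER", visit_index = 2L, diameter_mm = NA,
               ntl_status = "PRESENT"))

  stable <- rbind(mk_patient("R1"), mk_patient("R2"))
  tl <- build_timelines(stable)
  expect_equal(nrow(tl), 4L)
  expect_true(all(tl$overall == "SD"))
  expect_identical(build_timelines(stable), tl)

  # a 31% shrink at visit 2 for reader 1 only
  shrink <- rbind(mk_patient("R1", d2 = 13.8), mk_patient("R2"))
  tl2 <- build_timelines(shrink)
  expect_equal(tl2$overall[tl2$reader_id == "R1" & tl2$visit_index == 2], "PR")
  expect_equal(tl2$overall[tl2$reader_id == "R2" & tl2$visit_index == 2], "SD")

  # a NEW lesion at visit 2 forces PD from then on
  nl <- rbind(mk_patient("R1"),
              lesion_row(reader_id = "R1", lesion_id = "NEW1",
                         category = "NEW", visit_index = 2L, diameter_mm = 9))
  tl3 <- build_timelines(nl)
  expect_equal(tl3$overall[tl3$visit_index == 2], "PD")
  expect_equal(tl3$overall[tl3$visit_index == 1], "SD")
})

test_that("build_timelines handles missing baselines, NE visits and reader relabeling", {
  # reader without baseline is dropped with a warning
  nobase <- rbind(
    lesion_row(reader_id = "R1", visit_index = 0L),
    lesion_row(reader_id = "R1", visit_index = 1L),
    lesion_row(reader_id = "R2", visit_index = 1L))
  expect_warning(tl <- build_timelines(nobase), "baseline")
  expect_setequal(unique(tl$reader_id), "R1")

  # a patient-visit with no rows for one reader becomes NE and never
  # updates the nadir
  ne <- rbind(
    lesion_row(visit_index = 0L, diameter_mm = 50),
    lesion_row(visit_index = 1L, diameter_mm = 10),   # deep but noisy dip...
    lesion_row(visit_index = 3L, diameter_mm = 50),
    lesion_row(reader_id = "R2", visit_index = 0L, diameter_mm = 50),
    lesion_row(reader_id = "R2", visit_index = 1L, diameter_mm = 50),
    lesion_row(reader_id = "R2", visit_index = 2L, diameter_mm = 50),
    lesion_row(reader_id = "R2", visit_index = 3L, diameter_mm = 50))
  tl <- build_timelines(ne)
  expect_equal(tl$overall[tl$reader_id == "R1" & tl$visit_index == 2], "NE")
  # R1: visit 3 is PD versus the visit-1 nadir of 10
  expect_equal(tl$overall[tl$reader_id == "R1" & tl$visit_index == 3], "PD")
  # R2 never dipped: SD throughout
  expect_true(all(tl$overall[tl$reader_id == "R2"] == "SD"))

  # reader symmetry: relabeling readers permutes rows, not values
  swapped <- ne
  swapped$reader_id <- ifelse(swapped$reader_id == "R1", "R2", "R1")
  tls <- build_timelines(swapped)
  a <- tl[order(tl$reader_id, tl$visit_index), "overall"]
  b <- tls[order(ifelse(tls$reader_id == "R1", "R2", "R1"), tls$visit_index), "overall"]
  expect_identical(a, b)
})

test_that("build_timelines matches a brute-force oracle on random small tables", {
  set.seed(99)
  for (rep in 1:25) {
    n_les <- sample(1:3, 1)
    n_vis <- sample(2:4, 1)
    base <- runif(n_les, 12, 60)
    rows <- list()
    d <- matrix(0, n_les, n_vis + 1)
    for (l in seq_len(n_les)) {
      d[l, ] <- c(base[l], base[l] * exp(cumsum(rnorm(n_vis, 0, 0.25))))
      for (v in 0:n_vis)
        rows[[length(rows) + 1L]] <- lesion_row(
          lesion_id = paste0("L", l), visit_index = v,
          diameter_mm = round(d[l, v + 1]))
    }
    tab <- do.call(rbind, rows)
    tl <- build_timelines(tab)
    sods <- colSums(matrix(round(d), n_les), dims = 1)
    for (v in seq_len(n_vis)) {
      nadir <- min(sods[1:v])
      want <- oracle_target_response(sods[v + 1], sods[1], min(nadir, sods[1]))
      expect_identical(tl$overall[tl$visit_index == v], want)
    }
  }
})

test_that("validate_lesion_table rejects malformed input", {
  expect_error(validate_lesion_table(data.frame(patient_id = 1)), "missing columns")
  bad <- lesion_row(category = "NEW", visit_index = 0L)
  expect_error(validate_lesion_table(bad), "baseline")
  neg <- lesion_row(diameter_mm = -1)
  expect_error(validate_lesion_table(neg), "diameter")
})
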