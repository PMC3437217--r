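test_that("last_k returns the final min(k, n) elements", {
  expect_identical(last_k(letters[1:4], 3), c("b", "c", "d"))
  expect_identical(last_k(letters[1], 3), "a")
  expect_identical(last_k(character(0), 3), character(0))
  df <- data.frame(date = as.Date("2009-01-01") + 1:4, value = 1:4)
  expect_identical(last_k(df, 3)$value, 2:4)
})

test_that("glycemic control follows the modified HbA1c-or-glucose target", {
  expect_identical(glycemic_control(
    fake_tl(glucose = c(140, 128, 130, 125))), "met")
  expect_identical(glycemic_control(fake_tl(hba1c = 7.0)), "not_met")
  expect_identical(glycemic_control(fake_tl(hba1c = 6.9)), "met")
  # one uncontrolled value among the last three blocks the HbA1c route
  expect_identical(glycemic_control(
    fake_tl(hba1c = c(6.5, 7.2, 6.8))), "not_met")
  # either route suffices
  expect_identical(glycemic_control(
    fake_tl(hba1c = c(8, 8, 8), glucose = c(120, 110))), "met")
  expect_identical(glycemic_control(fake_tl()), "undetermined")
})

test_that("blood-pressure control requires all last-three pairs < 130/80", {
  expect_identical(bp_control(
    fake_tl(bp = rbind(c(125, 75), c(128, 79), c(120, 70)))), "met")
  expect_identical(bp_control(fake_tl(bp = rbind(c(130, 79)))), "not_met")
  expect_identical(bp_control(fake_tl(bp = rbind(c(129, 80)))), "not_met")
  # only the last three pairs count
  expect_identical(bp_control(fake_tl(
    bp = rbind(c(180, 110), c(125, 75), c(124, 74), c(120, 70)))), "met")
  expect_identical(bp_control(fake_tl()), "undetermined")
})

test_that("weight change is the first-to-last relative difference", {
  expect_identical(weight_change_pct(fake_tl(weight = c(100, 94))), -6)
  expect_identical(weight_change_pct(fake_tl(weight = c(100, 96))), -4)
  expect_true(is.na(weight_change_pct(fake_tl(weight = 100))))
})

test_that("indicator rules respect eligibility and contraindications", {
  vit27 <- mk_vit("T1", "2009-02-01", w = 69.1, h = 160)  # BMI 27
  rx_met <- mk_rx("T1", "2009-11-20", "metformin", 1700)
  tl <- mk_timeline(vitals = vit27, rx = rx_met)
  expect_identical(evaluate_indicator("P6", tl), "numerator")

  # metformin only at an early visit, outside the last three
  tl2 <- mk_timeline(vitals = vit27,
                     rx = mk_rx("T1", "2009-02-01", "metformin", 1700))
  expect_identical(evaluate_indicator("P6", tl2), "denominator_only")

  # contraindication excludes from the denominator
  tl3 <- mk_timeline(vitals = vit27, rx = rx_met,
                     patient = mk_patient("T1", contra = "metformin"))
  expect_identical(evaluate_indicator("P6", tl3), "not_in_denominator")

  # age 38 with risk factors: not in the ASA denominator
  tl4 <- mk_timeline(patient = mk_patient("T1", birth = "1970-06-01"),
                     dx = rbind(mk_dx("T1", "E112", "2008-03-01"),
                                mk_dx("T1", "I10", "2007-01-01")),
                     rx = mk_rx("T1", "2009-11-20",
                                "acetylsalicylic_acid", 100))
  expect_identical(evaluate_indicator("P8", tl4), "not_in_denominator")
  # same prescription at 55 with hypertension: numerator
  tl5 <- mk_timeline(patient = mk_patient("T1", birth = "1953-06-01"),
                     dx = rbind(mk_dx("T1", "E112", "2008-03-01"),
                                mk_dx("T1", "I10", "2007-01-01")),
                     rx = mk_rx("T1", "2009-11-20",
                                "acetylsalicylic_acid", 100))
  expect_identical(evaluate_indicator("P8", tl5), "numerator")
  # wrong ASA dose does not count
  tl6 <- mk_timeline(patient = mk_patient("T1", birth = "1953-06-01"),
                     dx = rbind(mk_dx("T1", "E112", "2008-03-01"),
                                mk_dx("T1", "I10", "2007-01-01")),
                     rx = mk_rx("T1", "2009-11-20",
                                "acetylsalicylic_acid", 300))
  expect_identical(evaluate_indicator("P8", tl6), "denominator_only")

  # statin indicator needs a last cholesterol above 200
  tl7 <- mk_timeline(labs = mk_lab("T1", "2009-05-01",
                                   "total_cholesterol_mg_dl", 230),
                     rx = mk_rx("T1", "2009-11-20", "statin", 20))
  expect_identical(evaluate_indicator("P9", tl7), "numerator")
  tl8 <- mk_timeline(labs = mk_lab("T1", "2009-05-01",
                                   "total_cholesterol_mg_dl", 180))
  expect_identical(evaluate_indicator("P9", tl8), "not_in_denominator")
  expect_identical(evaluate_indicator("O2", tl8), "numerator")
})

test_that("inactive catalog entries refuse evaluation", {
  tl <- mk_timeline()
  expect_error(evaluate_indicator("N1", tl), "not programmable")
  expect_error(evaluate_indicator("D1", tl), "not programmable")
  expect_error(evaluate_indicator("XX", tl), "unknown indicator")
})

test_that("evaluate_all matches a hand tally on a built fixture", {
  ids <- sprintf("H%02d", 1:6)
  pts <- do.call(rbind, lapply(ids, function(i)
    mk_patient(i, clinic = if (i <= "H03") "FMC01" else "FMC02")))
  dx <- do.call(rbind, lapply(ids, function(i)
    mk_dx(i, "E112", "2008-01-01")))
  vis <- do.call(rbind, lapply(ids, function(i) mk_vis(
    i, "2009-03-01", clinic = if (i <= "H03") "FMC01" else "FMC02")))
  # H01, H02 get a foot exam; H04 gets one too
  ce <- rbind(mk_ce("H01", "2009-04-01", "foot_exam"),
              mk_ce("H02", "2009-04-02", "foot_exam"),
              mk_ce("H04", "2009-04-03", "foot_exam"))
  co <- select_cohort(mk_bundle(pts, diagnoses = dx, visits = vis,
                                care_events = ce))
  res <- as.data.frame(evaluate_all(co))
  p2 <- res[res$indicator == "P2", ]
  expect_identical(p2$numerator[p2$clinic_id == "FMC01"], 2L)
  expect_identical(p2$denominator[p2$clinic_id == "FMC01"], 3L)
  expect_identical(p2$numerator[p2$clinic_id == "FMC02"], 1L)
  expect_identical(p2$numerator[p2$clinic_id == "Total"], 3L)
  expect_identical(p2$denominator[p2$clinic_id == "Total"], 6L)
  expect_equal(p2$percentage[p2$clinic_id == "Total"], 50)
  # pooled counts are sums of clinic counts, for every indicator
  for (id in unique(res$indicator)) {
    r <- res[res$indicator == id, ]
    expect_identical(sum(r$numerator[r$clinic_id != "Total"]),
                     r$numerator[r$clinic_id == "Total"])
    expect_identical(sum(r$denominator[r$clinic_id != "Total"]),
                     r$denominator[r$clinic_id == "Total"])
  }
})

test_that("an empty cohort yields 0/0 results with undefined percentages", {
  co <- select_cohort(mk_bundle(mk_patient("A")))  # no diagnoses at all
  res <- as.data.frame(evaluate_all(co))
  expect_identical(nrow(res), 14L)  # one pooled row per active indicator
  expect_true(all(res$numerator == 0 & res$denominator == 0))
  expect_true(all(is.na(res$percentage)))
})

test_that("single-clinic pooled results equal the clinic results", {
  cfg <- sim_config(n_clinics = 1, members_per_clinic = 300, seed = 2)
  co <- select_cohort(generate_population(cfg))
  res <- as.data.frame(evaluate_all(co))
  a <- res[res$clinic_id != "Total", ]
  b <- res[res$clinic_id == "Total", ]
  expect_identical(a$numerator, b$numerator)
  expect_identical(a$denominator, b$denominator)
})

test_that("each patient lands in exactly one tri-state per indicator", {
  cfg <- sim_config(n_clinics = 2, members_per_clinic = 300, seed = 6)
  co <- select_cohort(generate_population(cfg))
  po <- patient_indicator_outcomes(co)
  states <- c("not_in_denominator", "denominator_only", "numerator")
  for (id in setdiff(names(po), c("patient_id", "clinic_id"))) {
    expect_true(all(po[[id]] %in% states))
  }
  expect_identical(nrow(po), length(co$timelines))
})

test_that("removing a contraindication never shrinks a denominator", {
  cfg <- sim_config(n_clinics = 2, members_per_clinic = 250,
                    contraindication_rate = 0.3, seed = 13)
  b <- generate_population(cfg)
  res1 <- as.data.frame(evaluate_all(select_cohort(b)))
  b2 <- b
  b2$patients$contraindications <- ""
  res2 <- as.data.frame(evaluate_all(select_cohort(b2)))
  expect_true(all(res2$denominator >= res1$denominator))
})

test_that("pooled percentages sit within the clinic range", {
  cfg <- sim_config(n_clinics = 3, members_per_clinic = 400, seed = 21)
  res <- as.data.frame(evaluate_all(select_cohort(
    generate_population(cfg))))
  for (id in unique(res$indicator)) {
    r <- res[res$indicator == id, ]
    cl <- r$percentage[r$clinic_id != "Total"]
    cl <- cl[!is.na(cl)]
    tot <- r$percentage[r$clinic_id == "Total"]
    if (length(cl) && !is.na(tot)) {
      expect_gte(tot, min(cl) - 1e-9)
      expect_lte(tot, max(cl) + 1e-9)
    }
  }
})

test_that("engine counts equal the generator's ground-truth sidecar", {
  cfg <- sim_config(n_clinics = 3, members_per_clinic = 700, seed = 11)
  b <- generate_population(cfg)
  res <- as.data.frame(evaluate_all(select_cohort(b)))
  truth <- attr(b, "truth")
  agg <- aggregate(cbind(eligible, numerator) ~ indicator, truth, sum)
  tot <- res[res$clinic_id == "Total", ]
  m <- merge(tot, agg, by = "indicator")
  expect_identical(nrow(m), 14L)
  expect_identical(m$denominator, as.integer(m$eligible))
  expect_identical(m$numerator.x, as.integer(m$numerator.y))
})
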