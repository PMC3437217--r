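test_that("ICD-10 T2DM matching is exact after case/dot normalisation", {
  expect_true(is_t2dm_code("E112"))
  expect_true(is_t2dm_code("e14x"))
  expect_true(is_t2dm_code("E11.2"))
  expect_true(is_t2dm_code("E14"))
  expect_false(is_t2dm_code("E101"))   # type 1
  expect_false(is_t2dm_code("E110"))   # not in the enumerated set
  expect_false(is_t2dm_code("I10"))
  expect_identical(is_t2dm_code(c("E112", "E101", "E149")),
                   c(TRUE, FALSE, TRUE))
})

test_that("plausibility bounds are strict outside, inclusive at the edge", {
  expect_false(plausible("systolic", 49))
  expect_true(plausible("systolic", 50))
  expect_true(plausible("systolic", 250))
  expect_false(plausible("systolic", 251))
  expect_false(plausible("fasting_glucose", 36))
  expect_true(plausible("fasting_glucose", 37))
  expect_true(plausible("fasting_glucose", 600))  # no upper bound
  expect_false(plausible("weight", 29))
  expect_true(plausible("weight", 200))
  expect_false(plausible("weight", 201))
  expect_false(plausible("hba1c", 2.9))
  expect_false(plausible("total_cholesterol", 99))
  expect_error(plausible("shoe_size", 42), "configuration error")
})

test_that("cleaning keeps exactly the plausible values, date-sorted", {
  empty <- data.frame(date = as.Date(character(0)), value = numeric(0))
  out <- clean_measurements(empty, "weight")
  expect_identical(nrow(out$series), 0L)
  expect_identical(nrow(out$exclusions), 0L)

  s <- data.frame(date = as.Date("2009-03-01") + c(2, 0, 1),
                  value = c(201, 29, 80))
  out <- clean_measurements(s, "weight")
  expect_identical(out$series$value, 80)
  expect_identical(nrow(out$exclusions), 2L)
  expect_setequal(out$exclusions$value, c(29, 201))
  # idempotence
  out2 <- clean_measurements(out$series, "weight")
  expect_identical(out2$series, out$series)
  expect_identical(nrow(out2$exclusions), 0L)
})

test_that("BMI computation and classification follow the standard cutoffs", {
  expect_identical(compute_bmi(80, 160), 31.25)
  expect_identical(compute_bmi(57.6, 160), 22.5)
  expect_true(is.na(compute_bmi(29, 160)))    # implausible weight
  expect_true(is.na(compute_bmi(NA, 160)))
  expect_identical(classify_bmi(c(18.49, 18.5, 24.9, 25.0, 29.9, 30.0)),
                   c("underweight", "normal", "normal", "overweight",
                     "overweight", "obese"))
  expect_true(is.na(classify_bmi(NA_real_)))
})

test_that("cohort selection applies the three criteria with logged reasons", {
  pts <- rbind(
    mk_patient("ADULT", birth = "1963-06-01"),
    mk_patient("TEEN", birth = "1989-06-15"),      # 19 at window start
    mk_patient("NOVISIT", birth = "1950-01-01"),
    mk_patient("NOTDM", birth = "1950-01-01"))
  dx <- rbind(mk_dx("ADULT", "E11.2", "2007-05-01", slot = 2),
              mk_dx("TEEN", "E149", "2008-01-01"),
              mk_dx("NOVISIT", "E14X", "2008-01-01"),
              mk_dx("NOTDM", "I10", "2008-01-01"))
  vis <- rbind(mk_vis("ADULT", "2009-04-01"),
               mk_vis("TEEN", "2009-04-01"),
               mk_vis("TEEN", "2009-05-01"),
               mk_vis("TEEN", "2009-06-01"),
               mk_vis("NOVISIT", "2008-12-30"),   # outside window
               mk_vis("NOTDM", "2009-04-01"))
  co <- select_cohort(mk_bundle(pts, diagnoses = dx, visits = vis))
  expect_identical(names(co$timelines), "ADULT")
  ex <- co$exclusions
  expect_identical(ex$reason[ex$patient_id == "TEEN"], "age")
  expect_identical(ex$reason[ex$patient_id == "NOVISIT"],
                   "no visit in window")
  expect_false("NOTDM" %in% ex$patient_id)  # never T2DM-coded
  # monotonicity: adding a qualifying visit never removes anyone
  vis2 <- rbind(vis, mk_vis("NOVISIT", "2009-07-07"))
  co2 <- select_cohort(mk_bundle(pts, diagnoses = dx, visits = vis2))
  expect_true(all(names(co$timelines) %in% names(co2$timelines)))
  expect_setequal(names(co2$timelines), c("ADULT", "NOVISIT"))
})

test_that("a 20-year-old at the window start is eligible", {
  pts <- mk_patient("JUST20", birth = "1988-12-31")
  b <- mk_bundle(pts, diagnoses = mk_dx("JUST20", "E112", "2008-06-01"),
                 visits = mk_vis("JUST20", "2009-02-01"))
  expect_identical(names(select_cohort(b)$timelines), "JUST20")
})

test_that("timelines carry history flags, cleaned series and BMI anchors", {
  tl <- mk_timeline(
    dx = rbind(mk_dx("T1", "E112", "2008-03-01"),
               mk_dx("T1", "I10", "2007-06-01"),      # history counts
               mk_dx("T1", "E780", "2009-05-01")),    # in-window dyslipidemia
    vitals = rbind(
      mk_vit("T1", "2009-02-01", w = 80, h = 160, s = 120, d = 70),
      mk_vit("T1", "2009-06-15", w = 25, s = 400, d = 75),  # implausible
      mk_vit("T1", "2009-11-20", w = 76, h = 160, s = 125, d = 78)))
  expect_true(tl$comorbidity$hypertension)
  expect_true(tl$comorbidity$dyslipidemia)
  # dyslipidemia first coded in-window: still screening-eligible (P4)
  expect_false(tl$dyslipidemia_before_window)
  expect_identical(tl$weight$value, c(80, 76))
  expect_identical(nrow(tl$bp), 2L)  # the 400/75 record pairs out
  expect_setequal(tl$cleaning_log$value, c(25, 400))
  expect_identical(tl$bmi_first$value, 31.25)
  expect_identical(tl$bmi_first$category, "obese")
  expect_identical(tl$bmi_last$value, 29.69)
  expect_identical(tl$bmi_last$category, "overweight")
  expect_identical(weight_change_pct(tl), -5)
})

test_that("patients without vitals have missing BMI anchors", {
  tl <- mk_timeline()
  expect_true(is.na(tl$bmi_first$value))
  expect_true(is.na(tl$bmi_last$value))
  expect_true(is.na(weight_change_pct(tl)))
})

test_that("same-day duplicate measurements keep the last by file order", {
  tl <- mk_timeline(vitals = rbind(
    mk_vit("T1", "2009-02-01", w = 90, h = 160),
    mk_vit("T1", "2009-02-01", w = 82, h = 160)))
  expect_identical(tl$weight$value, 82)
  expect_identical(nrow(tl$duplicate_log), 1L)
  expect_match(tl$duplicate_log$issue, "duplicate")
})

test_that("cohort selection agrees with a naive scan on random bundles", {
  for (seed in 1:10) {
    cfg <- sim_config(n_clinics = 2, members_per_clinic = 30,
                      attendance_probability = 0.7, t2dm_prevalence = 0.5,
                      seed = seed)
    b <- inject_data_defects(generate_population(cfg), cfg)
    expect_setequal(names(select_cohort(b)$timelines),
                    oracle_select_ids(b))
  }
})
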