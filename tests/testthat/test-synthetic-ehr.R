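small_cfg <- function(...) {
  sim_config(n_clinics = 2, members_per_clinic = 300, seed = 42, ...)
}

test_that("an identical seed yields an identical bundle", {
  b1 <- generate_population(small_cfg())
  b2 <- generate_population(small_cfg())
  expect_identical(b1, b2)
  # and defect injection is equally seed-determined
  cfg <- small_cfg()
  expect_identical(inject_data_defects(b1, cfg), inject_data_defects(b2, cfg))
})

test_that("zero members yield an empty bundle, invalid probabilities error", {
  b <- generate_population(sim_config(n_clinics = 2, members_per_clinic = 0,
                                      seed = 1))
  expect_identical(nrow(b$patients), 0L)
  expect_error(sim_config(t2dm_prevalence = 1.2), "config error")
  expect_error(sim_config(attendance_probability = -0.1), "config error")
})

test_that("zero prevalence produces no T2DM-coded patient", {
  cfg <- sim_config(n_clinics = 2, members_per_clinic = 600,
                    attendance_probability = 0.9, t2dm_prevalence = 0,
                    seed = 5)
  b <- generate_population(cfg)
  expect_gt(nrow(b$patients), 1000)
  expect_false(any(is_t2dm_code(b$diagnoses$icd10_code)))
})

test_that("T2DM counts converge to the configured prevalence", {
  # 10,000 adult attendees at prevalence 0.144: the number of T2DM-coded
  # patients is binomial, so it should sit within 3 SE of 1,440
  cfg <- sim_config(n_clinics = 4, members_per_clinic = 2500,
                    attendance_probability = 1, t2dm_prevalence = 0.144,
                    youth_fraction = 0, nonattendee_fraction = 0,
                    seed = 2024)
  b <- generate_population(cfg)
  n <- nrow(b$patients)
  expect_identical(n, 10000L)
  n_t2dm <- length(unique(
    b$diagnoses$patient_id[is_t2dm_code(b$diagnoses$icd10_code)]))
  se <- sqrt(n * 0.144 * (1 - 0.144))
  expect_lt(abs(n_t2dm - n * 0.144), 3 * se)
})

test_that("visit counts match the configured mean", {
  cfg <- sim_config(n_clinics = 4, members_per_clinic = 1250,
                    attendance_probability = 1, t2dm_prevalence = 1,
                    youth_fraction = 0, nonattendee_fraction = 0,
                    seed = 77)
  b <- generate_population(cfg)
  v <- b$visits[b$visits$visit_type == "family_doctor", ]
  per_patient <- table(v$patient_id)
  expect_gte(min(per_patient), 1)  # attendees attend
  m <- mean(per_patient)
  expect_gte(m, 8.6)
  expect_lte(m, 9.0)
})

test_that("per-patient histories honour adherence and lab availability", {
  p <- mk_patient("X1", clinic = "FMC01", birth = "1950-01-01",
                  onset = 2000)
  cfg <- sim_config(indicator_adherence = c(P3 = 1, P5 = 1, P2 = 0),
                    seed = 1)
  set.seed(9)
  h <- generate_patient_history(p, cfg)
  expect_true(any(h$care_events$kind == "ophthalmology_referral"))
  expect_false(any(h$care_events$kind == "foot_exam"))
  expect_true(any(h$visits$visit_type == "nutrition_service"))

  # clinic without HbA1c testing: no resulted HbA1c values at all
  cfg2 <- sim_config(n_clinics = 2,
                     lab_availability_by_clinic = c(FALSE, TRUE),
                     indicator_adherence = c(P1 = 1), seed = 1)
  set.seed(10)
  h2 <- generate_patient_history(p, cfg2)  # FMC01 lacks the assay
  hb <- h2$labs[h2$labs$analyte == "hba1c_pct" &
                  h2$labs$status == "resulted", ]
  expect_identical(nrow(hb), 0L)
})

test_that("defect injection at rate 0 is the identity", {
  cfg <- small_cfg()
  b <- generate_population(cfg)
  cfg0 <- sim_config(n_clinics = 2, members_per_clinic = 300, seed = 42,
                     missingness_rates = c(schooling = 0),
                     implausible_rates = c(weight = 0))
  b0 <- inject_data_defects(b, cfg0)
  for (nm in c("patients", "vitals")) {
    expect_identical(as.data.frame(b0[[nm]]), as.data.frame(b[[nm]]))
  }
  expect_identical(nrow(attr(b0, "defect_log")), 0L)
})

test_that("missingness rate 1 blanks the targeted field everywhere", {
  cfg <- small_cfg()
  b <- generate_population(cfg)
  cfg1 <- sim_config(n_clinics = 2, members_per_clinic = 300, seed = 42,
                     missingness_rates = c(schooling = 1))
  b1 <- inject_data_defects(b, cfg1)
  expect_true(all(is.na(b1$patients$schooling)))
  # untouched fields stay intact
  expect_identical(b1$patients$marital_status, b$patients$marital_status)
})

test_that("implausible injection hits its configured rate and only values", {
  cfg <- sim_config(n_clinics = 2, members_per_clinic = 2000,
                    attendance_probability = 1, t2dm_prevalence = 1,
                    youth_fraction = 0, nonattendee_fraction = 0,
                    missingness_rates = c(bmi = 0),
                    implausible_rates = c(weight = 0.10),
                    seed = 8)
  b <- generate_population(cfg)
  bd <- inject_data_defects(b, cfg)
  # record counts never change, only field values
  for (nm in names(bd)[!vapply(bd, is.null, logical(1))]) {
    expect_identical(nrow(bd[[nm]]), nrow(b[[nm]]))
  }
  w <- bd$vitals$weight_kg[!is.na(bd$vitals$weight_kg)]
  n <- length(w)
  expect_gt(n, 5000)
  frac_bad <- mean(!plausible("weight", w))
  expect_lt(abs(frac_bad - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  # every injected value violates the bounds, and every violation was logged
  dl <- attr(bd, "defect_log")
  expect_true(all(dl$measure == "weight"))
  expect_false(any(plausible("weight", dl$value)))
  expect_identical(nrow(dl), sum(!plausible("weight", w)))
})

test_that("generated bundles survive the read/write round trip", {
  cfg <- small_cfg()
  b <- inject_data_defects(generate_population(cfg), cfg)
  d <- withr::local_tempdir()
  write_ehr_bundle(b, d)
  b2 <- read_ehr_bundle(d)
  for (nm in c("patients", "diagnoses", "visits", "vitals",
               "prescriptions", "labs", "care_events")) {
    expect_identical(as.data.frame(b2[[nm]]), as.data.frame(b[[nm]]),
                     info = nm)
  }
})
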