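# Seeded synthetic multi-clinic EHR generator.
#
# Emulates the statistical structure the analysis assumes: a multi-clinic
# adult primary-care population, ~14% T2DM prevalence among attendees,
# study-like demographics, comorbidity prevalences and visit frequencies,
# field-level missingness, implausible-vitals contamination, and
# configurable per-indicator adherence probabilities. Events are generated
# eligibility-first (comorbidity, BMI, contraindications drawn before
# numerator events), so each indicator's observed rate converges to its
# configured adherence among the eligible. A ground-truth sidecar (true
# eligibility and numerator flags per patient) is attached for testing.

#' Simulation configuration
#'
#' All probabilities are validated to lie in \[0, 1\]; the seed fully
#' determines the generated bundle. Defaults are the study-like conditions
#' documented in the methods vignette: 14.4\% T2DM prevalence among clinic
#' attendees, T2DM ages ~ N(62.3, 12.9^2) truncated to adults, 58.5\%
#' female, comorbidity prevalences (hypertension 0.604, dyslipidemia 0.416,
#' other CVD 0.092, chronic complication 0.317), negative-binomial visit
#' counts with mean 8.8 and sd 4.6 (truncated at one visit, since attendees
#' attend), and field-level missingness / implausible-vitals rates applied
#' by [inject_data_defects()].
#'
#' @param n_clinics,members_per_clinic clinic count and adult members per
#'   clinic.
#' @param attendance_probability probability a member attends during the
#'   observation year.
#' @param t2dm_prevalence T2DM prevalence among adult attendees.
#' @param observation_year calendar observation year.
#' @param age_mean_t2dm,age_sd_t2dm,age_mean_other,age_sd_other adult age
#'   distributions (years), truncated to \[20, 99\].
#' @param female_fraction probability of female sex.
#' @param comorbidity_prevalences named probabilities for `hypertension`,
#'   `dyslipidemia`, `other_cvd`, `chronic_complication`.
#' @param smoking_prevalence probability of a recorded tobacco-use code.
#' @param complication_type_weights relative weights of the four chronic
#'   complication types.
#' @param visits_per_year_mean,visits_per_year_sd family-doctor visit count
#'   distribution (negative binomial matched to mean and sd, >= 1).
#' @param bmi_category_probabilities probabilities over underweight /
#'   normal / overweight / obese (normalised internally).
#' @param schooling_probabilities,marital_probabilities,
#'   employment_probabilities categorical distributions conditional on the
#'   field being recorded.
#' @param insurance_subscriber_fraction probability of subscriber role.
#' @param duration_category_probabilities diabetes-duration categories
#'   (<5, 5-10, 11-15, >15 years) conditional on onset being recorded.
#' @param missingness_rates per-field missingness probabilities applied by
#'   [inject_data_defects()] (`schooling`, `marital_status`, `employment`,
#'   `diabetes_onset_year`, `bmi`).
#' @param implausible_rates per-measure probabilities that a recorded vital
#'   is replaced by a value strictly outside the plausibility bounds.
#' @param indicator_adherence named per-indicator probabilities that an
#'   eligible patient meets the numerator.
#' @param contraindication_rate per-flag probability of a drug
#'   contraindication.
#' @param glucose_result_prob,cholesterol_result_prob availability of
#'   resulted fasting-glucose / total-cholesterol values (cholesterol rate
#'   applies to patients with prior dyslipidemia; screening of the others is
#'   governed by the `P4` adherence).
#' @param lab_order_only_prob probability of a lab order without a result
#'   (patient did not attend the laboratory).
#' @param lab_availability_by_clinic logical vector (recycled) flagging
#'   clinics where HbA1c testing is available; default all available.
#' @param youth_fraction,nonattendee_fraction small fractions of under-20
#'   attendees and of patients whose visits fall outside the observation
#'   year, so cohort exclusion paths are exercised.
#' @param bp_record_prob probability that blood pressure is recorded at a
#'   given visit (always recorded at the first and last visit).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_clinics = 4L,
                       members_per_clinic = 2000L,
                       attendance_probability = 0.40,
                       t2dm_prevalence = 0.144,
                       observation_year = 2009L,
                       age_mean_t2dm = 62.3, age_sd_t2dm = 12.9,
                       age_mean_other = 48, age_sd_other = 16,
                       female_fraction = 0.585,
                       comorbidity_prevalences = c(hypertension = 0.604,
                                                   dyslipidemia = 0.416,
                                                   other_cvd = 0.092,
                                                   chronic_complication = 0.317),
                       smoking_prevalence = 0.15,
                       complication_type_weights = c(peripheral_vascular = 14.5,
                                                     nephropathy = 10.6,
                                                     retinopathy = 7.9,
                                                     neuropathy = 4.9),
                       visits_per_year_mean = 8.8,
                       visits_per_year_sd = 4.6,
                       bmi_category_probabilities = c(underweight = 0.0035,
                                                      normal = 0.1832,
                                                      overweight = 0.4189,
                                                      obese = 0.3944),
                       schooling_probabilities = c(illiterate = 12.4,
                                                   primary = 26.8,
                                                   secondary = 12.3,
                                                   high_school = 12.7,
                                                   university = 7.0),
                       marital_probabilities = c(married_partner = 46.2,
                                                 single_divorced = 9.7,
                                                 widowed = 13.0),
                       employment_probabilities = c(housewife = 29.3,
                                                    employed = 17.5,
                                                    unemployed = 0.2,
                                                    retired = 10.4),
                       insurance_subscriber_fraction = 0.233,
                       duration_category_probabilities = c(lt5 = 2.4,
                                                           y5_10 = 8.5,
                                                           y11_15 = 7.9,
                                                           gt15 = 16.6),
                       missingness_rates = c(schooling = 0.287,
                                             marital_status = 0.310,
                                             employment = 0.426,
                                             diabetes_onset_year = 0.645,
                                             bmi = 0.143),
                       implausible_rates = c(weight = 0.05,
                                             height = 0.08,
                                             systolic = 0.12,
                                             diastolic = 0.12),
                       indicator_adherence = c(P1 = 0.071, P2 = 0.303,
                                               P3 = 0.130, P4 = 0.578,
                                               P5 = 0.039, P6 = 0.632,
                                               P7 = 0.574, P8 = 0.434,
                                               P9 = 0.479, O1 = 0.231,
                                               O2 = 0.520, O3 = 0.108,
                                               O4 = 0.133),
                       contraindication_rate = 0.02,
                       glucose_result_prob = 0.62,
                       cholesterol_result_prob = 0.65,
                       lab_order_only_prob = 0.16,
                       lab_availability_by_clinic = NULL,
                       youth_fraction = 0.02,
                       nonattendee_fraction = 0.03,
                       bp_record_prob = 0.95,
                       seed = 1L) {
  stopifnot(n_clinics >= 1, members_per_clinic >= 0)
  .check_prob(attendance_probability, "attendance_probability")
  .check_prob(t2dm_prevalence, "t2dm_prevalence")
  .check_prob(female_fraction, "female_fraction")
  .check_prob(comorbidity_prevalences, "comorbidity_prevalences")
  .check_prob(smoking_prevalence, "smoking_prevalence")
  .check_prob(missingness_rates, "missingness_rates")
  .check_prob(implausible_rates, "implausible_rates")
  .check_prob(indicator_adherence, "indicator_adherence")
  .check_prob(contraindication_rate, "contraindication_rate")
  .check_prob(glucose_result_prob, "glucose_result_prob")
  .check_prob(cholesterol_result_prob, "cholesterol_result_prob")
  .check_prob(lab_order_only_prob, "lab_order_only_prob")
  .check_prob(youth_fraction, "youth_fraction")
  .check_prob(nonattendee_fraction, "nonattendee_fraction")
  .check_prob(bp_record_prob, "bp_record_prob")
  if (visits_per_year_sd^2 <= visits_per_year_mean) {
    stop("config error: visit counts require sd^2 > mean (over-dispersion)",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  # partial adherence maps are merged over the defaults
  adh <- eval(formals(sim_config)$indicator_adherence)
  adh[names(indicator_adherence)] <- indicator_adherence
  cfg$indicator_adherence <- adh
  cfg$bmi_category_probabilities <-
    bmi_category_probabilities / sum(bmi_category_probabilities)
  cfg$schooling_probabilities <-
    schooling_probabilities / sum(schooling_probabilities)
  cfg$marital_probabilities <-
    marital_probabilities / sum(marital_probabilities)
  cfg$employment_probabilities <-
    employment_probabilities / sum(employment_probabilities)
  cfg$duration_category_probabilities <-
    duration_category_probabilities / sum(duration_category_probabilities)
  structure(cfg, class = "sim_config")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# visit counts: negative binomial matched to (mean, sd), truncated at >= 1
.rvisits <- function(n, mu, sd) {
  size <- mu^2 / (sd^2 - mu)
  v <- stats::rnbinom(n, size = size, mu = mu)
  while (any(v == 0)) {
    z <- v == 0
    v[z] <- stats::rnbinom(sum(z), size = size, mu = mu)
  }
  v
}

.window <- function(config) {
  as.Date(sprintf("%d-%s", config$observation_year, c("01-01", "12-31")))
}

# draw all patient-level latent flags for T2DM patients
.draw_flags <- function(pts, config, lab_avail) {
  n <- nrow(pts)
  a <- config$indicator_adherence
  cp <- config$comorbidity_prevalences
  bern <- function(p) stats::runif(n) < p
  fl <- data.frame(patient_id = pts$patient_id, stringsAsFactors = FALSE)
  fl$htn <- bern(cp[["hypertension"]])
  fl$dyslip <- bern(cp[["dyslipidemia"]])
  fl$cvd <- bern(cp[["other_cvd"]])
  fl$compl <- bern(cp[["chronic_complication"]])
  fl$compl_type <- sample(names(config$complication_type_weights), n,
                          replace = TRUE,
                          prob = config$complication_type_weights)
  fl$smoking <- bern(config$smoking_prevalence)
  fl$bmi_cat <- sample(names(config$bmi_category_probabilities), n,
                       replace = TRUE,
                       prob = config$bmi_category_probabilities)
  fl$height <- pmin(pmax(round(stats::rnorm(n, 161, 8)), 140), 195)
  bmi_lo <- c(underweight = 16.5, normal = 18.7, overweight = 25.2,
              obese = 30.2)
  bmi_hi <- c(underweight = 18.3, normal = 24.8, overweight = 29.8,
              obese = 41.0)
  fl$bmi <- stats::runif(n, bmi_lo[fl$bmi_cat], bmi_hi[fl$bmi_cat])
  fl$w_first <- round(fl$bmi * (fl$height / 100)^2, 1)
  fl$n_visits <- .rvisits(n, config$visits_per_year_mean,
                          config$visits_per_year_sd)
  # contraindication flags come from the patient records so the truth
  # sidecar and the engine read the same facts
  sets <- strsplit(ifelse(is.na(pts$contraindications), "",
                          pts$contraindications), "|", fixed = TRUE)
  for (flag in CONTRA_FLAGS) {
    fl[[paste0("contra_", flag)]] <-
      vapply(sets, function(s) flag %in% s, logical(1))
  }
  # adherence draws (one per indicator; eligibility applied downstream)
  for (id in names(a)) fl[[paste0("a_", id)]] <- bern(a[[id]])
  # measurement availability
  fl$hba1c_present <- lab_avail[pts$clinic_id] & fl$a_P1
  fl$glucose_present <- bern(config$glucose_result_prob)
  fl$chol_present <- ifelse(fl$dyslip, bern(config$cholesterol_result_prob),
                            fl$a_P4)
  fl$order_only <- bern(config$lab_order_only_prob)
  # control states (outcome adherence)
  fl$c_O1 <- fl$a_O1; fl$c_O2 <- fl$a_O2; fl$c_O3 <- fl$a_O3
  # weight trajectory: >= 5.5% loss if O4-adherent, else bounded change
  loss <- ifelse(fl$a_O4, -stats::runif(n, 0.055, 0.12),
                 stats::runif(n, -0.045, 0.06))
  fl$w_last <- round(fl$w_first * (1 + loss), 1)
  fl
}

# histories + truth for a set of T2DM patients with drawn flags
.gen_histories <- function(pts, fl, config) {
  n <- nrow(pts)
  w <- .window(config)
  ndays <- as.integer(w[2] - w[1]) + 1L
  rand_dates <- function(k) w[1] + (sample.int(ndays, k, replace = TRUE) - 1L)

  day_list <- lapply(fl$n_visits, function(k) sort(sample.int(ndays,
                                                              min(k, ndays))))
  nv <- lengths(day_list)
  first_date <- w[1] + (vapply(day_list, function(d) d[1], 1L) - 1L)
  last_date <- w[1] + (vapply(day_list, function(d) d[length(d)], 1L) - 1L)
  tv <- sum(nv)
  vis_dates <- w[1] + (unlist(day_list) - 1L)
  vis_pid <- rep(pts$patient_id, nv)
  visits <- data.frame(patient_id = vis_pid,
                       clinic_id = rep(pts$clinic_id, nv),
                       visit_date = vis_dates,
                       visit_type = "family_doctor",
                       stringsAsFactors = FALSE)
  # nutrition-service visits for P5-adherent patients
  m5 <- which(fl$a_P5)
  if (length(m5)) {
    visits <- rbind(visits, data.frame(
      patient_id = pts$patient_id[m5], clinic_id = pts$clinic_id[m5],
      visit_date = rand_dates(length(m5)),
      visit_type = "nutrition_service", stringsAsFactors = FALSE))
  }

  # diagnoses: the qualifying T2DM code plus comorbidity history
  t2dm_pool <- c(paste0("E11", 1:9), "E14X")
  dxs <- list(data.frame(
    patient_id = pts$patient_id,
    icd10_code = sample(t2dm_pool, n, replace = TRUE),
    recorded_date = w[1] + sample(-1825:364, n, replace = TRUE),
    field_slot = sample(1:3, n, replace = TRUE), stringsAsFactors = FALSE))
  add_dx <- function(mask, code_pool, dates) {
    m <- which(mask)
    if (!length(m)) return()
    dxs[[length(dxs) + 1L]] <<- data.frame(
      patient_id = pts$patient_id[m],
      icd10_code = sample(code_pool, length(m), replace = TRUE),
      recorded_date = dates(length(m)),
      field_slot = sample(1:3, length(m), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  hist_dates <- function(k) w[1] + sample(-1825:364, k, replace = TRUE)
  pre_dates <- function(k) w[1] - sample(30:1825, k, replace = TRUE)
  add_dx(fl$htn, "I10", hist_dates)
  add_dx(fl$dyslip, "E780", pre_dates)  # pre-window: defines P4 denominator
  add_dx(fl$cvd, c("I251", "I219", "I500", "I639"), hist_dates)
  add_dx(fl$smoking, "Z720", hist_dates)
  compl_code <- c(peripheral_vascular = "I739", nephropathy = "E112",
                  retinopathy = "E113", neuropathy = "E114")
  m <- which(fl$compl)
  if (length(m)) {
    dxs[[length(dxs) + 1L]] <- data.frame(
      patient_id = pts$patient_id[m],
      icd10_code = unname(compl_code[fl$compl_type[m]]),
      recorded_date = hist_dates(length(m)),
      field_slot = sample(1:3, length(m), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  diagnoses <- .rbind_all(dxs)

  # vitals: BP at visits (always at first and last), weight/height at the
  # first and last visit
  idx_end <- cumsum(nv)
  idx_start <- idx_end - nv + 1L
  bp_rec <- stats::runif(tv) < config$bp_record_prob
  bp_rec[idx_start] <- TRUE
  bp_rec[idx_end] <- TRUE
  ctrl3 <- rep(fl$c_O3, nv)
  sys <- ifelse(ctrl3, sample(100:128, tv, replace = TRUE),
                sample(132:180, tv, replace = TRUE))
  dia <- ifelse(ctrl3, sample(60:78, tv, replace = TRUE),
                sample(60:105, tv, replace = TRUE))
  wt <- rep(NA_real_, tv); ht <- rep(NA_real_, tv)
  wt[idx_start] <- fl$w_first
  wt[idx_end] <- fl$w_last            # single-visit patients keep w_first
  wt[idx_end[nv == 1L]] <- fl$w_first[nv == 1L]
  ht[idx_start] <- fl$height
  ht[idx_end] <- fl$height
  keep <- bp_rec | !is.na(wt)
  vitals <- data.frame(patient_id = vis_pid[keep],
                       measure_date = vis_dates[keep],
                       weight_kg = wt[keep], height_cm = ht[keep],
                       systolic_mmhg = ifelse(bp_rec, sys, NA_real_)[keep],
                       diastolic_mmhg = ifelse(bp_rec, dia, NA_real_)[keep],
                       stringsAsFactors = FALSE)

  # labs
  labs <- list()
  add_lab <- function(mask, analyte, gen_val) {
    m <- which(mask)
    if (!length(m)) return()
    k <- sample(1:3, length(m), replace = TRUE)
    pid <- rep(pts$patient_id[m], k)
    dates <- w[1] +
      (unlist(lapply(k, function(ki) sample.int(ndays, ki))) - 1L)
    labs[[length(labs) + 1L]] <<- data.frame(
      patient_id = pid, event_date = dates, analyte = analyte,
      status = "resulted", value = gen_val(m, k), stringsAsFactors = FALSE)
  }
  add_lab(fl$hba1c_present, "hba1c_pct", function(m, k) {
    ctrl <- rep(fl$c_O1[m], k)
    round(ifelse(ctrl, stats::runif(sum(k), 5.3, 6.8),
                 stats::runif(sum(k), 7.3, 11.0)), 1)
  })
  add_lab(fl$glucose_present, "fasting_glucose_mg_dl", function(m, k) {
    ctrl <- rep(fl$c_O1[m], k)
    round(ifelse(ctrl, stats::runif(sum(k), 80, 129),
                 stats::runif(sum(k), 141, 320)))
  })
  add_lab(fl$chol_present, "total_cholesterol_mg_dl", function(m, k) {
    ctrl <- rep(fl$c_O2[m], k)
    round(ifelse(ctrl, stats::runif(sum(k), 120, 198),
                 stats::runif(sum(k), 203, 340)))
  })
  m <- which(fl$order_only)
  if (length(m)) {
    labs[[length(labs) + 1L]] <- data.frame(
      patient_id = pts$patient_id[m], event_date = rand_dates(length(m)),
      analyte = sample(ANALYTES, length(m), replace = TRUE),
      status = "ordered_only", value = NA_real_, stringsAsFactors = FALSE)
  }
  labs <- .rbind_all(labs)

  # care events
  ces <- list()
  add_ce <- function(mask, kind) {
    m <- which(mask)
    if (!length(m)) return()
    ces[[length(ces) + 1L]] <<- data.frame(
      patient_id = pts$patient_id[m], event_date = rand_dates(length(m)),
      kind = kind, stringsAsFactors = FALSE)
  }
  add_ce(fl$a_P2, "foot_exam")
  add_ce(fl$a_P3, "ophthalmology_referral")
  care_events <- .rbind_all(ces)

  # prescriptions: numerator drugs at the last visit for adherent eligible
  # patients; background prescribing elsewhere
  p6_elig <- fl$bmi_cat %in% c("overweight", "obese") & !fl$contra_metformin
  p7_elig <- fl$htn & !fl$contra_acei_arb
  age <- age_at(pts$birth_date, w[1])
  p8_elig <- age > 40 & (fl$smoking | fl$htn | fl$dyslip) & !fl$contra_asa
  p9_elig <- fl$chol_present & !fl$c_O2 & !fl$contra_statin
  rxs <- list()
  add_rx <- function(mask, drug, dates, dose) {
    m <- which(mask)
    if (!length(m)) return()
    rxs[[length(rxs) + 1L]] <<- data.frame(
      patient_id = pts$patient_id[m],
      visit_date = dates[m],
      drug = if (length(drug) == 1) drug else drug[m],
      daily_dose_mg = if (length(dose) <= 1) dose else dose[m],
      stringsAsFactors = FALSE)
  }
  add_rx(p6_elig & fl$a_P6, "metformin", last_date, 1700)
  # metformin early in the year only: outside the last-three-visits window
  # for patients with enough visits, exercising the temporal rule
  add_rx(p6_elig & !fl$a_P6 & nv >= 4 & stats::runif(n) < 0.3,
         "metformin", first_date, 1700)
  add_rx(!p6_elig & stats::runif(n) < 0.3, "metformin", first_date, 1700)
  add_rx(p7_elig & fl$a_P7, sample(c("acei", "arb"), n, replace = TRUE),
         last_date, 20)
  asa_dose <- sample(c(75, 100, 150), n, replace = TRUE)
  add_rx(p8_elig & fl$a_P8, "acetylsalicylic_acid", last_date, asa_dose)
  add_rx(p8_elig & !fl$a_P8 & stats::runif(n) < 0.3,
         "acetylsalicylic_acid", last_date, 300)  # wrong dose, not counted
  add_rx(p9_elig & fl$a_P9, "statin", last_date, 20)
  add_rx(stats::runif(n) < 0.46, "glibenclamide", first_date, 10)
  add_rx(stats::runif(n) < 0.14, "insulin", last_date, NA_real_)
  add_rx(stats::runif(n) < 0.07, "acarbose", first_date, 150)
  prescriptions <- .rbind_all(rxs)

  # ground truth: engine-level eligibility and numerator status
  o1_elig <- fl$hba1c_present | fl$glucose_present
  o2_elig <- fl$chol_present
  o4_elig <- p6_elig & fl$n_visits >= 2
  o5_elig <- o1_elig & o2_elig
  truth_cols <- list(
    P1 = list(e = rep(TRUE, n), s = fl$hba1c_present),
    P2 = list(e = rep(TRUE, n), s = fl$a_P2),
    P3 = list(e = rep(TRUE, n), s = fl$a_P3),
    P4 = list(e = !fl$dyslip, s = fl$chol_present),
    P5 = list(e = rep(TRUE, n), s = fl$a_P5),
    P6 = list(e = p6_elig, s = fl$a_P6),
    P7 = list(e = p7_elig, s = fl$a_P7),
    P8 = list(e = p8_elig, s = fl$a_P8),
    P9 = list(e = p9_elig, s = fl$a_P9),
    O1 = list(e = o1_elig, s = fl$c_O1),
    O2 = list(e = o2_elig, s = fl$c_O2),
    O3 = list(e = rep(TRUE, n), s = fl$c_O3),
    O4 = list(e = o4_elig, s = fl$a_O4),
    O5 = list(e = o5_elig, s = fl$c_O1 & fl$c_O2 & fl$c_O3))
  truth <- .rbind_all(lapply(names(truth_cols), function(id) {
    tc <- truth_cols[[id]]
    data.frame(patient_id = pts$patient_id, indicator = id,
               eligible = tc$e, numerator = tc$e & tc$s,
               stringsAsFactors = FALSE)
  }))

  list(visits = visits, diagnoses = diagnoses, vitals = vitals, labs = labs,
       care_events = care_events, prescriptions = prescriptions,
       truth = truth)
}

# demographics shared by all generated patients
.gen_patient_rows <- function(ids, clinic, config, kind) {
  n <- length(ids)
  if (n == 0) return(NULL)
  w0 <- .window(config)[1]
  age <- switch(kind,
    t2dm = .rtrunc_norm(n, config$age_mean_t2dm, config$age_sd_t2dm,
                        20.05, 99),
    other = .rtrunc_norm(n, config$age_mean_other, config$age_sd_other,
                         20.05, 99),
    youth = stats::runif(n, 12, 19.8))
  birth <- w0 - round(age * 365.25)
  onset_age_cat <- sample(names(config$duration_category_probabilities), n,
                          replace = TRUE,
                          prob = config$duration_category_probabilities)
  duration <- ifelse(onset_age_cat == "lt5", sample(1:4, n, TRUE),
              ifelse(onset_age_cat == "y5_10", sample(5:10, n, TRUE),
              ifelse(onset_age_cat == "y11_15", sample(11:15, n, TRUE),
                     sample(16:30, n, TRUE))))
  onset <- config$observation_year - duration
  onset <- pmax(onset, as.integer(format(birth, "%Y")) + 18L)
  contra <- vapply(seq_len(n), function(i) {
    f <- CONTRA_FLAGS[stats::runif(length(CONTRA_FLAGS)) <
                        config$contraindication_rate]
    paste(f, collapse = "|")
  }, "")
  data.frame(
    patient_id = ids, clinic_id = clinic,
    sex = ifelse(stats::runif(n) < config$female_fraction, "female",
                 "male"),
    birth_date = birth,
    schooling = sample(names(config$schooling_probabilities), n, TRUE,
                       prob = config$schooling_probabilities),
    marital_status = sample(names(config$marital_probabilities), n, TRUE,
                            prob = config$marital_probabilities),
    employment = sample(names(config$employment_probabilities), n, TRUE,
                        prob = config$employment_probabilities),
    insurance_role = ifelse(stats::runif(n) <
                              config$insurance_subscriber_fraction,
                            "subscriber", "dependent"),
    diabetes_onset_year = if (kind == "t2dm") onset else
      rep(NA_integer_, n),
    contraindications = contra,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-clinic EHR bundle
#'
#' Draws clinic attendees, assigns T2DM status at the configured prevalence,
#' and generates full visit / diagnosis / vitals / prescription / laboratory
#' / care-event histories for T2DM patients (minimal histories for other
#' attendees). The returned bundle passes the read/write round trip, carries
#' a `clinic_registry` (member counts, attendee counts, HbA1c availability)
#' and a ground-truth sidecar in attribute `"truth"`. An identical seed
#' yields an identical bundle. No data defects are present; apply
#' [inject_data_defects()] for study-like missingness and implausible
#' values.
#'
#' @param config a [sim_config()].
#' @return an `ehr_bundle`.
#' @export
generate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    clinics <- sprintf("FMC%02d", seq_len(config$n_clinics))
    lab_avail <- config$lab_availability_by_clinic
    if (is.null(lab_avail)) lab_avail <- TRUE
    lab_avail <- setNames(rep_len(as.logical(lab_avail),
                                  config$n_clinics), clinics)
    n_att <- stats::rbinom(config$n_clinics, config$members_per_clinic,
                           config$attendance_probability)
    registry <- data.frame(clinic_id = clinics,
                           n_members = config$members_per_clinic,
                           n_attendees = n_att,
                           hba1c_available = unname(lab_avail),
                           stringsAsFactors = FALSE)
    N <- sum(n_att)
    if (N == 0) {
      ehr_bundle(clinic_registry = registry)
    } else {
    clinic <- rep(clinics, n_att)
    n_youth <- round(config$youth_fraction * N)
    n_nonatt <- round(config$nonattendee_fraction * N)
    kind <- rep("adult", N)
    if (n_youth > 0) kind[sample.int(N, n_youth)] <- "youth"
    # extra patients whose visits fall outside the window
    kind <- c(kind, rep("nonatt", n_nonatt))
    clinic <- c(clinic, rep_len(clinics, n_nonatt))
    ids <- sprintf("P%06d", seq_along(kind))

    t2dm <- stats::runif(length(ids)) < config$t2dm_prevalence
    t2dm[kind == "youth"] <-
      stats::runif(sum(kind == "youth")) < config$t2dm_prevalence * 0.2

    full <- t2dm & kind == "adult"
    pts_list <- list(
      .gen_patient_rows(ids[full], clinic[full], config, "t2dm"),
      .gen_patient_rows(ids[!full & kind != "youth"],
                        clinic[!full & kind != "youth"], config, "other"),
      .gen_patient_rows(ids[!full & kind == "youth"],
                        clinic[!full & kind == "youth"], config, "youth"))
    patients <- .rbind_all(pts_list)
    patients <- patients[match(ids, patients$patient_id), , drop = FALSE]
    rownames(patients) <- NULL
    patients$diabetes_onset_year[!t2dm] <- NA_integer_

    w <- .window(config)
    ndays <- as.integer(w[2] - w[1]) + 1L

    # full histories for adult T2DM attendees
    pts_full <- patients[full, , drop = FALSE]
    if (nrow(pts_full) > 0) {
      fl <- .draw_flags(pts_full, config, lab_avail)
      hist <- .gen_histories(pts_full, fl, config)
    } else {
      hist <- list(truth = NULL)
    }

    # minimal histories for everyone else: 1-3 visits (shifted a year back
    # for non-attendees), one diagnosis, blood pressure at the first visit
    rest <- which(!full)
    if (length(rest)) {
      nvr <- sample(1:3, length(rest), replace = TRUE)
      off <- ifelse(kind[rest] == "nonatt", -365L, 0L)
      day1 <- sample.int(ndays, length(rest), replace = TRUE)
      vis_r <- data.frame(
        patient_id = rep(ids[rest], nvr),
        clinic_id = rep(clinic[rest], nvr),
        visit_date = w[1] +
          (unlist(lapply(seq_along(rest), function(i) {
            sort(sample.int(ndays, nvr[i]))
          })) - 1L) + rep(off, nvr),
        visit_type = "family_doctor", stringsAsFactors = FALSE)
      other_pool <- c("J069", "M545", "K297", "E669", "Z000", "I10")
      dx_code <- ifelse(t2dm[rest],
                        sample(c(paste0("E11", 1:9), "E14X"), length(rest),
                               replace = TRUE),
                        sample(other_pool, length(rest), replace = TRUE))
      dx_r <- data.frame(patient_id = ids[rest], icd10_code = dx_code,
                         recorded_date = w[1] + day1 - 1L + off,
                         field_slot = sample(1:3, length(rest),
                                             replace = TRUE),
                         stringsAsFactors = FALSE)
      vit_r <- data.frame(patient_id = ids[rest],
                          measure_date = w[1] + day1 - 1L + off,
                          weight_kg = NA_real_, height_cm = NA_real_,
                          systolic_mmhg = sample(100:150, length(rest),
                                                 replace = TRUE),
                          diastolic_mmhg = sample(60:95, length(rest),
                                                  replace = TRUE),
                          stringsAsFactors = FALSE)
    } else {
      vis_r <- NULL; dx_r <- NULL; vit_r <- NULL
    }

    b <- ehr_bundle(
      patients = patients,
      diagnoses = .rbind_all(list(hist$diagnoses, dx_r)),
      visits = .rbind_all(list(hist$visits, vis_r)),
      vitals = .rbind_all(list(hist$vitals, vit_r)),
      prescriptions = hist$prescriptions,
      labs = hist$labs,
      care_events = hist$care_events,
      clinic_registry = registry)
    attr(b, "truth") <- hist$truth
    b
    }
  })
}

#' Generate one patient's synthetic history
#'
#' Runs the per-patient generative model (visit counts, comorbidity
#' diagnoses, vitals, laboratory results, prescriptions, care events) for a
#' single existing patient record, treated as an adult T2DM attendee. Uses
#' the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param patient one-row patients data frame (see `EHR_SCHEMAS$patients`).
#' @param config a [sim_config()].
#' @return named list of record tables (`visits`, `diagnoses`, `vitals`,
#'   `labs`, `care_events`, `prescriptions`) plus the `truth` sidecar.
#' @export
generate_patient_history <- function(patient, config = sim_config()) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1)
  clinics <- sprintf("FMC%02d", seq_len(config$n_clinics))
  lab_avail <- config$lab_availability_by_clinic
  if (is.null(lab_avail)) lab_avail <- TRUE
  lab_avail <- setNames(rep_len(as.logical(lab_avail), config$n_clinics),
                        clinics)
  if (!patient$clinic_id %in% names(lab_avail)) {
    lab_avail <- c(lab_avail, setNames(TRUE, patient$clinic_id))
  }
  fl <- .draw_flags(patient, config, lab_avail)
  .gen_histories(patient, fl, config)
}

#' Inject study-like data defects into a bundle
#'
#' Sets targeted patient fields to missing independently at their
#' configured missingness rates (BMI missingness blanks weight and height
#' across a patient's vitals), and replaces recorded vitals by values drawn
#' strictly outside the plausibility bounds at the configured implausible
#' rates. Record counts are never altered, only field values. Every defect
#' is logged in attribute `"defect_log"` (`patient_id`, `date`, `measure`,
#' `value`), so cleaning can be checked to remove exactly the injected set.
#'
#' @param bundle an `ehr_bundle` from [generate_population()].
#' @param config the [sim_config()] holding `missingness_rates` and
#'   `implausible_rates`.
#' @param seed seed for the defect draws (default derived from the config
#'   seed).
#' @return the defected bundle, with attributes `"truth"` (carried over)
#'   and `"defect_log"`.
#' @export
inject_data_defects <- function(bundle, config = sim_config(),
                                seed = config$seed + 1L) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  .with_seed(seed, {
    mr <- config$missingness_rates
    ir <- config$implausible_rates
    pts <- bundle$patients
    for (field in intersect(names(mr), c("schooling", "marital_status",
                                         "employment",
                                         "diabetes_onset_year"))) {
      hit <- stats::runif(nrow(pts)) < mr[[field]]
      pts[[field]][hit] <- NA
    }
    vit <- bundle$vitals
    log <- list()
    if (!is.na(mr["bmi"]) && nrow(pts) > 0) {
      hit_pid <- pts$patient_id[stats::runif(nrow(pts)) < mr[["bmi"]]]
      z <- vit$patient_id %in% hit_pid
      vit$weight_kg[z] <- NA_real_
      vit$height_cm[z] <- NA_real_
    }
    draw_outside <- function(k, lo_rng, hi_rng, digits) {
      low <- stats::runif(k) < 0.5
      round(ifelse(low, stats::runif(k, lo_rng[1], lo_rng[2]),
                   stats::runif(k, hi_rng[1], hi_rng[2])), digits)
    }
    ranges <- list(
      weight = list(col = "weight_kg", lo = c(5, 28), hi = c(205, 390),
                    digits = 1),
      height = list(col = "height_cm", lo = c(60, 125), hi = c(255, 290),
                    digits = 1),
      systolic = list(col = "systolic_mmhg", lo = c(10, 45),
                      hi = c(255, 390), digits = 0),
      diastolic = list(col = "diastolic_mmhg", lo = c(5, 35),
                       hi = c(205, 290), digits = 0))
    for (measure in intersect(names(ir), names(ranges))) {
      s <- ranges[[measure]]
      cand <- which(!is.na(vit[[s$col]]))
      hit <- cand[stats::runif(length(cand)) < ir[[measure]]]
      if (length(hit)) {
        bad <- draw_outside(length(hit), s$lo, s$hi, s$digits)
        vit[[s$col]][hit] <- bad
        log[[length(log) + 1L]] <- data.frame(
          patient_id = vit$patient_id[hit], date = vit$measure_date[hit],
          measure = measure, value = bad, stringsAsFactors = FALSE)
      }
    }
    out <- bundle
    out$patients <- pts
    out$vitals <- vit
    dl <- .rbind_all(log)
    if (is.null(dl)) {
      dl <- data.frame(patient_id = character(0),
                       date = as.Date(character(0)),
                       measure = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
    }
    attr(out, "truth") <- attr(bundle, "truth")
    attr(out, "defect_log") <- dl
    out
  })
}
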