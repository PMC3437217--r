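# Small constructors for hand-built EHR bundles used across tests.

mk_patient <- function(id, clinic = "FMC01", sex = "female",
                       birth = "1960-05-10", schooling = "primary",
                       marital = "married_partner", employment = "housewife",
                       insurance = "dependent", onset = NA,
                       contra = "") {
  data.frame(patient_id = id, clinic_id = clinic, sex = sex,
             birth_date = as.Date(birth), schooling = schooling,
             marital_status = marital, employment = employment,
             insurance_role = insurance,
             diabetes_onset_year = as.integer(onset),
             contraindications = contra, stringsAsFactors = FALSE)
}

mk_dx <- function(id, code, date, slot = 1L) {
  data.frame(patient_id = id, icd10_code = code,
             recorded_date = as.Date(date), field_slot = as.integer(slot),
             stringsAsFactors = FALSE)
}

mk_vis <- function(id, date, type = "family_doctor", clinic = "FMC01") {
  data.frame(patient_id = id, clinic_id = clinic,
             visit_date = as.Date(date), visit_type = type,
             stringsAsFactors = FALSE)
}

mk_vit <- function(id, date, w = NA, h = NA, s = NA, d = NA) {
  data.frame(patient_id = id, measure_date = as.Date(date),
             weight_kg = as.numeric(w), height_cm = as.numeric(h),
             systolic_mmhg = as.numeric(s), diastolic_mmhg = as.numeric(d),
             stringsAsFactors = FALSE)
}

mk_rx <- function(id, date, drug, dose = NA) {
  data.frame(patient_id = id, visit_date = as.Date(date), drug = drug,
             daily_dose_mg = as.numeric(dose), stringsAsFactors = FALSE)
}

mk_lab <- function(id, date, analyte, value, status = "resulted") {
  data.frame(patient_id = id, event_date = as.Date(date),
             analyte = analyte, status = status,
             value = as.numeric(value), stringsAsFactors = FALSE)
}

mk_ce <- function(id, date, kind) {
  data.frame(patient_id = id, event_date = as.Date(date), kind = kind,
             stringsAsFactors = FALSE)
}

rbindl <- function(...) do.call(rbind, Filter(Negate(is.null), list(...)))

mk_bundle <- function(patients, diagnoses = NULL, visits = NULL,
                      vitals = NULL, prescriptions = NULL, labs = NULL,
                      care_events = NULL, clinic_registry = NULL) {
  ehr_bundle(patients = patients, diagnoses = diagnoses, visits = visits,
             vitals = vitals, prescriptions = prescriptions, labs = labs,
             care_events = care_events, clinic_registry = clinic_registry)
}

# a cohort-eligible T2DM patient with configurable extras, returning the
# built timeline
mk_timeline <- function(id = "T1", visits = c("2009-02-01", "2009-06-15",
                                              "2009-09-10", "2009-11-20"),
                        dx = mk_dx(id, "E112", "2008-03-01"),
                        vitals = NULL, labs = NULL, rx = NULL, ce = NULL,
                        patient = mk_patient(id), ...) {
  b <- mk_bundle(patient,
                 diagnoses = dx,
                 visits = do.call(rbind, lapply(visits, function(d)
                   mk_vis(id, d))),
                 vitals = vitals, prescriptions = rx, labs = labs,
                 care_events = ce)
  build_timeline(id, b, ...)
}

# bare timeline stub for measurement-rule unit tests; only the fields the
# rule under test reads
fake_tl <- function(hba1c = NULL, glucose = NULL, weight = NULL,
                    bp = NULL) {
  series <- function(v, dates = NULL) {
    if (is.null(v)) return(data.frame(date = as.Date(character(0)),
                                      value = numeric(0)))
    if (is.null(dates)) dates <- as.Date("2009-01-01") + seq_along(v)
    data.frame(date = as.Date(dates), value = v)
  }
  bp_df <- if (is.null(bp)) {
    data.frame(date = as.Date(character(0)), systolic = numeric(0),
               diastolic = numeric(0))
  } else {
    data.frame(date = as.Date("2009-01-01") + seq_len(nrow(bp)),
               systolic = bp[, 1], diastolic = bp[, 2])
  }
  structure(list(hba1c = series(hba1c), glucose = series(glucose),
                 weight = series(weight), bp = bp_df),
            class = "patient_timeline")
}
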