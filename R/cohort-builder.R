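# Cohort selection, plausibility cleaning, BMI, per-patient timelines.

#' Cohort selection criteria
#'
#' Default criteria select adults (completed age >= 20 at the start of the
#' observation window) carrying a type 2 diabetes ICD-10 code
#' (E111-E119, E140-E149, E14X) in any of the three diagnosis fields, with
#' at least one family-doctor visit inside the window (calendar year 2009
#' by default).
#'
#' @param icd10_codes character set of qualifying codes (uppercase,
#'   dot-free). `E14X` and the bare stem `E14` are both accepted spellings
#'   of unspecified diabetes.
#' @param min_age_years minimum completed age at the window start.
#' @param window length-2 `Date` vector, inclusive.
#' @param required_visit_type visit type establishing cohort membership.
#' @return list of class `cohort_criteria`.
#' @export
cohort_criteria <- function(icd10_codes = c(paste0("E11", 1:9),
                                            paste0("E14", 1:9),
                                            "E14X", "E14"),
                            min_age_years = 20L,
                            window = as.Date(c("2009-01-01", "2009-12-31")),
                            required_visit_type = "family_doctor") {
  window <- as.Date(window)
  stopifnot(length(icd10_codes) > 0, length(window) == 2,
            window[1] <= window[2])
  structure(list(icd10_codes = toupper(icd10_codes),
                 min_age_years = as.integer(min_age_years),
                 window = window,
                 required_visit_type = required_visit_type),
            class = "cohort_criteria")
}

#' Predefined biological-plausibility bounds
#'
#' Closed retained intervals per measure; a value is excluded only when it
#' is strictly below the lower or strictly above the upper bound (so a
#' systolic pressure of exactly 50 mmHg is retained). HbA1c, fasting glucose
#' and total cholesterol have only a lower bound by default.
#'
#' @param ... named length-2 numeric overrides, e.g. `weight = c(30, 200)`.
#' @return named list of class `plausibility_bounds`.
#' @export
plausibility_bounds <- function(...) {
  b <- list(systolic = c(50, 250), diastolic = c(40, 200),
            height = c(130, 250), weight = c(30, 200),
            hba1c = c(3.0, Inf), fasting_glucose = c(37, Inf),
            total_cholesterol = c(100, Inf))
  over <- list(...)
  for (nm in names(over)) {
    v <- as.numeric(over[[nm]])
    stopifnot(length(v) == 2, v[1] < v[2])
    b[[nm]] <- v
  }
  structure(b, class = "plausibility_bounds")
}

#' Is an ICD-10 code a qualifying T2DM code?
#'
#' Codes are uppercased and dots removed before exact matching against the
#' criteria set (`"e14.x"` matches `E14X`). Unknown codes return `FALSE`.
#'
#' @param code character vector of ICD-10 codes.
#' @param criteria a [cohort_criteria()].
#' @return logical vector.
#' @export
is_t2dm_code <- function(code, criteria = cohort_criteria()) {
  norm <- toupper(gsub(".", "", code, fixed = TRUE))
  norm %in% criteria$icd10_codes
}

#' Is a measured value biologically plausible?
#'
#' @param measure one of `names(plausibility_bounds())`.
#' @param value numeric vector.
#' @param bounds a [plausibility_bounds()].
#' @return logical vector (`NA` values yield `NA`).
#' @export
plausible <- function(measure, value, bounds = plausibility_bounds()) {
  if (!measure %in% names(bounds)) {
    stop("configuration error: unknown measure '", measure, "'",
         call. = FALSE)
  }
  b <- bounds[[measure]]
  value >= b[1] & value <= b[2]
}

#' Drop implausible values from a dated measurement series
#'
#' Returns the plausible values date-sorted (stable for ties) together with
#' an exclusion log naming each removed value. `NA` values are treated as
#' missing, not implausible: they are dropped silently because a missing
#' measurement was never recorded. Idempotent on cleaned input.
#'
#' @param series data frame with columns `date` and `value` (extra columns
#'   are carried through).
#' @param measure measure name, see [plausible()].
#' @param bounds a [plausibility_bounds()].
#' @return list with `series` (cleaned) and `exclusions` (data frame
#'   `date`, `measure`, `value`).
#' @export
clean_measurements <- function(series, measure,
                               bounds = plausibility_bounds()) {
  if (is.null(series) || nrow(series) == 0) {
    return(list(series = series,
                exclusions = data.frame(date = as.Date(character(0)),
                                        measure = character(0),
                                        value = numeric(0))))
  }
  series <- series[order(series$date), , drop = FALSE]
  present <- !is.na(series$value)
  ok <- present & plausible(measure, series$value, bounds)
  excl <- series[present & !ok, , drop = FALSE]
  list(series = {
         s <- series[ok, , drop = FALSE]; rownames(s) <- NULL; s
       },
       exclusions = data.frame(date = excl$date,
                               measure = rep(measure, nrow(excl)),
                               value = excl$value,
                               stringsAsFactors = FALSE))
}

#' Body mass index from weight and height
#'
#' `weight / height_m^2`, reported to two decimals; `NA` when either input
#' is missing or implausible.
#'
#' @param weight_kg,height_cm numeric vectors.
#' @param bounds a [plausibility_bounds()].
#' @return numeric vector of BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_cm,
                        bounds = plausibility_bounds()) {
  ok <- !is.na(weight_kg) & !is.na(height_cm) &
    plausible("weight", weight_kg, bounds) &
    plausible("height", height_cm, bounds)
  out <- rep(NA_real_, length(ok))
  out[ok] <- round(weight_kg[ok] / (height_cm[ok] / 100)^2, 2)
  out
}

#' Nutritional-status category from BMI
#'
#' Standard WHO cutoffs as half-open bins: underweight < 18.5, normal
#' \[18.5, 25), overweight \[25, 30), obese >= 30 kg/m^2.
#'
#' @param bmi numeric vector.
#' @return character vector in
#'   `c("underweight", "normal", "overweight", "obese")`; `NA` for `NA` BMI.
#' @export
classify_bmi <- function(bmi) {
  out <- rep(NA_character_, length(bmi))
  ok <- !is.na(bmi)
  out[ok] <- as.character(cut(bmi[ok],
                              breaks = c(-Inf, 18.5, 25, 30, Inf),
                              labels = c("underweight", "normal",
                                         "overweight", "obese"),
                              right = FALSE))
  out
}

#' Diagnosis-code families for comorbidity and complication flags
#'
#' Prefix sets matched (after uppercasing and dot removal) against a
#' patient's diagnosis history: I10-I15 hypertension; E78 dyslipidemia;
#' selected I2x/I5x/I6x other cardiovascular disease; Z72.0/F17 tobacco
#' use; the T2DM fourth-character codes (and common alternatives) for the
#' chronic complications (e.g. E11.2 nephropathy, E11.3 retinopathy,
#' E11.4 neuropathy, E11.5/I73 peripheral circulatory disease).
#'
#' @return named list of code-prefix character vectors.
#' @export
comorbidity_code_map <- function() {
  list(hypertension = c("I10", "I11", "I12", "I13", "I14", "I15"),
       dyslipidemia = "E78",
       other_cvd = c("I20", "I21", "I24", "I25", "I50", "I63", "I64"),
       smoking = c("Z720", "F17"),
       nephropathy = c("E112", "E142", "N083"),
       retinopathy = c("E113", "E143", "H360"),
       neuropathy = c("E114", "E144", "G632"),
       peripheral_vascular = c("E115", "E145", "I73"))
}

.matches_prefix <- function(codes, prefixes) {
  if (length(codes) == 0) return(FALSE)
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1)))
}

#' Assemble one patient's cleaned, windowed timeline
#'
#' Collects and cleans all of a patient's records: date-sorted per-measure
#' series restricted to the observation window and passing plausibility;
#' comorbidity flags from any diagnosis on or before the window end
#' (medical history has unlimited lookback); first/last in-window BMI from
#' records carrying both a plausible weight and height. Same-day duplicate
#' measurements keep the last by file order and log the drop.
#'
#' @param patient a `patient_id` or one-row patients data frame.
#' @param bundle an `ehr_bundle`.
#' @param criteria a [cohort_criteria()].
#' @param bounds a [plausibility_bounds()].
#' @return list of class `patient_timeline`.
#' @export
build_timeline <- function(patient, bundle, criteria = cohort_criteria(),
                           bounds = plausibility_bounds()) {
  if (is.character(patient)) {
    patient <- bundle$patients[bundle$patients$patient_id == patient, ,
                               drop = FALSE]
  }
  stopifnot(nrow(patient) == 1)
  pid <- patient$patient_id
  grab <- function(tab, cols) {
    i <- tab$patient_id == pid
    lapply(setNames(cols, cols), function(cl) tab[[cl]][i])
  }
  rec <- c(
    setNames(grab(bundle$diagnoses, c("icd10_code", "recorded_date")),
             c("dx_code", "dx_date")),
    setNames(grab(bundle$visits, c("visit_date", "visit_type")),
             c("vis_date", "vis_type")),
    setNames(grab(bundle$vitals, c("measure_date", "weight_kg", "height_cm",
                                   "systolic_mmhg", "diastolic_mmhg")),
             c("vit_date", "vit_w", "vit_h", "vit_s", "vit_d")),
    setNames(grab(bundle$prescriptions, c("visit_date", "drug",
                                          "daily_dose_mg")),
             c("rx_date", "rx_drug", "rx_dose")),
    setNames(grab(bundle$labs, c("event_date", "analyte", "status",
                                 "value")),
             c("lab_date", "lab_analyte", "lab_status", "lab_value")),
    setNames(grab(bundle$care_events, c("event_date", "kind")),
             c("ce_date", "ce_kind")))
  .assemble_timeline(patient, rec, criteria, bounds)
}

# core worker; `rec` holds one patient's record columns as plain vectors
# (see build_timeline); pure vector operations, since this runs once per
# cohort patient
.assemble_timeline <- function(prow, rec, criteria, bounds) {
  w0 <- criteria$window[1]; w1 <- criteria$window[2]
  pid <- prow$patient_id

  keep_dx <- !is.na(rec$dx_date) & rec$dx_date <= w1
  codes <- toupper(gsub(".", "", rec$dx_code[keep_dx], fixed = TRUE))
  codes_pre <- codes[rec$dx_date[keep_dx] < w0]
  cmap <- comorbidity_code_map()
  comorb <- list(
    hypertension = .matches_prefix(codes, cmap$hypertension),
    dyslipidemia = .matches_prefix(codes, cmap$dyslipidemia),
    other_cvd = .matches_prefix(codes, cmap$other_cvd),
    smoking = .matches_prefix(codes, cmap$smoking))
  compl <- list(
    nephropathy = .matches_prefix(codes, cmap$nephropathy),
    retinopathy = .matches_prefix(codes, cmap$retinopathy),
    neuropathy = .matches_prefix(codes, cmap$neuropathy),
    peripheral_vascular = .matches_prefix(codes, cmap$peripheral_vascular))

  in_window <- function(d) !is.na(d) & d >= w0 & d <= w1
  vin <- in_window(rec$vis_date)
  fd_dates <- sort(rec$vis_date[vin & rec$vis_type ==
                                  criteria$required_visit_type])
  nutrition_dates <- sort(rec$vis_date[vin & rec$vis_type ==
                                         "nutrition_service"])
  last3 <- utils::tail(fd_dates, 3L)

  cleaning_log <- list()
  dup_log <- list()
  log_dups <- function(dates) {
    dup_log[[length(dup_log) + 1L]] <<- .qdf(
      patient_id = rep(pid, length(dates)), date = dates,
      issue = rep("same-day duplicate: kept last by file order",
                  length(dates)))
  }
  log_excl <- function(dates, measure, values) {
    cleaning_log[[length(cleaning_log) + 1L]] <<- .qdf(
      date = dates, measure = rep(measure, length(dates)), value = values,
      patient_id = rep(pid, length(dates)))
  }
  # stable date sort, same-day dedupe keeping last by file order, then
  # plausibility cleaning; input values non-missing
  clean_series <- function(dates, values, measure) {
    o <- order(dates)
    dates <- dates[o]; values <- values[o]
    d2 <- duplicated(dates, fromLast = TRUE)
    if (any(d2)) {
      log_dups(dates[d2])
      dates <- dates[!d2]; values <- values[!d2]
    }
    b <- bounds[[measure]]
    ok <- values >= b[1] & values <= b[2]
    if (!all(ok)) log_excl(dates[!ok], measure, values[!ok])
    .qdf(date = dates[ok], value = values[ok])
  }

  lab_series <- function(analyte, measure) {
    sel <- rec$lab_status == "resulted" & rec$lab_analyte == analyte &
      in_window(rec$lab_date) & !is.na(rec$lab_value)
    clean_series(rec$lab_date[sel], rec$lab_value[sel], measure)
  }
  hba1c <- lab_series("hba1c_pct", "hba1c")
  glucose <- lab_series("fasting_glucose_mg_dl", "fasting_glucose")
  cholesterol <- lab_series("total_cholesterol_mg_dl", "total_cholesterol")

  # vitals: record-level stable sort + same-day dedupe (keeping the whole
  # last record preserves BP/BMI pairing), then per-column cleaning
  vsel <- which(in_window(rec$vit_date))
  vsel <- vsel[order(rec$vit_date[vsel])]
  vdate <- rec$vit_date[vsel]
  d2 <- duplicated(vdate, fromLast = TRUE)
  if (any(d2)) {
    log_dups(vdate[d2])
    vsel <- vsel[!d2]; vdate <- vdate[!d2]
  }
  vw <- rec$vit_w[vsel]; vh <- rec$vit_h[vsel]
  vs <- rec$vit_s[vsel]; vd <- rec$vit_d[vsel]
  col_ok <- function(values, measure) {
    pres <- !is.na(values)
    b <- bounds[[measure]]
    ok <- pres & values >= b[1] & values <= b[2]
    bad <- pres & !ok
    if (any(bad)) log_excl(vdate[bad], measure, values[bad])
    ok
  }
  okw <- col_ok(vw, "weight"); okh <- col_ok(vh, "height")
  oks <- col_ok(vs, "systolic"); okd <- col_ok(vd, "diastolic")
  weight <- .qdf(date = vdate[okw], value = vw[okw])
  height <- .qdf(date = vdate[okh], value = vh[okh])
  sys_s <- .qdf(date = vdate[oks], value = vs[oks])
  dia_s <- .qdf(date = vdate[okd], value = vd[okd])
  bp_ok <- oks & okd
  bp <- .qdf(date = vdate[bp_ok], systolic = vs[bp_ok],
             diastolic = vd[bp_ok])

  # BMI at records with both plausible weight and height
  bmi_ok <- okw & okh
  bmi_dates <- vdate[bmi_ok]
  bmi_values <- round(vw[bmi_ok] / (vh[bmi_ok] / 100)^2, 2)
  bmi_point <- function(i) {
    if (length(bmi_values) == 0) return(list(value = NA_real_,
                                             category = NA_character_,
                                             date = as.Date(NA)))
    list(value = bmi_values[i], category = classify_bmi(bmi_values[i]),
         date = bmi_dates[i])
  }

  rx_in <- in_window(rec$rx_date)
  rx_w <- .qdf(patient_id = rep(pid, sum(rx_in)),
               visit_date = rec$rx_date[rx_in],
               drug = rec$rx_drug[rx_in],
               daily_dose_mg = rec$rx_dose[rx_in])
  ce_in <- in_window(rec$ce_date)
  ce_w <- .qdf(patient_id = rep(pid, sum(ce_in)),
               event_date = rec$ce_date[ce_in], kind = rec$ce_kind[ce_in])

  contra <- character(0)
  if (!is.na(prow$contraindications) && nzchar(prow$contraindications)) {
    contra <- strsplit(prow$contraindications, "|", fixed = TRUE)[[1]]
  }
  onset <- prow$diabetes_onset_year
  duration <- if (is.na(onset)) NA_integer_ else
    as.integer(format(w0, "%Y")) - as.integer(onset)

  structure(list(
    patient_id = pid,
    clinic_id = prow$clinic_id,
    sex = prow$sex, schooling = prow$schooling,
    marital_status = prow$marital_status, employment = prow$employment,
    insurance_role = prow$insurance_role,
    age_years = age_at(prow$birth_date, w0),
    diabetes_duration_years = duration,
    comorbidity = comorb,
    complications = compl,
    dyslipidemia_before_window = .matches_prefix(codes_pre,
                                                 cmap$dyslipidemia),
    visit_dates = fd_dates,
    last3_visit_dates = last3,
    nutrition_visit_dates = nutrition_dates,
    hba1c = hba1c, glucose = glucose, cholesterol = cholesterol,
    weight = weight, height = height, bp = bp,
    systolic = sys_s, diastolic = dia_s,
    bmi_first = bmi_point(1L), bmi_last = bmi_point(length(bmi_values)),
    prescriptions = rx_w,
    care_events = ce_w,
    contraindications = contra,
    cleaning_log = .rbind_all(cleaning_log),
    duplicate_log = .rbind_all(dup_log)
  ), class = "patient_timeline")
}

#' Select the T2DM study cohort from a bundle
#'
#' A patient enters the cohort iff (a) any diagnosis record in any of the
#' three fields carries a qualifying T2DM code dated on or before the window
#' end, (b) completed age at the window start is at least
#' `criteria$min_age_years`, and (c) at least one visit of the required type
#' falls inside the window. Every T2DM-coded patient that is excluded
#' appears in the exclusion log with a single reason (`"age"` takes
#' precedence over `"no visit in window"`).
#'
#' @param bundle an `ehr_bundle`.
#' @param criteria a [cohort_criteria()].
#' @param bounds a [plausibility_bounds()].
#' @return object of class `t2dm_cohort`: list with `timelines` (named list
#'   of `patient_timeline`), `clinic_counts`, `exclusions`, `criteria`,
#'   `bounds`, `clinic_registry`.
#' @export
select_cohort <- function(bundle, criteria = cohort_criteria(),
                          bounds = plausibility_bounds()) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  w0 <- criteria$window[1]; w1 <- criteria$window[2]
  pts <- bundle$patients

  dxx <- bundle$diagnoses
  dxx <- dxx[!is.na(dxx$recorded_date) & dxx$recorded_date <= w1 &
               dxx$field_slot %in% 1:3 &
               is_t2dm_code(dxx$icd10_code, criteria), , drop = FALSE]
  t2dm_ids <- unique(dxx$patient_id)

  vv <- bundle$visits
  vv <- vv[vv$visit_type == criteria$required_visit_type &
             !is.na(vv$visit_date) & vv$visit_date >= w0 &
             vv$visit_date <= w1, , drop = FALSE]
  visited_ids <- unique(vv$patient_id)

  cand <- pts[pts$patient_id %in% t2dm_ids, , drop = FALSE]
  age <- age_at(cand$birth_date, w0)
  old_enough <- !is.na(age) & age >= criteria$min_age_years
  has_visit <- cand$patient_id %in% visited_ids
  included <- old_enough & has_visit

  reason <- rep(NA_character_, nrow(cand))
  reason[!old_enough] <- "age"
  reason[old_enough & !has_visit] <- "no visit in window"
  exclusions <- data.frame(patient_id = cand$patient_id[!included],
                           reason = reason[!included],
                           stringsAsFactors = FALSE)

  inc <- cand[included, , drop = FALSE]
  # split each needed column once by patient; assembly then works on plain
  # vectors, which keeps the per-patient loop cheap
  split_cols <- function(tab, cols, out_names) {
    fa <- factor(tab$patient_id, levels = inc$patient_id)
    setNames(lapply(cols, function(cl) split(tab[[cl]], fa)), out_names)
  }
  S <- c(
    split_cols(bundle$diagnoses, c("icd10_code", "recorded_date"),
               c("dx_code", "dx_date")),
    split_cols(bundle$visits, c("visit_date", "visit_type"),
               c("vis_date", "vis_type")),
    split_cols(bundle$vitals, c("measure_date", "weight_kg", "height_cm",
                                "systolic_mmhg", "diastolic_mmhg"),
               c("vit_date", "vit_w", "vit_h", "vit_s", "vit_d")),
    split_cols(bundle$prescriptions, c("visit_date", "drug",
                                       "daily_dose_mg"),
               c("rx_date", "rx_drug", "rx_dose")),
    split_cols(bundle$labs, c("event_date", "analyte", "status", "value"),
               c("lab_date", "lab_analyte", "lab_status", "lab_value")),
    split_cols(bundle$care_events, c("event_date", "kind"),
               c("ce_date", "ce_kind")))
  fields <- names(S)
  prows <- lapply(seq_len(nrow(inc)), function(i) as.list(inc[i, ]))

  timelines <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    pid <- inc$patient_id[i]
    rec <- lapply(setNames(fields, fields), function(f) S[[f]][[pid]])
    timelines[[i]] <- .assemble_timeline(prows[[i]], rec, criteria, bounds)
  }
  names(timelines) <- inc$patient_id

  clinic_counts <- if (nrow(inc) == 0) {
    data.frame(clinic_id = character(0), n_patients = integer(0),
               stringsAsFactors = FALSE)
  } else {
    tab <- table(inc$clinic_id)
    data.frame(clinic_id = names(tab), n_patients = as.integer(tab),
               stringsAsFactors = FALSE)
  }

  structure(list(criteria = criteria, bounds = bounds,
                 timelines = timelines, clinic_counts = clinic_counts,
                 exclusions = exclusions,
                 clinic_registry = bundle$clinic_registry),
            class = "t2dm_cohort")
}

#' @export
print.t2dm_cohort <- function(x, ...) {
  cat("<t2dm_cohort>", length(x$timelines), "patients in",
      nrow(x$clinic_counts), "clinic(s);",
      nrow(x$exclusions), "excluded\n")
  cat("  window:", format(x$criteria$window[1]), "to",
      format(x$criteria$window[2]), "\n")
  invisible(x)
}

#' Pooled cleaning log of a cohort
#'
#' One row per measurement excluded as biologically implausible across all
#' cohort timelines.
#'
#' @param cohort a `t2dm_cohort`.
#' @return data frame with `patient_id`, `date`, `measure`, `value`.
#' @export
cohort_cleaning_log <- function(cohort) {
  logs <- lapply(cohort$timelines, `[[`, "cleaning_log")
  out <- .rbind_all(logs)
  if (is.null(out)) {
    out <- data.frame(date = as.Date(character(0)), measure = character(0),
                      value = numeric(0), patient_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out[, c("patient_id", "date", "measure", "value")]
}
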