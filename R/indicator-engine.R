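# Declarative evaluation of the 14 active quality-of-care indicators over a
# cohort of cleaned patient timelines.
#
# Each indicator is a denominator predicate (eligibility) and a numerator
# predicate (care criterion met), both over a `patient_timeline`. Drug
# indicators read prescriptions at the patient's last three family-doctor
# visits; outcome indicators read the last (up to) three cleaned
# measurements. "Unless contraindicated" clauses exclude from the
# denominator, which is standard quality-measure practice.

#' Last k elements of a date-sorted series
#'
#' With fewer than `k` available, all available elements are returned (the
#' weakest consistent reading of "in the last k measurements"; eligibility
#' then requires only a non-empty series).
#'
#' @param series data frame (date-sorted) or vector.
#' @param k positive integer.
#' @return the final `min(k, length)` rows/elements.
#' @export
last_k <- function(series, k = 3L) {
  stopifnot(k >= 1)
  if (is.data.frame(series)) {
    if (nrow(series) == 0) return(series)
    utils::tail(series, k)
  } else {
    utils::tail(series, k)
  }
}

#' Glycemic control from the last three measurements
#'
#' Met iff every HbA1c value among the last three is < 7\%, or every
#' fasting-glucose value among the last three is <= 130 mg/dl (either
#' criterion suffices; this is the modified target used where HbA1c testing
#' is not uniformly available). Undetermined when neither series has any
#' in-window resulted value.
#'
#' @param timeline a `patient_timeline`.
#' @return one of `"met"`, `"not_met"`, `"undetermined"`.
#' @export
glycemic_control <- function(timeline) {
  h <- timeline$hba1c; g <- timeline$glucose
  if ((is.null(h) || nrow(h) == 0) && (is.null(g) || nrow(g) == 0)) {
    return("undetermined")
  }
  h_ok <- !is.null(h) && nrow(h) > 0 && all(last_k(h, 3L)$value < 7.0)
  g_ok <- !is.null(g) && nrow(g) > 0 && all(last_k(g, 3L)$value <= 130)
  if (h_ok || g_ok) "met" else "not_met"
}

#' Blood-pressure control from the last three measurement pairs
#'
#' Met iff every pair among the last three has systolic < 130 and
#' diastolic < 80 mmHg (strict). Undetermined when no cleaned pair exists.
#'
#' @param timeline a `patient_timeline`.
#' @return one of `"met"`, `"not_met"`, `"undetermined"`.
#' @export
bp_control <- function(timeline) {
  bp <- timeline$bp
  if (is.null(bp) || nrow(bp) == 0) return("undetermined")
  b3 <- last_k(bp, 3L)
  if (all(b3$systolic < 130 & b3$diastolic < 80)) "met" else "not_met"
}

#' Relative weight change over the observation window
#'
#' `100 * (last - first) / first` over the in-window cleaned weights; a
#' value of -6 means a 6\% loss. `NA` with fewer than two dated weights.
#'
#' @param timeline a `patient_timeline`.
#' @return numeric percentage or `NA`.
#' @export
weight_change_pct <- function(timeline) {
  w <- timeline$weight
  if (is.null(w) || nrow(w) < 2) return(NA_real_)
  100 * (w$value[nrow(w)] - w$value[1]) / w$value[1]
}

# -- per-indicator denominator/numerator predicates ------------------------

.has_rows <- function(df) !is.null(df) && nrow(df) > 0

.drug_at_last3 <- function(tl, drugs, dose_range = NULL) {
  rx <- tl$prescriptions
  if (!.has_rows(rx) || length(tl$last3_visit_dates) == 0) return(FALSE)
  sel <- rx$drug %in% drugs & rx$visit_date %in% tl$last3_visit_dates
  if (!is.null(dose_range)) {
    sel <- sel & !is.na(rx$daily_dose_mg) &
      rx$daily_dose_mg >= dose_range[1] & rx$daily_dose_mg <= dose_range[2]
  }
  any(sel)
}

.last_chol <- function(tl) {
  ch <- tl$cholesterol
  if (!.has_rows(ch)) NA_real_ else ch$value[nrow(ch)]
}

.bmi_eligible <- function(tl) {
  cat <- tl$bmi_first$category
  !is.na(cat) && cat %in% c("overweight", "obese") &&
    !("metformin" %in% tl$contraindications)
}

# registry of rules keyed by catalog id; each entry: denominator and
# numerator functions over a timeline (numerator assumed inside denominator)
.indicator_rules <- function() {
  list(
    P1 = list(den = function(tl) TRUE,
              num = function(tl) .has_rows(tl$hba1c)),
    P2 = list(den = function(tl) TRUE,
              num = function(tl) .has_rows(tl$care_events) &&
                any(tl$care_events$kind == "foot_exam")),
    P3 = list(den = function(tl) TRUE,
              num = function(tl) .has_rows(tl$care_events) &&
                any(tl$care_events$kind == "ophthalmology_referral")),
    P4 = list(den = function(tl) !tl$dyslipidemia_before_window,
              num = function(tl) .has_rows(tl$cholesterol)),
    P5 = list(den = function(tl) TRUE,
              num = function(tl) length(tl$nutrition_visit_dates) > 0),
    P6 = list(den = .bmi_eligible,
              num = function(tl) .drug_at_last3(tl, "metformin")),
    P7 = list(den = function(tl) tl$comorbidity$hypertension &&
                !("acei_arb" %in% tl$contraindications),
              num = function(tl) .drug_at_last3(tl, c("acei", "arb"))),
    P8 = list(den = function(tl) tl$age_years > 40 &&
                (tl$comorbidity$smoking || tl$comorbidity$hypertension ||
                   tl$comorbidity$dyslipidemia) &&
                !("asa" %in% tl$contraindications),
              num = function(tl) .drug_at_last3(tl, "acetylsalicylic_acid",
                                                dose_range = c(75, 150))),
    P9 = list(den = function(tl) {
                ch <- .last_chol(tl)
                !is.na(ch) && ch > 200 &&
                  !("statin" %in% tl$contraindications)
              },
              num = function(tl) .drug_at_last3(tl, "statin")),
    O1 = list(den = function(tl) .has_rows(tl$hba1c) ||
                .has_rows(tl$glucose),
              num = function(tl) glycemic_control(tl) == "met"),
    O2 = list(den = function(tl) .has_rows(tl$cholesterol),
              num = function(tl) .last_chol(tl) < 200),
    O3 = list(den = function(tl) .has_rows(tl$bp),
              num = function(tl) bp_control(tl) == "met"),
    O4 = list(den = function(tl) .bmi_eligible(tl) &&
                .has_rows(tl$weight) && nrow(tl$weight) >= 2,
              num = function(tl) weight_change_pct(tl) <= -5),
    O5 = list(den = function(tl) (.has_rows(tl$hba1c) ||
                                    .has_rows(tl$glucose)) &&
                .has_rows(tl$cholesterol) && .has_rows(tl$bp),
              num = function(tl) glycemic_control(tl) == "met" &&
                bp_control(tl) == "met" && .last_chol(tl) < 200)
  )
}

#' Evaluate one indicator on one patient timeline
#'
#' Applies the denominator rule then, only when it holds, the numerator
#' rule. Undetermined measurement states (no usable measurements) map to
#' `not_in_denominator`.
#'
#' @param id indicator id (`"P1"`..`"P9"`, `"O1"`..`"O5"`), or a one-row
#'   slice of [indicator_catalog()].
#' @param timeline a `patient_timeline`.
#' @param catalog the indicator catalog (used to check the `active` flag).
#' @return one of `"not_in_denominator"`, `"denominator_only"`,
#'   `"numerator"`.
#' @export
evaluate_indicator <- function(id, timeline,
                               catalog = indicator_catalog()) {
  if (is.data.frame(id)) id <- id$id
  entry <- catalog[catalog$id == id, , drop = FALSE]
  if (nrow(entry) == 0) stop("unknown indicator id: ", id, call. = FALSE)
  if (!entry$active) {
    stop("indicator not programmable: ", id, call. = FALSE)
  }
  rule <- .indicator_rules()[[id]]
  if (!isTRUE(rule$den(timeline))) return("not_in_denominator")
  if (isTRUE(rule$num(timeline))) "numerator" else "denominator_only"
}

#' Per-patient tri-state outcomes for all active indicators
#'
#' @param cohort a `t2dm_cohort`.
#' @param catalog the indicator catalog.
#' @return data frame with `patient_id`, `clinic_id`, one column per active
#'   indicator id holding the tri-state outcome.
#' @export
patient_indicator_outcomes <- function(cohort,
                                       catalog = indicator_catalog()) {
  active <- catalog$id[catalog$active]
  rules <- .indicator_rules()[active]
  tls <- cohort$timelines
  out <- data.frame(
    patient_id = vapply(tls, `[[`, "", "patient_id"),
    clinic_id = vapply(tls, `[[`, "", "clinic_id"),
    stringsAsFactors = FALSE, row.names = NULL)
  for (id in active) {
    rule <- rules[[id]]
    out[[id]] <- vapply(tls, function(tl) {
      if (!isTRUE(rule$den(tl))) "not_in_denominator"
      else if (isTRUE(rule$num(tl))) "numerator" else "denominator_only"
    }, "", USE.NAMES = FALSE)
  }
  out
}

#' Evaluate all active indicators over a cohort
#'
#' Per-clinic and pooled numerator/denominator counts and percentages for
#' every active indicator. The pooled percentage is
#' `100 * sum(numerators) / sum(denominators)` (a patient-weighted rate,
#' not the mean of clinic rates). Percentages are carried unrounded;
#' rendering rounds half-up to one decimal. A clinic flagged in the
#' registry as lacking HbA1c testing keeps its full denominator for the
#' HbA1c-measurement indicator (P1) but its clinic-level percentage is
#' marked not-available (`NA`) for reporting, while its counts still enter
#' the pooled total.
#'
#' @param cohort a `t2dm_cohort`.
#' @param catalog the indicator catalog.
#' @return data frame of class `indicator_results`: `indicator`, `clinic_id`
#'   (`"Total"` for pooled rows), `numerator`, `denominator`, `percentage`.
#' @export
evaluate_all <- function(cohort, catalog = indicator_catalog()) {
  active <- catalog$id[catalog$active]
  po <- patient_indicator_outcomes(cohort, catalog)
  clinics <- sort(unique(po$clinic_id))
  res <- list()
  no_hba1c <- character(0)
  reg <- cohort$clinic_registry
  if (!is.null(reg) && "hba1c_available" %in% names(reg)) {
    no_hba1c <- reg$clinic_id[!is.na(reg$hba1c_available) &
                                !reg$hba1c_available]
  }
  for (id in active) {
    st <- po[[id]]
    in_den <- st != "not_in_denominator"
    num <- st == "numerator"
    for (cl in clinics) {
      i <- po$clinic_id == cl
      d <- sum(in_den & i); n <- sum(num & i)
      pct <- if (d > 0) 100 * n / d else NA_real_
      if (id == "P1" && cl %in% no_hba1c) pct <- NA_real_
      res[[length(res) + 1L]] <- data.frame(
        indicator = id, clinic_id = cl, numerator = n, denominator = d,
        percentage = pct, stringsAsFactors = FALSE)
    }
    d <- sum(in_den); n <- sum(num)
    res[[length(res) + 1L]] <- data.frame(
      indicator = id, clinic_id = "Total", numerator = n, denominator = d,
      percentage = if (d > 0) 100 * n / d else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- .rbind_all(res)
  if (is.null(out)) {
    out <- data.frame(indicator = character(0), clinic_id = character(0),
                      numerator = integer(0), denominator = integer(0),
                      percentage = numeric(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("indicator_results", "data.frame")
  out
}

#' @export
print.indicator_results <- function(x, ...) {
  y <- as.data.frame(x)
  y$percentage <- ifelse(is.na(y$percentage), "Not available",
                         sprintf("%.1f", round_half_up(y$percentage, 1)))
  print(y, row.names = FALSE)
  invisible(x)
}
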