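# Descriptive cohort tables, pooled-rate utilities, report rendering.

# percentage distribution of a categorical vector per clinic + pooled,
# with an explicit "Missing data" row when NA is present
.pct_table <- function(values, clinic, levels, labels = levels,
                       missing_row = TRUE) {
  clinics <- sort(unique(clinic))
  cols <- c(clinics, "Total")
  out <- data.frame(label = c(labels, if (missing_row) "Missing data"),
                    stringsAsFactors = FALSE)
  for (cl in cols) {
    v <- if (cl == "Total") values else values[clinic == cl]
    n <- length(v)
    counts <- vapply(levels, function(l) sum(v == l, na.rm = TRUE),
                     numeric(1))
    if (missing_row) counts <- c(counts, sum(is.na(v)))
    out[[cl]] <- if (n > 0) 100 * counts / n else rep(NA_real_,
                                                      length(counts))
  }
  out
}

.mean_sd_table <- function(values, clinic) {
  clinics <- sort(unique(clinic))
  cols <- c(clinics, "Total")
  out <- data.frame(label = c("mean", "sd"), stringsAsFactors = FALSE)
  for (cl in cols) {
    v <- if (cl == "Total") values else values[clinic == cl]
    v <- v[!is.na(v)]
    out[[cl]] <- if (length(v)) c(mean(v), stats::sd(v)) else
      c(NA_real_, NA_real_)
  }
  out
}

#' Descriptive characteristics of a cohort
#'
#' Per-clinic and pooled distributions of the cohort's demographic and
#' clinical characteristics: sex, age groups (<30, 30-39, ..., >= 70),
#' schooling, marital status, employment, insurance role, diabetes
#' duration, comorbidities, chronic-complication types, end-of-year
#' nutritional status (with explicit missing-data rows), mean (sd) age and
#' family-doctor visit counts, the distribution of the number of distinct
#' hypoglycemic drug classes prescribed (0, 1, 2, >= 3) and per-class
#' frequencies. Percentages are unrounded; the print method formats to one
#' decimal.
#'
#' @param cohort a `t2dm_cohort`.
#' @return named list of data frames, class `cohort_description`.
#' @export
describe_cohort <- function(cohort) {
  tls <- cohort$timelines
  g <- function(f) vapply(tls, f, numeric(1))
  gc_ <- function(f) vapply(tls, f, character(1))
  gl <- function(f) vapply(tls, f, logical(1))
  clinic <- gc_(function(t) t$clinic_id)
  n <- length(tls)

  sex <- gc_(function(t) t$sex)
  age <- g(function(t) as.numeric(t$age_years))
  age_group <- cut(age, c(-Inf, 30, 40, 50, 60, 70, Inf),
                   labels = c("<30", "30-39", "40-49", "50-59", "60-69",
                              ">=70"), right = FALSE)
  chr_or_na <- function(field) gc_(function(t) {
    v <- t[[field]]
    if (is.null(v) || is.na(v)) NA_character_ else v
  })
  dur <- g(function(t) {
    d <- t$diabetes_duration_years
    if (is.null(d) || is.na(d)) NA_real_ else as.numeric(d)
  })
  dur_cat <- cut(dur, c(-Inf, 5, 11, 16, Inf),
                 labels = c("<5 years", "5-10 years", "11-15 years",
                            ">15 years"), right = FALSE)
  hypo_classes <- c("metformin", "glibenclamide", "acarbose",
                    "rosiglitazone", "pioglitazone", "insulin")
  hypo_per_patient <- lapply(tls, function(t) {
    rx <- t$prescriptions
    if (is.null(rx) || nrow(rx) == 0) character(0)
    else intersect(unique(rx$drug), hypo_classes)
  })
  n_hypo <- pmin(lengths(hypo_per_patient), 3L)
  flag_table <- function(pairs) {
    clinics <- sort(unique(clinic))
    out <- data.frame(label = names(pairs), stringsAsFactors = FALSE)
    for (cl in c(clinics, "Total")) {
      i <- if (cl == "Total") rep(TRUE, n) else clinic == cl
      out[[cl]] <- vapply(pairs, function(v) {
        if (sum(i) > 0) 100 * sum(v[i]) / sum(i) else NA_real_
      }, numeric(1))
    }
    out
  }

  structure(list(
    sex = .pct_table(sex, clinic, c("female", "male"),
                     c("Female", "Male"), missing_row = FALSE),
    age_mean_sd = .mean_sd_table(age, clinic),
    age_groups = .pct_table(as.character(age_group), clinic,
                            levels(age_group), missing_row = FALSE),
    schooling = .pct_table(chr_or_na("schooling"), clinic,
                           setdiff(SCHOOLING_LEVELS, "missing")),
    marital_status = .pct_table(chr_or_na("marital_status"), clinic,
                                setdiff(MARITAL_LEVELS, "missing")),
    employment = .pct_table(chr_or_na("employment"), clinic,
                            setdiff(EMPLOYMENT_LEVELS, "missing")),
    insurance = .pct_table(chr_or_na("insurance_role"), clinic,
                           setdiff(INSURANCE_LEVELS, "missing"),
                           missing_row = FALSE),
    duration = .pct_table(as.character(dur_cat), clinic, levels(dur_cat)),
    comorbidity = flag_table(list(
      "Hypertensive disease" = gl(function(t) t$comorbidity$hypertension),
      "Other cardiovascular disease" = gl(function(t)
        t$comorbidity$other_cvd),
      "Hyperlipidemia" = gl(function(t) t$comorbidity$dyslipidemia),
      "Diabetic chronic complications" = gl(function(t)
        any(unlist(t$complications))))),
    complication_type = flag_table(list(
      "Peripheral vascular disease" = gl(function(t)
        t$complications$peripheral_vascular),
      "Diabetic nephropathy" = gl(function(t) t$complications$nephropathy),
      "Diabetic retinopathy" = gl(function(t) t$complications$retinopathy),
      "Peripheral neuropathy" = gl(function(t) t$complications$neuropathy))),
    nutritional_status = .pct_table(
      gc_(function(t) {
        if (is.na(t$bmi_last$value)) NA_character_
        else classify_bmi(t$bmi_last$value)
      }),
      clinic, c("underweight", "normal", "overweight", "obese")),
    visits_mean_sd = .mean_sd_table(
      g(function(t) length(t$visit_dates)), clinic),
    hypoglycemic_count = .pct_table(as.character(n_hypo), clinic,
                                    c("0", "1", "2", "3"),
                                    c("None", "1", "2", ">=3"),
                                    missing_row = FALSE),
    hypoglycemic_drugs = flag_table(setNames(
      lapply(c("metformin", "glibenclamide", "acarbose", "insulin"),
             function(d) vapply(hypo_per_patient, function(s) d %in% s,
                                logical(1))),
      c("Metformin", "Glibenclamide", "Acarbose", "Insulin")))
  ), class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    y <- x[[nm]]
    for (cl in setdiff(names(y), "label")) {
      y[[cl]] <- sprintf("%.1f", round_half_up(y[[cl]], 1))
    }
    print(y, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Pool per-clinic rates into a patient-weighted total
#'
#' `100 * sum(rate_i/100 * denom_i) / sum(denom_i)`, rounded half-up to one
#' decimal: the pooled percentage implied by printed per-clinic percentages
#' and their denominators. Algebraically the weighted mean of the rates
#' with denominator weights, so it equally pools mean-valued rows (e.g.
#' mean ages) when `rates` are means.
#'
#' @param clinic_rates numeric vector of per-clinic percentages (or means).
#' @param clinic_denominators positive counts, same length.
#' @return pooled value, one decimal.
#' @export
pooled_from_rates <- function(clinic_rates, clinic_denominators) {
  if (length(clinic_rates) != length(clinic_denominators)) {
    stop("length mismatch between rates and denominators", call. = FALSE)
  }
  stopifnot(all(clinic_denominators > 0))
  round_half_up(sum(clinic_rates * clinic_denominators) /
                  sum(clinic_denominators), 1)
}

#' Render indicator results to CSV or JSON
#'
#' Deterministic renderings of an [evaluate_all()] result table.
#' Percentages are rounded half-up to one decimal; a missing percentage
#' (empty denominator, or a clinic whose measurement source is absent) is
#' rendered as `"Not available"` while its counts remain numeric. The CSV
#' and JSON renderings agree field for field.
#'
#' @param results an `indicator_results` data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  y <- as.data.frame(results)
  y$percentage <- ifelse(is.na(y$percentage), "Not available",
                         sprintf("%.1f", round_half_up(y$percentage, 1)))
  if (format == "csv") {
    utils::write.csv(y, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(y, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
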