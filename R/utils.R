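# Shared enum levels and small numeric helpers.

SEX_LEVELS        <- c("female", "male", "missing")
SCHOOLING_LEVELS  <- c("illiterate", "primary", "secondary", "high_school",
                       "university", "missing")
MARITAL_LEVELS    <- c("married_partner", "single_divorced", "widowed",
                       "missing")
EMPLOYMENT_LEVELS <- c("housewife", "employed", "unemployed", "retired",
                       "missing")
INSURANCE_LEVELS  <- c("subscriber", "dependent", "missing")
VISIT_TYPES       <- c("family_doctor", "nutrition_service", "other")
DRUG_LEVELS       <- c("metformin", "glibenclamide", "acarbose",
                       "rosiglitazone", "pioglitazone", "insulin",
                       "acetylsalicylic_acid", "statin", "acei", "arb",
                       "other")
ANALYTES          <- c("hba1c_pct", "fasting_glucose_mg_dl",
                       "total_cholesterol_mg_dl")
LAB_STATUS        <- c("ordered_only", "resulted")
CARE_EVENT_KINDS  <- c("ophthalmology_referral", "foot_exam")
CONTRA_FLAGS      <- c("metformin", "acei_arb", "asa", "statin")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when formatting percentages for
#' report tables. Base \code{round()} rounds half to even, which does not
#' match conventional table formatting (e.g. 8.875 must print as 8.9).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(8.875, 2)  # 8.88
#' round_half_up(0.5, 0)    # 1
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored as 8.8749999... (binary
  # representation of a decimal 8.875) still round up
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Completed age in years at a reference date
#'
#' @param birth_date,ref_date `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @export
age_at <- function(birth_date, ref_date) {
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(ref_date)
  age <- r$year - b$year
  before_birthday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  as.integer(age - ifelse(before_birthday, 1L, 0L))
}

# probability check used by config validators
.check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("config error: ", what, " must be a probability in [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

# empty data.frame with given character columns; numeric/date columns are
# coerced downstream, this is only used for zero-row tables
.empty_df <- function(cols) {
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

# minimal-overhead data.frame constructor for equal-length vectors; used in
# hot per-patient loops where data.frame()'s checks dominate runtime
.qdf <- function(...) {
  x <- list(...)
  n <- if (length(x)) length(x[[1L]]) else 0L
  class(x) <- "data.frame"
  attr(x, "row.names") <- if (n) c(NA_integer_, -n) else integer(0)
  x
}

# stable rbind of a list of data.frames sharing identical columns
.rbind_all <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
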