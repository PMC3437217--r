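# Flat-file EHR data model: table schemas, bundle container, readers/writers.
#
# The extract is modelled as seven delimited tables (one per record type)
# plus an optional clinic registry. Dates are ISO-8601 in files; missing
# values are empty cells ("NA" is also accepted on read).

# canonical column sets, in file order
EHR_SCHEMAS <- list(
  patients = c("patient_id", "clinic_id", "sex", "birth_date", "schooling",
               "marital_status", "employment", "insurance_role",
               "diabetes_onset_year", "contraindications"),
  diagnoses = c("patient_id", "icd10_code", "recorded_date", "field_slot"),
  visits = c("patient_id", "clinic_id", "visit_date", "visit_type"),
  vitals = c("patient_id", "measure_date", "weight_kg", "height_cm",
             "systolic_mmhg", "diastolic_mmhg"),
  prescriptions = c("patient_id", "visit_date", "drug", "daily_dose_mg"),
  labs = c("patient_id", "event_date", "analyte", "status", "value"),
  care_events = c("patient_id", "event_date", "kind")
)

EHR_DATE_COLS <- list(
  diagnoses = "recorded_date", visits = "visit_date",
  vitals = "measure_date", prescriptions = "visit_date",
  labs = "event_date", care_events = "event_date", patients = "birth_date"
)

EHR_NUM_COLS <- list(
  patients = "diabetes_onset_year", diagnoses = "field_slot",
  vitals = c("weight_kg", "height_cm", "systolic_mmhg", "diastolic_mmhg"),
  prescriptions = "daily_dose_mg", labs = "value"
)

#' Default synonym map used to normalise drug names on read
#'
#' Electronic prescriptions name generic products; indicator logic works on
#' drug classes. Any name not covered maps to \code{"other"}.
#'
#' @return named list: class name -> character vector of product synonyms.
#' @export
default_drug_synonyms <- function() {
  list(
    metformin = c("metformin", "metformina"),
    glibenclamide = c("glibenclamide", "glyburide", "glibenclamida"),
    acarbose = "acarbose",
    rosiglitazone = "rosiglitazone",
    pioglitazone = "pioglitazone",
    insulin = c("insulin", "insulin_nph", "insulin_glargine", "insulina"),
    acetylsalicylic_acid = c("acetylsalicylic_acid", "aspirin", "asa"),
    statin = c("statin", "pravastatin", "simvastatin", "atorvastatin",
               "rosuvastatin"),
    acei = c("acei", "enalapril", "captopril", "lisinopril", "ramipril"),
    arb = c("arb", "losartan", "telmisartan", "valsartan", "candesartan")
  )
}

#' File dialect for the flat EHR extract
#'
#' @param sep field delimiter.
#' @param na_strings strings read as missing (missing is written as "").
#' @param date_format date format in files (ISO-8601 by default).
#' @param drug_synonyms synonym map, see [default_drug_synonyms()].
#' @return a list of class `ehr_dialect`.
#' @export
ehr_dialect <- function(sep = ",", na_strings = c("", "NA"),
                        date_format = "%Y-%m-%d",
                        drug_synonyms = default_drug_synonyms()) {
  structure(list(sep = sep, na_strings = na_strings,
                 date_format = date_format, drug_synonyms = drug_synonyms),
            class = "ehr_dialect")
}

# map product names onto drug-class enum; unknown -> "other"
.normalize_drugs <- function(x, synonyms) {
  lut <- unlist(lapply(names(synonyms), function(cls) {
    setNames(rep(cls, length(synonyms[[cls]])), tolower(synonyms[[cls]]))
  }))
  out <- unname(lut[tolower(x)])
  out[is.na(out) & !is.na(x)] <- "other"
  out
}

#' Assemble an EHR bundle from in-memory tables
#'
#' Performs light validation (required columns, referential integrity).
#' Non-patient rows whose `patient_id` does not resolve to a row of
#' `patients` are an error here; [read_ehr_bundle()] drops and logs them
#' instead, which is the tolerant path for file ingestion.
#'
#' @param patients,diagnoses,visits,vitals,prescriptions,labs,care_events
#'   data frames following the documented schemas; missing tables default to
#'   empty.
#' @param clinic_registry optional data frame of per-clinic denominators and
#'   resources (`clinic_id`, `n_members`, `n_members_adult`, `n_attendees`,
#'   `hba1c_available`).
#' @return an object of class `ehr_bundle`: a named list of tables.
#' @export
ehr_bundle <- function(patients = NULL, diagnoses = NULL, visits = NULL,
                       vitals = NULL, prescriptions = NULL, labs = NULL,
                       care_events = NULL, clinic_registry = NULL) {
  tabs <- list(patients = patients, diagnoses = diagnoses, visits = visits,
               vitals = vitals, prescriptions = prescriptions, labs = labs,
               care_events = care_events)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) {
      tabs[[nm]] <- .coerce_table(.empty_df(EHR_SCHEMAS[[nm]]), nm,
                                  ehr_dialect())
    }
    missing_cols <- setdiff(EHR_SCHEMAS[[nm]], names(tabs[[nm]]))
    if (length(missing_cols)) {
      stop("schema error: table '", nm, "' is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    tabs[[nm]] <- tabs[[nm]][, EHR_SCHEMAS[[nm]], drop = FALSE]
  }
  if (anyDuplicated(tabs$patients$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  known <- tabs$patients$patient_id
  for (nm in setdiff(names(tabs), "patients")) {
    bad <- !(tabs[[nm]]$patient_id %in% known)
    if (any(bad)) {
      stop("referential integrity: ", sum(bad), " row(s) of '", nm,
           "' reference unknown patient_id", call. = FALSE)
    }
  }
  structure(c(tabs, list(clinic_registry = clinic_registry)),
            class = "ehr_bundle")
}

# coerce character-read table to typed columns
.coerce_table <- function(df, name, dialect) {
  for (col in EHR_DATE_COLS[[name]]) {
    df[[col]] <- as.Date(as.character(df[[col]]), format = dialect$date_format)
  }
  for (col in EHR_NUM_COLS[[name]]) {
    df[[col]] <- suppressWarnings(as.numeric(as.character(df[[col]])))
  }
  if (name == "diagnoses") df$field_slot <- as.integer(df$field_slot)
  if (name == "patients") {
    df$diabetes_onset_year <- as.integer(df$diabetes_onset_year)
    # empty contraindication set is the empty string, not missing
    df$contraindications[is.na(df$contraindications)] <- ""
  }
  for (col in setdiff(names(df), c(EHR_DATE_COLS[[name]],
                                   EHR_NUM_COLS[[name]]))) {
    df[[col]] <- as.character(df[[col]])
  }
  rownames(df) <- NULL
  df
}

#' Read a flat-file EHR extract into a bundle
#'
#' Reads the seven delimited tables, types the columns, normalises drug
#' names through the dialect's synonym map, and enforces referential
#' integrity: rows whose `patient_id` is absent from the patients table, and
#' rows with unparseable dates, are dropped and recorded in the load log
#' (attribute `"load_log"`), never fatal. A missing required column is fatal
#' and names the table and column.
#'
#' @param dir directory containing `patients.csv`, `diagnoses.csv`, ... ;
#'   ignored when `paths` is given.
#' @param paths optional named list/vector of file paths keyed by table name.
#' @param dialect an [ehr_dialect()].
#' @return an `ehr_bundle`; attribute `"load_log"` is a data frame with one
#'   row per dropped record (`table`, `row`, `patient_id`, `issue`).
#' @export
read_ehr_bundle <- function(dir = NULL, paths = NULL,
                            dialect = ehr_dialect()) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- setNames(file.path(dir, paste0(names(EHR_SCHEMAS), ".csv")),
                      names(EHR_SCHEMAS))
  }
  log <- list()
  tabs <- list()
  for (nm in names(EHR_SCHEMAS)) {
    if (!file.exists(paths[[nm]])) {
      stop("missing table file: ", paths[[nm]], call. = FALSE)
    }
    raw <- utils::read.csv(paths[[nm]], sep = dialect$sep,
                           colClasses = "character",
                           na.strings = dialect$na_strings,
                           stringsAsFactors = FALSE)
    missing_cols <- setdiff(EHR_SCHEMAS[[nm]], names(raw))
    if (length(missing_cols)) {
      stop("schema error: table '", nm, "' is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    raw <- raw[, EHR_SCHEMAS[[nm]], drop = FALSE]
    df <- .coerce_table(raw, nm, dialect)
    # unparseable (non-missing) dates -> drop row, log
    for (col in setdiff(EHR_DATE_COLS[[nm]], "birth_date")) {
      bad <- is.na(df[[col]]) & !is.na(raw[[col]])
      if (any(bad)) {
        log[[length(log) + 1L]] <- data.frame(
          table = nm, row = which(bad), patient_id = df$patient_id[bad],
          issue = paste0("unparseable date in '", col, "'"),
          stringsAsFactors = FALSE)
        df <- df[!bad, , drop = FALSE]
        raw <- raw[!bad, , drop = FALSE]
      }
    }
    if (nm == "prescriptions") {
      df$drug <- .normalize_drugs(df$drug, dialect$drug_synonyms)
    }
    rownames(df) <- NULL
    tabs[[nm]] <- df
  }
  known <- tabs$patients$patient_id
  for (nm in setdiff(names(tabs), "patients")) {
    orphan <- !(tabs[[nm]]$patient_id %in% known)
    if (any(orphan)) {
      log[[length(log) + 1L]] <- data.frame(
        table = nm, row = which(orphan),
        patient_id = tabs[[nm]]$patient_id[orphan],
        issue = "orphan record: patient_id not in patients table",
        stringsAsFactors = FALSE)
      tabs[[nm]] <- tabs[[nm]][!orphan, , drop = FALSE]
      rownames(tabs[[nm]]) <- NULL
    }
  }
  registry_path <- if (!is.null(dir)) file.path(dir, "clinic_registry.csv")
                   else paths[["clinic_registry"]]
  registry <- NULL
  if (!is.null(registry_path) && length(registry_path) == 1 &&
      !is.na(registry_path) && file.exists(registry_path)) {
    registry <- utils::read.csv(registry_path, sep = dialect$sep,
                                na.strings = dialect$na_strings,
                                stringsAsFactors = FALSE)
    if ("hba1c_available" %in% names(registry)) {
      registry$hba1c_available <- as.logical(registry$hba1c_available)
    }
  }
  b <- do.call(ehr_bundle, c(tabs, list(clinic_registry = registry)))
  load_log <- .rbind_all(log)
  if (is.null(load_log)) {
    load_log <- data.frame(table = character(0), row = integer(0),
                           patient_id = character(0), issue = character(0),
                           stringsAsFactors = FALSE)
  }
  attr(b, "load_log") <- load_log
  b
}

#' Write a bundle as the flat-file analytic dataset
#'
#' Writes one delimited table per record type (dates ISO-8601, missing as
#' empty cells) so that [read_ehr_bundle()] reproduces the bundle
#' record-for-record. The load log, if present, is written alongside as
#' line-oriented JSON (`load_log.jsonl`); a ground-truth sidecar attribute
#' from the simulator is written as `truth.csv`.
#'
#' @param bundle an `ehr_bundle`.
#' @param dir output directory (created if needed).
#' @param dialect an [ehr_dialect()].
#' @return `dir`, invisibly.
#' @export
write_ehr_bundle <- function(bundle, dir, dialect = ehr_dialect()) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(EHR_SCHEMAS)) {
    df <- bundle[[nm]]
    for (col in EHR_DATE_COLS[[nm]]) {
      df[[col]] <- format(df[[col]], dialect$date_format)
    }
    utils::write.table(df, file.path(dir, paste0(nm, ".csv")),
                       sep = dialect$sep, na = "", row.names = FALSE,
                       qmethod = "double", quote = TRUE)
  }
  if (!is.null(bundle$clinic_registry)) {
    utils::write.table(bundle$clinic_registry,
                       file.path(dir, "clinic_registry.csv"),
                       sep = dialect$sep, na = "", row.names = FALSE,
                       quote = TRUE)
  }
  ll <- attr(bundle, "load_log")
  if (!is.null(ll) && nrow(ll) > 0) {
    con <- file(file.path(dir, "load_log.jsonl"), "w")
    for (i in seq_len(nrow(ll))) {
      writeLines(jsonlite::toJSON(as.list(ll[i, ]), auto_unbox = TRUE), con)
    }
    close(con)
  }
  truth <- attr(bundle, "truth")
  if (!is.null(truth)) {
    utils::write.table(truth, file.path(dir, "truth.csv"), sep = dialect$sep,
                       na = "", row.names = FALSE, quote = TRUE)
  }
  invisible(dir)
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>\n")
  for (nm in names(EHR_SCHEMAS)) {
    cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  }
  if (!is.null(x$clinic_registry)) {
    cat(sprintf("  clinic_registry: %d clinics\n", nrow(x$clinic_registry)))
  }
  ll <- attr(x, "load_log")
  if (!is.null(ll) && nrow(ll)) cat("  load log:", nrow(ll), "entries\n")
  invisible(x)
}
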