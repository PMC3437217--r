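# Independent brute-force implementations of cohort selection and indicator
# evaluation, written naively from the published rules (per-patient loops
# over raw tables; no shared code with the package internals). Used as the
# oracle in equivalence tests on small bundles.

oracle_norm_code <- function(x) toupper(gsub(".", "", x, fixed = TRUE))

oracle_t2dm_codes <- function() {
  c(paste0("E11", 1:9), paste0("E14", 1:9), "E14X", "E14")
}

# completed age via calendar-year sequence (independent of age_at)
oracle_age <- function(birth, ref) {
  if (birth > ref) return(NA_integer_)
  length(seq(from = birth, to = ref, by = "1 year")) - 1L
}

oracle_select_ids <- function(bundle, w0 = as.Date("2009-01-01"),
                              w1 = as.Date("2009-12-31"), min_age = 20L) {
  keep <- character(0)
  for (i in seq_len(nrow(bundle$patients))) {
    p <- bundle$patients[i, ]
    dx <- bundle$diagnoses[bundle$diagnoses$patient_id == p$patient_id, ]
    has_code <- FALSE
    for (j in seq_len(nrow(dx))) {
      if (!is.na(dx$recorded_date[j]) && dx$recorded_date[j] <= w1 &&
          dx$field_slot[j] %in% c(1, 2, 3) &&
          oracle_norm_code(dx$icd10_code[j]) %in% oracle_t2dm_codes()) {
        has_code <- TRUE
      }
    }
    if (!has_code) next
    if (oracle_age(p$birth_date, w0) < min_age) next
    vis <- bundle$visits[bundle$visits$patient_id == p$patient_id, ]
    ok_visit <- FALSE
    for (j in seq_len(nrow(vis))) {
      if (vis$visit_type[j] == "family_doctor" &&
          !is.na(vis$visit_date[j]) &&
          vis$visit_date[j] >= w0 && vis$visit_date[j] <= w1) {
        ok_visit <- TRUE
      }
    }
    if (ok_visit) keep <- c(keep, p$patient_id)
  }
  keep
}

# plausibility check straight from the published bounds
oracle_plausible <- function(measure, v) {
  switch(measure,
         systolic = v >= 50 & v <= 250,
         diastolic = v >= 40 & v <= 200,
         height = v >= 130 & v <= 250,
         weight = v >= 30 & v <= 200,
         hba1c = v >= 3,
         fasting_glucose = v >= 37,
         total_cholesterol = v >= 100)
}

# pooled numerator/denominator per indicator, by per-patient re-derivation
oracle_eval <- function(bundle, ids, w0 = as.Date("2009-01-01"),
                        w1 = as.Date("2009-12-31")) {
  res <- matrix(0L, nrow = 14, ncol = 2,
                dimnames = list(c("P1", "P2", "P3", "P4", "P5", "P6", "P7",
                                  "P8", "P9", "O1", "O2", "O3", "O4", "O5"),
                                c("num", "den")))
  prefix_any <- function(codes, prefixes) {
    out <- FALSE
    for (p in prefixes) if (any(substr(codes, 1, nchar(p)) == p))
      out <- TRUE
    out
  }
  for (pid in ids) {
    p <- bundle$patients[bundle$patients$patient_id == pid, ]
    dx <- bundle$diagnoses[bundle$diagnoses$patient_id == pid, ]
    dx <- dx[!is.na(dx$recorded_date) & dx$recorded_date <= w1, ]
    codes <- oracle_norm_code(dx$icd10_code)
    codes_pre <- codes[dx$recorded_date < w0]
    htn <- prefix_any(codes, c("I10", "I11", "I12", "I13", "I14", "I15"))
    dyslip <- prefix_any(codes, "E78")
    dyslip_pre <- prefix_any(codes_pre, "E78")
    smoking <- prefix_any(codes, c("Z720", "F17"))
    contra <- strsplit(ifelse(is.na(p$contraindications), "",
                              p$contraindications), "|", fixed = TRUE)[[1]]

    vis <- bundle$visits[bundle$visits$patient_id == pid, ]
    fd <- sort(vis$visit_date[vis$visit_type == "family_doctor" &
                                vis$visit_date >= w0 &
                                vis$visit_date <= w1])
    last3 <- if (length(fd) > 3) fd[(length(fd) - 2):length(fd)] else fd
    nutr <- vis$visit_date[vis$visit_type == "nutrition_service" &
                             vis$visit_date >= w0 & vis$visit_date <= w1]

    labs <- bundle$labs[bundle$labs$patient_id == pid, ]
    labs <- labs[labs$status == "resulted" & !is.na(labs$value) &
                   labs$event_date >= w0 & labs$event_date <= w1, ]
    get_series <- function(analyte, measure) {
      s <- labs[labs$analyte == analyte, ]
      s <- s[order(s$event_date), ]
      s$value[oracle_plausible(measure, s$value)]
    }
    hba1c <- get_series("hba1c_pct", "hba1c")
    glu <- get_series("fasting_glucose_mg_dl", "fasting_glucose")
    chol <- get_series("total_cholesterol_mg_dl", "total_cholesterol")

    vit <- bundle$vitals[bundle$vitals$patient_id == pid, ]
    vit <- vit[vit$measure_date >= w0 & vit$measure_date <= w1, ]
    vit <- vit[order(vit$measure_date), ]
    wts <- vit$weight_kg[!is.na(vit$weight_kg) &
                           oracle_plausible("weight", vit$weight_kg)]
    bp_keep <- !is.na(vit$systolic_mmhg) & !is.na(vit$diastolic_mmhg) &
      oracle_plausible("systolic", vit$systolic_mmhg) &
      oracle_plausible("diastolic", vit$diastolic_mmhg)
    bps <- vit[bp_keep, c("systolic_mmhg", "diastolic_mmhg")]
    bmi_keep <- !is.na(vit$weight_kg) & !is.na(vit$height_cm) &
      oracle_plausible("weight", vit$weight_kg) &
      oracle_plausible("height", vit$height_cm)
    bmis <- round(vit$weight_kg[bmi_keep] /
                    (vit$height_cm[bmi_keep] / 100)^2, 2)
    bmi_first <- if (length(bmis)) bmis[1] else NA

    rx <- bundle$prescriptions[bundle$prescriptions$patient_id == pid, ]
    rx <- rx[rx$visit_date %in% last3, ]
    drug_last3 <- function(drugs) any(rx$drug %in% drugs)
    ce <- bundle$care_events[bundle$care_events$patient_id == pid, ]
    ce <- ce[ce$event_date >= w0 & ce$event_date <= w1, ]

    lastn <- function(x, k) if (length(x) > k)
      x[(length(x) - k + 1):length(x)] else x
    gly_met <- (length(hba1c) > 0 && all(lastn(hba1c, 3) < 7)) ||
      (length(glu) > 0 && all(lastn(glu, 3) <= 130))
    bp3 <- if (nrow(bps)) bps[max(1, nrow(bps) - 2):nrow(bps), ] else bps
    bp_met <- nrow(bps) > 0 && all(bp3$systolic_mmhg < 130 &
                                     bp3$diastolic_mmhg < 80)
    last_chol <- if (length(chol)) chol[length(chol)] else NA
    overwt <- !is.na(bmi_first) && bmi_first >= 25 &&
      !("metformin" %in% contra)
    age <- oracle_age(p$birth_date, w0)

    tally <- function(id, den, num) {
      if (den) {
        res[id, "den"] <<- res[id, "den"] + 1L
        if (num) res[id, "num"] <<- res[id, "num"] + 1L
      }
    }
    tally("P1", TRUE, length(hba1c) > 0)
    tally("P2", TRUE, any(ce$kind == "foot_exam"))
    tally("P3", TRUE, any(ce$kind == "ophthalmology_referral"))
    tally("P4", !dyslip_pre, length(chol) > 0)
    tally("P5", TRUE, length(nutr) > 0)
    tally("P6", overwt, drug_last3("metformin"))
    tally("P7", htn && !("acei_arb" %in% contra),
          drug_last3(c("acei", "arb")))
    tally("P8", age > 40 && (smoking || htn || dyslip) &&
            !("asa" %in% contra),
          any(rx$drug == "acetylsalicylic_acid" &
                !is.na(rx$daily_dose_mg) &
                rx$daily_dose_mg >= 75 & rx$daily_dose_mg <= 150))
    tally("P9", !is.na(last_chol) && last_chol > 200 &&
            !("statin" %in% contra), drug_last3("statin"))
    tally("O1", length(hba1c) > 0 || length(glu) > 0, gly_met)
    tally("O2", length(chol) > 0, !is.na(last_chol) && last_chol < 200)
    tally("O3", nrow(bps) > 0, bp_met)
    tally("O4", overwt && length(wts) >= 2,
          100 * (wts[length(wts)] - wts[1]) / wts[1] <= -5)
    tally("O5", (length(hba1c) > 0 || length(glu) > 0) &&
            length(chol) > 0 && nrow(bps) > 0,
          gly_met && bp_met && !is.na(last_chol) && last_chol < 200)
  }
  res
}
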