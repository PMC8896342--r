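## Clinical data model: patient metadata, WHO BMI classes, glycemic control,
## biochemical reference ranges, and cohort descriptive statistics.

.THERAPY_COLS <- c("insulin", "metformin", "dpp4i", "sglt2i", "glp1ra")

.NUMERIC_CLIN <- c("age_years", "onset_age_years", "family_history_dm_n",
                   "bmi_kg_m2", "hba1c_pct", "fasting_glucose_mg_dl",
                   "c_peptide_ng_ml")

#' Biochemical reference ranges
#'
#' Laboratory reference intervals used to flag abnormal values: fasting
#' glucose 74--105 mg/dL, HbA1c below 5.7\%, C-peptide 0.81--2.85 ng/mL,
#' and the HbA1c treatment target of 7\% that separates controlled from
#' poor glycemic control in treated patients.
#'
#' @param glucose_low,glucose_high fasting glucose interval, mg/dL.
#' @param hba1c_upper upper HbA1c reference bound, percent.
#' @param c_peptide_low,c_peptide_high C-peptide interval, ng/mL.
#' @param hba1c_control_target HbA1c treatment target, percent.
#' @return A named list of class \code{ReferenceRanges}.
#' @export
referenceRanges <- function(glucose_low = 74, glucose_high = 105,
                            hba1c_upper = 5.7,
                            c_peptide_low = 0.81, c_peptide_high = 2.85,
                            hba1c_control_target = 7.0) {
    stopifnot(glucose_low < glucose_high, c_peptide_low < c_peptide_high)
    structure(list(glucose_low = glucose_low, glucose_high = glucose_high,
                   hba1c_upper = hba1c_upper,
                   c_peptide_low = c_peptide_low,
                   c_peptide_high = c_peptide_high,
                   hba1c_control_target = hba1c_control_target),
              class = "ReferenceRanges")
}

#' WHO body-mass-index class
#'
#' Classifies BMI (kg/m^2) by the WHO cutoffs: underweight below 18.5,
#' normal 18.5--24.99, overweight 25--29.99, obese at or above 30.
#'
#' @param bmi numeric vector of BMI values, kg/m^2; must be positive.
#' @return Factor with levels underweight, normal, overweight, obese
#'   (\code{NA} propagated).
#' @export
#' @examples
#' bmiClass(c(17, 18.5, 24.99, 29.1, 40.2))
bmiClass <- function(bmi) {
    if (any(!is.na(bmi) & bmi <= 0))
        stop("BMI must be positive")
    cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
        labels = c("underweight", "normal", "overweight", "obese"))
}

#' Glycemic-control flag
#'
#' Treated patients at or above the 7\% HbA1c target are in poor control;
#' below it, controlled. Missing HbA1c yields \code{"unknown"} and is
#' excluded from cohort denominators.
#'
#' @param hba1c numeric HbA1c, percent.
#' @param target HbA1c target, percent (default 7).
#' @return Character vector: \code{"controlled"}, \code{"poor"} or
#'   \code{"unknown"}.
#' @export
#' @examples
#' glycemicControl(c(6.9, 7.0, 9.8, NA))
glycemicControl <- function(hba1c, target = 7.0) {
    if (any(!is.na(hba1c) & hba1c <= 0))
        stop("HbA1c must be positive")
    ifelse(is.na(hba1c), "unknown", ifelse(hba1c >= target, "poor", "controlled"))
}

#' Is a biochemical value within its reference range?
#'
#' Closed reference intervals for glucose and C-peptide; upper-bound-only
#' (strictly below) for HbA1c.
#'
#' @param value numeric measurement, positive.
#' @param analyte one of \code{"glucose"}, \code{"hba1c"},
#'   \code{"c_peptide"}.
#' @param ranges a \code{\link{referenceRanges}} list.
#' @return Logical vector.
#' @export
withinReference <- function(value, analyte = c("glucose", "hba1c", "c_peptide"),
                            ranges = referenceRanges()) {
    analyte <- match.arg(analyte)
    if (any(!is.na(value) & value <= 0))
        stop("measurement values must be positive")
    switch(analyte,
        glucose   = value >= ranges$glucose_low & value <= ranges$glucose_high,
        hba1c     = value < ranges$hba1c_upper,
        c_peptide = value >= ranges$c_peptide_low & value <= ranges$c_peptide_high)
}

#' Read a patient/control clinical metadata table
#'
#' Tab-separated table with one row per participant. Expected columns:
#' \code{case_id}, \code{group}, \code{age_years}, \code{sex} (M/F),
#' \code{onset_age_years}, \code{family_history_dm_n}, \code{bmi_kg_m2}
#' (or \code{weight_kg} + \code{height_m}, from which BMI is derived),
#' \code{hba1c_pct}, \code{fasting_glucose_mg_dl}, \code{c_peptide_ng_ml},
#' \code{secondary_complications} and the therapy columns \code{insulin},
#' \code{metformin}, \code{dpp4i}, \code{sglt2i}, \code{glp1ra} (Yes/No).
#' Empty fields are missing values.
#'
#' @param path TSV path.
#' @return A \code{data.frame} of validated patient records.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    if (!"case_id" %in% names(df))
        stop(sprintf("clinical table '%s' must have a case_id column", path))
    if (anyDuplicated(df$case_id))
        stop("duplicate case_id in clinical table")
    if (!"bmi_kg_m2" %in% names(df) &&
        all(c("weight_kg", "height_m") %in% names(df)))
        df$bmi_kg_m2 <- df$weight_kg / df$height_m^2
    for (col in intersect(.NUMERIC_CLIN, names(df)))
        df[[col]] <- as.numeric(df[[col]])
    yesno <- function(x) {
        out <- tolower(as.character(x)) %in% c("yes", "true", "1")
        out[is.na(x)] <- NA
        out
    }
    for (col in intersect(c(.THERAPY_COLS, "secondary_complications"), names(df)))
        df[[col]] <- yesno(df[[col]])
    validateClinicalTable(df)
    df
}

#' Validate clinical-record invariants
#'
#' Checks that onset age does not exceed enrolment age and that any stored
#' BMI agrees (within 0.05) with BMI derived from weight and height when
#' both are present.
#'
#' @param df clinical \code{data.frame}.
#' @return Invisibly \code{TRUE}; stops on violation.
#' @export
validateClinicalTable <- function(df) {
    if (all(c("onset_age_years", "age_years") %in% names(df))) {
        bad <- which(!is.na(df$onset_age_years) & !is.na(df$age_years) &
                     df$onset_age_years > df$age_years)
        if (length(bad))
            stop(sprintf("onset age exceeds enrolment age for: %s",
                         paste(df$case_id[bad], collapse = ", ")))
    }
    if (all(c("weight_kg", "height_m", "bmi_kg_m2") %in% names(df))) {
        derived <- df$weight_kg / df$height_m^2
        bad <- which(!is.na(derived) & !is.na(df$bmi_kg_m2) &
                     abs(derived - df$bmi_kg_m2) > 0.05)
        if (length(bad))
            stop(sprintf("stored BMI disagrees with weight/height^2 for: %s",
                         paste(df$case_id[bad], collapse = ", ")))
    }
    invisible(TRUE)
}

#' Cohort descriptive statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of each numeric
#' clinical field over non-missing values, plus counts and fractions of the
#' categorical fields: sex, each therapy, any antidiabetic therapy, WHO BMI
#' class, and glycemic control. Fractions are reported over the full cohort
#' denominator; the glycemic-control fraction additionally reports its
#' non-missing denominator.
#'
#' @param records clinical \code{data.frame} (typically patients only).
#' @return A list with elements \code{numeric} (data.frame: field, n, mean,
#'   sd), \code{categorical} (data.frame: field, level, count, fraction,
#'   denominator) and \code{n} (cohort size).
#' @export
cohortSummary <- function(records) {
    if (nrow(records) == 0L)
        stop("empty cohort")
    n <- nrow(records)
    num <- do.call(rbind, lapply(intersect(.NUMERIC_CLIN, names(records)),
        function(col) {
            v <- records[[col]][!is.na(records[[col]])]
            data.frame(field = col, n = length(v),
                       mean = if (length(v)) mean(v) else NA_real_,
                       sd = if (length(v) >= 2L) sd(v) else NA_real_)
        }))
    cat_rows <- list()
    addrow <- function(field, level, count, denom = n) {
        cat_rows[[length(cat_rows) + 1L]] <<- data.frame(
            field = field, level = level, count = count,
            fraction = count / denom, denominator = denom)
    }
    if ("sex" %in% names(records))
        for (s in c("M", "F"))
            addrow("sex", s, sum(records$sex == s, na.rm = TRUE))
    present_therapies <- intersect(.THERAPY_COLS, names(records))
    for (col in present_therapies)
        addrow("therapy", col, sum(records[[col]], na.rm = TRUE))
    if (length(present_therapies)) {
        any_tx <- rowSums(records[present_therapies], na.rm = TRUE) >= 1L
        addrow("therapy", "any", sum(any_tx))
        addrow("therapy", "multiple", sum(
            rowSums(records[present_therapies], na.rm = TRUE) >= 2L))
    }
    if ("bmi_kg_m2" %in% names(records)) {
        cls <- bmiClass(records$bmi_kg_m2)
        for (lv in levels(cls))
            addrow("bmi_class", lv, sum(cls == lv, na.rm = TRUE))
    }
    if ("hba1c_pct" %in% names(records)) {
        gc <- glycemicControl(records$hba1c_pct)
        denom <- sum(gc != "unknown")
        addrow("glycemic_control", "poor", sum(gc == "poor"))
        addrow("glycemic_control", "controlled", sum(gc == "controlled"))
        addrow("glycemic_control", "poor_of_known", sum(gc == "poor"),
               denom = max(denom, 1L))
    }
    if ("secondary_complications" %in% names(records))
        addrow("secondary_complications", "yes",
               sum(records$secondary_complications, na.rm = TRUE))
    if ("family_history_dm_n" %in% names(records))
        addrow("family_history", "any",
               sum(records$family_history_dm_n >= 1L, na.rm = TRUE))
    list(numeric = num, categorical = do.call(rbind, cat_rows), n = n)
}
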