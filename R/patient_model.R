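#' @keywords internal
"_PACKAGE"

## Patient feature schema -----------------------------------------------------
##
## A cohort is a plain data.frame with one row per patient and a fixed column
## set: clinical history, laboratory results (tri-state: a test may not have
## been performed), MDCT imaging flags, and optional MRI/PET fields.
## Tri-state fields are stored as the character tokens "true"/"false"/
## "not_done" so that an unperformed test is never silently coerced to a
## negative result; suv_max is numeric with NA meaning not measured.

#' Disease label vocabulary
#'
#' The eight fibrosing lung diseases distinguished by the stepwise algorithm.
#' `INDETERMINATE` is a valid *prediction* (no rule fired) but never a valid
#' ground-truth label.
#'
#' @return Character vector of the eight ground-truth disease labels.
#' @export
disease_labels <- function() {
  c("UIP_IPF", "FIBROSING_NSIP", "CHRONIC_HP", "PPFE",
    "POST_TB", "POST_IRRADIATION", "SARCOIDOSIS", "PMF")
}

#' Malignancy complication flags
#'
#' Malignancy only complicates the non-interstitial scarring diseases in this
#' framework: scar carcinoma arises in post-tuberculous fibrosis, metastatic
#' spread in post-irradiation fibrosis.
#'
#' @return Character vector `c("NONE", "SCAR_CARCINOMA", "METASTASIS")`.
#' @export
malignancy_flags <- function() {
  c("NONE", "SCAR_CARCINOMA", "METASTASIS")
}

#' Boolean clinical/imaging fields of a patient record
#' @return Character vector of field names stored as logicals.
#' @export
boolean_fields <- function() {
  c("smoking_history", "allergen_exposure", "occupational_dust_exposure",
    "rheumatologic_history", "malignancy_irradiation_history",
    "skin_erythema", "arthralgia",
    "upper_lobe_predominance", "lower_lobe_predominance",
    "peripheral_subpleural", "peribronchovascular",
    "ground_glass", "air_trapping", "head_cheese_sign",
    "traction_bronchiectasis", "honeycombing", "crazy_paving",
    "centrilobular_nodules", "perilymphatic_nodules",
    "calcific_random_nodules", "tree_in_bud",
    "consolidation_calcification", "cavitation",
    "lymphadenopathy_gt_1cm", "pulmonary_hypertension", "platy_thorax",
    "fibrosis_confined_to_radiation_field")
}

#' Tri-state (true/false/not_done) laboratory and MRI fields
#' @return Character vector of field names stored as tri-state tokens.
#' @export
tristate_fields <- function() {
  c("blood_eosinophilia", "serum_ige_elevated", "tuberculin_positive",
    "bal_lymphocytosis", "t2_hyperintense", "dwi_restriction")
}

#' Canonical cohort column order
#'
#' The column schema used by [read_cohort()] and [write_cohort()]. The two
#' label columns (`true_label`, `true_malignancy`) are optional on disk.
#'
#' @return Character vector of column names in serialization order.
#' @export
cohort_columns <- function() {
  c("patient_id", "age_years", "sex", "course",
    "smoking_history", "allergen_exposure", "occupational_dust_exposure",
    "rheumatologic_history", "malignancy_irradiation_history",
    "skin_erythema", "arthralgia",
    "blood_eosinophilia", "serum_ige_elevated", "tuberculin_positive",
    "bal_lymphocytosis",
    "upper_lobe_predominance", "lower_lobe_predominance",
    "peripheral_subpleural", "peribronchovascular",
    "ground_glass", "air_trapping", "head_cheese_sign",
    "traction_bronchiectasis", "honeycombing", "crazy_paving",
    "centrilobular_nodules", "perilymphatic_nodules",
    "calcific_random_nodules", "tree_in_bud",
    "consolidation_calcification", "cavitation",
    "lymphadenopathy_gt_1cm", "pulmonary_hypertension", "platy_thorax",
    "fibrosis_confined_to_radiation_field",
    "t2_hyperintense", "dwi_restriction", "suv_max",
    "true_label", "true_malignancy")
}

optional_columns <- function() c("true_label", "true_malignancy")

#' Construct a single patient record
#'
#' Returns a one-row data.frame with every boolean field `FALSE`, every
#' tri-state field `"not_done"`, no lobar predominance, and `suv_max`
#' unmeasured; any field can be overridden by name. Convenient for building
#' test fixtures and canonical disease profiles.
#'
#' @param patient_id Identifier string.
#' @param age_years Age in years (default 60).
#' @param sex `"M"` or `"F"`.
#' @param course `"insidious"` or `"rapidly_progressive"`.
#' @param ... Named field overrides (must be schema fields).
#' @return One-row data.frame following [cohort_columns()].
#' @export
patient_record <- function(patient_id = "P001", age_years = 60L, sex = "M",
                           course = "insidious", ...) {
  rec <- list(patient_id = patient_id, age_years = as.integer(age_years),
              sex = sex, course = course)
  for (f in boolean_fields()) rec[[f]] <- FALSE
  for (f in tristate_fields()) rec[[f]] <- "not_done"
  rec$suv_max <- NA_real_
  rec$true_label <- NA_character_
  rec$true_malignancy <- NA_character_
  dots <- list(...)
  bad <- setdiff(names(dots), cohort_columns())
  if (length(bad) > 0) {
    stop("unknown patient record field(s): ", paste(bad, collapse = ", "))
  }
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  as.data.frame(rec[cohort_columns()], stringsAsFactors = FALSE)
}

tristate_tokens <- function() c("true", "false", "not_done")

#' Validate a patient record against the schema invariants
#'
#' Checks field presence and types, enumeration membership, the age domain
#' (18-110 years), mutual exclusion of upper and lower lobar predominance
#' (both `FALSE` means no clear predominance and is allowed), non-negative
#' `suv_max`, and the malignancy-label consistency rules (scar carcinoma only
#' on post-TB fibrosis, metastasis only on post-irradiation fibrosis).
#'
#' Violations are *returned*, not raised, so a caller can report all problems
#' in a cohort at once.
#'
#' @param record A one-row data.frame or named list with the schema fields.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_record <- function(record) {
  record <- as.list(record)
  v <- character(0)
  mandatory <- setdiff(cohort_columns(), optional_columns())
  missing <- setdiff(mandatory, names(record))
  if (length(missing) > 0) {
    return(paste0("missing field: ", missing))
  }
  if (!is.character(record$patient_id) || is.na(record$patient_id) ||
      !nzchar(record$patient_id)) {
    v <- c(v, "patient_id: must be a non-empty string")
  }
  age <- record$age_years
  if (!is.numeric(age) || is.na(age) || age != as.integer(age)) {
    v <- c(v, "age_years: must be an integer")
  } else if (age < 18 || age > 110) {
    v <- c(v, sprintf("age_years: %d outside [18, 110]", as.integer(age)))
  }
  if (!record$sex %in% c("M", "F")) {
    v <- c(v, sprintf("sex: invalid value '%s'", record$sex))
  }
  if (!record$course %in% c("insidious", "rapidly_progressive")) {
    v <- c(v, sprintf("course: invalid value '%s'", record$course))
  }
  for (f in boolean_fields()) {
    x <- record[[f]]
    if (!is.logical(x) || is.na(x)) {
      v <- c(v, sprintf("%s: must be TRUE or FALSE", f))
    }
  }
  for (f in tristate_fields()) {
    x <- record[[f]]
    if (!is.character(x) || length(x) != 1 || !x %in% tristate_tokens()) {
      v <- c(v, sprintf("%s: must be one of true/false/not_done", f))
    }
  }
  if (isTRUE(record$upper_lobe_predominance) &&
      isTRUE(record$lower_lobe_predominance)) {
    v <- c(v, paste("upper_lobe_predominance, lower_lobe_predominance:",
                    "mutually exclusive"))
  }
  suv <- record$suv_max
  if (!is.numeric(suv)) {
    v <- c(v, "suv_max: must be numeric or NA (not measured)")
  } else if (!is.na(suv) && suv < 0) {
    v <- c(v, sprintf("suv_max: %g is negative", suv))
  }
  lab <- record$true_label
  if (!is.null(lab) && !is.na(lab)) {
    if (!lab %in% disease_labels()) {
      v <- c(v, sprintf(
        "true_label: '%s' is not a valid ground-truth disease label", lab))
    }
  }
  mal <- record$true_malignancy
  if (!is.null(mal) && !is.na(mal)) {
    if (!mal %in% malignancy_flags()) {
      v <- c(v, sprintf("true_malignancy: invalid value '%s'", mal))
    } else if (mal == "SCAR_CARCINOMA" &&
               (is.null(lab) || is.na(lab) || lab != "POST_TB")) {
      v <- c(v, "true_malignancy: SCAR_CARCINOMA requires true_label POST_TB")
    } else if (mal == "METASTASIS" &&
               (is.null(lab) || is.na(lab) || lab != "POST_IRRADIATION")) {
      v <- c(v,
        "true_malignancy: METASTASIS requires true_label POST_IRRADIATION")
    }
  }
  v
}

#' Validate every record of a cohort
#'
#' @param cohort Data.frame of patient records.
#' @return Named list (by patient_id) of non-empty violation vectors; empty
#'   list if the whole cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    v <- validate_record(cohort[i, , drop = FALSE])
    if (length(v) > 0) out[[as.character(cohort$patient_id[i])]] <- v
  }
  out
}

## Serialization --------------------------------------------------------------

serialize_cohort <- function(cohort) {
  cols <- intersect(cohort_columns(), names(cohort))
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  for (cl in cols) {
    x <- cohort[[cl]]
    if (cl %in% boolean_fields()) {
      out[[cl]] <- ifelse(x, "true", "false")
    } else if (cl == "suv_max") {
      out[[cl]] <- ifelse(is.na(x), "not_done",
                          vapply(x, format, "", digits = 15))
    } else if (cl %in% c("age_years")) {
      out[[cl]] <- as.character(as.integer(x))
    } else {
      out[[cl]] <- as.character(x)
    }
  }
  ## drop label columns that are entirely absent
  for (cl in intersect(optional_columns(), names(out))) {
    if (all(is.na(cohort[[cl]]))) out[[cl]] <- NULL
  }
  out
}

deserialize_cohort <- function(raw, lenient = FALSE) {
  known <- cohort_columns()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    if (!lenient) {
      stop("unknown column(s) in cohort file: ",
           paste(unknown, collapse = ", "),
           " (use lenient = TRUE to ignore)")
    }
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  mandatory <- setdiff(known, optional_columns())
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(row.names = seq_len(n))
  parse_bool <- function(x, col) {
    bad <- which(!x %in% c("true", "false"))
    if (length(bad) > 0) {
      stop(sprintf("column %s, row %d: invalid boolean token '%s'",
                   col, bad[1], x[bad[1]]))
    }
    x == "true"
  }
  parse_tri <- function(x, col) {
    bad <- which(!x %in% tristate_tokens())
    if (length(bad) > 0) {
      stop(sprintf("column %s, row %d: invalid tri-state token '%s'",
                   col, bad[1], x[bad[1]]))
    }
    x
  }
  for (cl in known) {
    if (!cl %in% names(raw)) {
      if (cl %in% optional_columns()) out[[cl]] <- rep(NA_character_, n)
      next
    }
    x <- as.character(raw[[cl]])
    out[[cl]] <-
      if (cl %in% boolean_fields()) parse_bool(x, cl)
      else if (cl %in% tristate_fields()) parse_tri(x, cl)
      else if (cl == "age_years") as.integer(x)
      else if (cl == "suv_max") {
        suppressWarnings(num <- as.numeric(ifelse(x == "not_done", NA, x)))
        bad <- which(is.na(num) & x != "not_done")
        if (length(bad) > 0) {
          stop(sprintf("column suv_max, row %d: invalid value '%s'",
                       bad[1], x[bad[1]]))
        }
        num
      }
      else x
  }
  out[known]
}

#' Write a cohort to CSV or JSON
#'
#' Columns are written in the fixed [cohort_columns()] order; booleans as
#' `true`/`false`, tri-state fields as `true`/`false`/`not_done`, and an
#' unmeasured `suv_max` as `not_done`. Writing the same records twice yields
#' byte-identical files. Label columns are omitted when absent from every
#' record.
#'
#' @param cohort Data.frame of valid patient records.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  bad <- validate_cohort(cohort)
  if (length(bad) > 0) {
    stop("invalid record(s): ",
         paste(sprintf("%s [%s]", names(bad),
                       vapply(bad, paste, "", collapse = "; ")),
               collapse = " / "))
  }
  ser <- serialize_cohort(cohort)
  if (format == "csv") {
    utils::write.csv(ser, path, row.names = FALSE, quote = FALSE, eol = "\n")
  } else {
    jsonlite::write_json(ser, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort from CSV or JSON
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x)) == x` for any
#' valid cohort. Unknown columns are rejected unless `lenient = TRUE`;
#' missing mandatory columns and malformed boolean/tri-state tokens raise
#' errors naming the column (and row).
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`.
#' @param lenient Ignore (drop) unknown columns instead of erroring.
#' @return Data.frame of patient records in schema column order.
#' @export
read_cohort <- function(path, format = c("csv", "json"), lenient = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("cohort file has no columns: ", path)
  }
  raw[] <- lapply(raw, as.character)
  deserialize_cohort(raw, lenient = lenient)
}
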