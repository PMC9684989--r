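## Stepwise multi-disciplinary rule engine ------------------------------------
##
## An ordered, first-match-wins rule list reconstructing the study's
## diagnostic flow: an irradiation-history gate first (post-irradiation
## fibrosis may be lower-lobe, so history overrides lobar routing), then a
## lower-lobe branch for the interstitial pneumonias and an upper-lobe
## branch for the scarring diseases. Within the upper branch TB-specific
## stigmata are checked before platy-thorax, so PPFE is only diagnosed when
## TB discriminators are absent -- which is exactly the direction of the
## study's residual TB/PPFE confusion. The malignancy overlay (MRI triad or
## SUV > 3) is evaluated independently of the terminal rule.

#' Classifier configuration
#'
#' @param suv_threshold PET standardized-uptake-value above which a lesion is
#'   treated as a malignancy predictor (default 3.0).
#' @param nodal_short_axis_threshold_cm Documentation of the lymphadenopathy
#'   definition (input records carry a pre-thresholded boolean); default 1 cm.
#' @return A `classifier_config` list including the fixed rule order.
#' @export
classifier_config <- function(suv_threshold = 3.0,
                              nodal_short_axis_threshold_cm = 1.0) {
  stopifnot(suv_threshold > 0)
  structure(list(
    suv_threshold = suv_threshold,
    nodal_short_axis_threshold_cm = nodal_short_axis_threshold_cm,
    rule_order = c("R0_post_irradiation",
                   "R1a_uip_honeycombing", "R1b_chronic_hp",
                   "R1c_fibrosing_nsip",
                   "R2a_post_tb", "R2b_sarcoidosis", "R2c_pmf", "R2d_ppfe",
                   "R3_indeterminate")),
    class = "classifier_config")
}

tri_true <- function(record, field) identical(record[[field]], "true")

#' Classify a single patient record
#'
#' Evaluates the ordered diagnostic rules and returns a full trace: every
#' rule evaluated, whether it fired, the evidence fields supporting it, the
#' final disease label (or `INDETERMINATE` when no terminal rule matches,
#' e.g. no clear lobar predominance), the malignancy flag, and whether
#' supportive (non-required) findings were present for the fired rule.
#'
#' The malignancy overlay fires on bright T2 signal with DWI restriction, or
#' on SUV above the configured threshold; it is typed by the terminal label
#' (scar carcinoma on post-TB fibrosis, metastasis on post-irradiation
#' fibrosis) and otherwise reported as `NONE` with a note, since the study
#' observed malignant transformation only in those two scarring diseases.
#'
#' @param record A valid patient record (one-row data.frame or named list).
#' @param config A [classifier_config()].
#' @return A `rule_trace` list with elements `steps` (data.frame of rule,
#'   fired, evidence), `final_label`, `fired_rule`, `malignancy`,
#'   `confidence_note` and `note`.
#' @export
classify <- function(record, config = classifier_config()) {
  record <- as.list(record)
  v <- validate_record(record)
  if (length(v) > 0) {
    stop("invalid record '", record$patient_id %||% "?", "': ",
         paste(v, collapse = "; "))
  }
  has <- function(f) isTRUE(record[[f]])
  steps <- data.frame(rule = character(0), fired = logical(0),
                      evidence = character(0), stringsAsFactors = FALSE)
  final <- "INDETERMINATE"
  fired_rule <- "R3_indeterminate"
  supportive <- character(0)
  note <- NA_character_

  add_step <- function(rule, fired, evidence) {
    steps <<- rbind(steps, data.frame(
      rule = rule, fired = fired,
      evidence = paste(evidence, collapse = "+"),
      stringsAsFactors = FALSE))
  }
  terminal <- function(rule, label, evidence, supp = character(0)) {
    add_step(rule, TRUE, evidence)
    final <<- label
    fired_rule <<- rule
    supportive <<- supp
  }

  repeat {
    ## R0: irradiation gate
    if (has("malignancy_irradiation_history") &&
        has("fibrosis_confined_to_radiation_field")) {
      terminal("R0_post_irradiation", "POST_IRRADIATION",
               c("malignancy_irradiation_history",
                 "fibrosis_confined_to_radiation_field"))
      break
    }
    add_step("R0_post_irradiation", FALSE, character(0))

    if (has("lower_lobe_predominance")) {
      ## lower-lobe branch: interstitial pneumonias
      if (has("honeycombing")) {
        terminal("R1a_uip_honeycombing", "UIP_IPF",
                 c("lower_lobe_predominance", "honeycombing"))
        break
      }
      add_step("R1a_uip_honeycombing", FALSE, character(0))
      hp_labs <- c("allergen_exposure"[has("allergen_exposure")],
                   "blood_eosinophilia"[tri_true(record,
                                                 "blood_eosinophilia")],
                   "bal_lymphocytosis"[tri_true(record,
                                                "bal_lymphocytosis")])
      if (has("head_cheese_sign") ||
          (has("crazy_paving") && length(hp_labs) > 0)) {
        ev <- c("lower_lobe_predominance",
                "head_cheese_sign"[has("head_cheese_sign")],
                if (!has("head_cheese_sign")) c("crazy_paving", hp_labs))
        terminal("R1b_chronic_hp", "CHRONIC_HP", ev,
                 supp = if (has("head_cheese_sign")) hp_labs else
                   character(0))
        break
      }
      add_step("R1b_chronic_hp", FALSE, character(0))
      if (has("traction_bronchiectasis") && has("ground_glass") &&
          !has("honeycombing")) {
        terminal("R1c_fibrosing_nsip", "FIBROSING_NSIP",
                 c("lower_lobe_predominance", "traction_bronchiectasis",
                   "ground_glass"),
                 supp = "rheumatologic_history"[has("rheumatologic_history")])
        break
      }
      add_step("R1c_fibrosing_nsip", FALSE, character(0))
    } else if (has("upper_lobe_predominance")) {
      ## upper-lobe branch: scarring diseases
      tb_stigmata <- c(
        "calcific_random_nodules"[has("calcific_random_nodules")],
        "tree_in_bud"[has("tree_in_bud")],
        "cavitation"[has("cavitation")],
        "tuberculin_positive"[tri_true(record, "tuberculin_positive")])
      if (has("peripheral_subpleural") && length(tb_stigmata) > 0) {
        terminal("R2a_post_tb", "POST_TB",
                 c("upper_lobe_predominance", "peripheral_subpleural",
                   tb_stigmata),
                 supp = "smoking_history"[has("smoking_history")])
        break
      }
      add_step("R2a_post_tb", FALSE, character(0))
      if (has("peribronchovascular") && has("perilymphatic_nodules")) {
        terminal("R2b_sarcoidosis", "SARCOIDOSIS",
                 c("upper_lobe_predominance", "peribronchovascular",
                   "perilymphatic_nodules"),
                 supp = c("skin_erythema"[has("skin_erythema")],
                          "arthralgia"[has("arthralgia")],
                          "lymphadenopathy_gt_1cm"[
                            has("lymphadenopathy_gt_1cm")]))
        break
      }
      add_step("R2b_sarcoidosis", FALSE, character(0))
      if (has("peribronchovascular") && has("occupational_dust_exposure")) {
        terminal("R2c_pmf", "PMF",
                 c("upper_lobe_predominance", "peribronchovascular",
                   "occupational_dust_exposure"),
                 supp = "consolidation_calcification"[
                   has("consolidation_calcification")])
        break
      }
      add_step("R2c_pmf", FALSE, character(0))
      if (has("peripheral_subpleural") && has("platy_thorax")) {
        terminal("R2d_ppfe", "PPFE",
                 c("upper_lobe_predominance", "peripheral_subpleural",
                   "platy_thorax"),
                 supp = "rapidly_progressive_course"[
                   identical(record$course, "rapidly_progressive")])
        break
      }
      add_step("R2d_ppfe", FALSE, character(0))
    }
    add_step("R3_indeterminate", TRUE, character(0))
    break
  }

  ## malignancy overlay, independent of the terminal rule
  mri_triad <- tri_true(record, "t2_hyperintense") &&
    tri_true(record, "dwi_restriction")
  suv_high <- is.numeric(record$suv_max) && !is.na(record$suv_max) &&
    record$suv_max > config$suv_threshold
  malignancy <- "NONE"
  if (mri_triad || suv_high) {
    if (final == "POST_TB") {
      malignancy <- "SCAR_CARCINOMA"
    } else if (final == "POST_IRRADIATION") {
      malignancy <- "METASTASIS"
    } else {
      note <- paste("malignancy predictors present but final label is",
                    final, "- no malignancy type assigned")
    }
  }

  structure(list(
    steps = steps,
    final_label = final,
    fired_rule = fired_rule,
    malignancy = malignancy,
    confidence_note = if (length(supportive) > 0) {
      "required_plus_supportive"
    } else "required_only",
    supportive = supportive,
    note = note), class = "rule_trace")
}

#' Classify every record of a cohort
#'
#' Element-wise [classify()], order preserved and fully deterministic.
#'
#' @param cohort Data.frame of valid patient records.
#' @param config A [classifier_config()].
#' @return Data.frame with one row per patient (`patient_id`,
#'   `predicted_label`, `predicted_malignancy`, `fired_rule`,
#'   `confidence_note`); the full per-patient `rule_trace` objects are
#'   attached as the `"traces"` attribute.
#' @export
classify_cohort <- function(cohort, config = classifier_config()) {
  traces <- lapply(seq_len(nrow(cohort)), function(i) {
    classify(cohort[i, , drop = FALSE], config)
  })
  out <- data.frame(
    patient_id = as.character(cohort$patient_id),
    predicted_label = vapply(traces, `[[`, "", "final_label"),
    predicted_malignancy = vapply(traces, `[[`, "", "malignancy"),
    fired_rule = vapply(traces, `[[`, "", "fired_rule"),
    confidence_note = vapply(traces, `[[`, "", "confidence_note"),
    stringsAsFactors = FALSE)
  attr(out, "traces") <- traces
  out
}
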