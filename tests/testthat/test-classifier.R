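test_that("each canonical disease presentation classifies to its own label", {
  recs <- canonical_records()
  for (label in names(recs)) {
    trace <- classify(recs[[label]])
    expect_identical(trace$final_label, label)
    expect_identical(trace$malignancy, "NONE")
  }
})

test_that("records without rule evidence are indeterminate, not guessed", {
  trace <- classify(patient_record("P-none"))
  expect_identical(trace$final_label, "INDETERMINATE")
  expect_identical(trace$fired_rule, "R3_indeterminate")
  ## lower-lobe fibrosis with no discriminating pattern is also routed out
  trace <- classify(patient_record("P-lower", lower_lobe_predominance = TRUE))
  expect_identical(trace$final_label, "INDETERMINATE")
})

test_that("the documented atypical presentations misclassify as in the study", {
  ## true HP without head-cheese/crazy-paving but with basal traction
  ## bronchiectasis and ground glass reads as fibrosing NSIP
  hp_like_nsip <- patient_record("A1", lower_lobe_predominance = TRUE,
    ground_glass = TRUE, air_trapping = TRUE,
    traction_bronchiectasis = TRUE, blood_eosinophilia = "false")
  expect_identical(classify(hp_like_nsip)$final_label, "FIBROSING_NSIP")

  ## true NSIP with a head-cheese sign reads as chronic HP
  nsip_like_hp <- canonical_records()$FIBROSING_NSIP
  nsip_like_hp$head_cheese_sign <- TRUE
  expect_identical(classify(nsip_like_hp)$final_label, "CHRONIC_HP")

  ## true post-TB with platy-thorax and no TB stigmata reads as PPFE
  tb_like_ppfe <- patient_record("A3", upper_lobe_predominance = TRUE,
    peripheral_subpleural = TRUE, air_trapping = TRUE, platy_thorax = TRUE,
    tuberculin_positive = "not_done")
  expect_identical(classify(tb_like_ppfe)$final_label, "PPFE")
})

test_that("rule order privileges irradiation history and TB stigmata", {
  ## irradiation history overrides lobar routing (post-irradiation fibrosis
  ## can be lower-lobe)
  rec <- canonical_records()$UIP_IPF
  rec$malignancy_irradiation_history <- TRUE
  rec$fibrosis_confined_to_radiation_field <- TRUE
  expect_identical(classify(rec)$final_label, "POST_IRRADIATION")
  ## platy-thorax only decides when TB stigmata are absent
  rec <- canonical_records()$POST_TB
  rec$platy_thorax <- TRUE
  expect_identical(classify(rec)$final_label, "POST_TB")
})

test_that("malignancy overlay is typed by the terminal label", {
  tb <- canonical_records()$POST_TB
  tb$t2_hyperintense <- "true"
  tb$dwi_restriction <- "true"
  tb$suv_max <- 8
  expect_identical(classify(tb)$malignancy, "SCAR_CARCINOMA")
  ## either predictor suffices on its own
  tb2 <- canonical_records()$POST_TB
  tb2$suv_max <- 3.5
  expect_identical(classify(tb2)$malignancy, "SCAR_CARCINOMA")
  tb3 <- canonical_records()$POST_TB
  tb3$t2_hyperintense <- "true"
  tb3$dwi_restriction <- "true"
  expect_identical(classify(tb3)$malignancy, "SCAR_CARCINOMA")
  ## at or below the SUV threshold there is no malignancy call
  tb4 <- canonical_records()$POST_TB
  tb4$suv_max <- 3.0
  expect_identical(classify(tb4)$malignancy, "NONE")
  ## configurable threshold
  expect_identical(
    classify(tb2, classifier_config(suv_threshold = 4))$malignancy, "NONE")
  ## metastasis on post-irradiation fibrosis
  irr <- canonical_records()$POST_IRRADIATION
  irr$suv_max <- 5
  expect_identical(classify(irr)$malignancy, "METASTASIS")
  ## predictors on any other disease yield NONE plus an explanatory note
  uip <- canonical_records()$UIP_IPF
  uip$suv_max <- 6
  trace <- classify(uip)
  expect_identical(trace$malignancy, "NONE")
  expect_match(trace$note, "malignancy predictors present")
})

test_that("an unperformed test never counts against a diagnosis", {
  hp <- canonical_records()$CHRONIC_HP
  hp$head_cheese_sign <- FALSE            # rely on crazy-paving + labs route
  hp$blood_eosinophilia <- "not_done"
  hp$bal_lymphocytosis <- "true"
  expect_identical(classify(hp)$final_label, "CHRONIC_HP")
  ## but not_done is never treated as positive evidence either
  hp$bal_lymphocytosis <- "not_done"
  hp$allergen_exposure <- FALSE
  expect_false(classify(hp)$final_label == "CHRONIC_HP")
})

test_that("supportive findings change the confidence note, never the label", {
  supportive <- list(
    rheumatologic_history = canonical_records()$FIBROSING_NSIP,
    skin_erythema = canonical_records()$SARCOIDOSIS,
    arthralgia = canonical_records()$SARCOIDOSIS,
    lymphadenopathy_gt_1cm = canonical_records()$SARCOIDOSIS,
    consolidation_calcification = canonical_records()$PMF,
    smoking_history = canonical_records()$POST_TB)
  for (field in names(supportive)) {
    base <- supportive[[field]]
    base[[field]] <- FALSE
    with_it <- base
    with_it[[field]] <- TRUE
    expect_identical(classify(with_it)$final_label,
                     classify(base)$final_label, label = field)
  }
  ## and across every record of the validation cohort, flipping a purely
  ## supportive field on never changes the predicted label
  cohort <- step2_cohort()
  baseline <- classify_cohort(cohort)$predicted_label
  for (field in c("rheumatologic_history", "skin_erythema", "arthralgia",
                  "consolidation_calcification")) {
    mod <- cohort
    mod[[field]] <- TRUE
    expect_identical(classify_cohort(mod)$predicted_label, baseline,
                     label = field)
  }
  ## the note distinguishes required-only from supported diagnoses
  nsip <- canonical_records()$FIBROSING_NSIP
  expect_identical(classify(nsip)$confidence_note, "required_plus_supportive")
  nsip$rheumatologic_history <- FALSE
  expect_identical(classify(nsip)$confidence_note, "required_only")
})

test_that("classification never reads the ground-truth columns", {
  cohort <- step2_cohort()
  stripped <- cohort
  stripped$true_label <- NA_character_
  stripped$true_malignancy <- NA_character_
  a <- classify_cohort(cohort)
  b <- classify_cohort(stripped)
  attr(a, "traces") <- NULL
  attr(b, "traces") <- NULL
  expect_identical(a, b)
})

test_that("cohort classification is deterministic, ordered and validating", {
  cohort <- step2_cohort()
  a <- classify_cohort(cohort)
  b <- classify_cohort(cohort)
  expect_identical(a$predicted_label, b$predicted_label)
  expect_identical(a$patient_id, cohort$patient_id)
  expect_identical(nrow(classify_cohort(cohort[0, ])), 0L)
  ## exactly one terminal rule per record
  traces <- attr(a, "traces")
  fired <- vapply(traces, function(t) sum(t$steps$fired), 0L)
  expect_true(all(fired == 1))
  ## invalid records are refused with the patient named
  bad <- cohort
  bad$age_years[5] <- 8L
  expect_error(classify_cohort(bad), cohort$patient_id[5])
})
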