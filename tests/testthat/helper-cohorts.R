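# Shared fixtures: the two built-in study cohorts are deterministic in
# exact-counts mode, so they are generated once per test run.

step1_cohort <- function() {
  if (is.null(.fixture_env$step1)) {
    .fixture_env$step1 <- generate_cohort(builtin_step1_spec())
  }
  .fixture_env$step1
}

step2_cohort <- function() {
  if (is.null(.fixture_env$step2)) {
    .fixture_env$step2 <- generate_cohort(builtin_step2_spec())
  }
  .fixture_env$step2
}

.fixture_env <- new.env(parent = emptyenv())

# Canonical single-record presentations of the eight diseases, mirroring the
# generator's fixed profiles (required rule evidence only).
canonical_records <- function() {
  list(
    UIP_IPF = patient_record("C-UIP", lower_lobe_predominance = TRUE,
      peripheral_subpleural = TRUE, ground_glass = TRUE,
      traction_bronchiectasis = TRUE, honeycombing = TRUE),
    FIBROSING_NSIP = patient_record("C-NSIP", lower_lobe_predominance = TRUE,
      peripheral_subpleural = TRUE, ground_glass = TRUE,
      traction_bronchiectasis = TRUE, rheumatologic_history = TRUE),
    CHRONIC_HP = patient_record("C-HP", lower_lobe_predominance = TRUE,
      peribronchovascular = TRUE, ground_glass = TRUE, air_trapping = TRUE,
      head_cheese_sign = TRUE, crazy_paving = TRUE, allergen_exposure = TRUE,
      blood_eosinophilia = "true", bal_lymphocytosis = "true"),
    PPFE = patient_record("C-PPFE", course = "rapidly_progressive",
      upper_lobe_predominance = TRUE, peripheral_subpleural = TRUE,
      consolidation_calcification = TRUE, platy_thorax = TRUE),
    POST_TB = patient_record("C-TB", upper_lobe_predominance = TRUE,
      peripheral_subpleural = TRUE, air_trapping = TRUE,
      traction_bronchiectasis = TRUE, calcific_random_nodules = TRUE,
      consolidation_calcification = TRUE, lymphadenopathy_gt_1cm = TRUE,
      smoking_history = TRUE),
    POST_IRRADIATION = patient_record("C-IRR",
      malignancy_irradiation_history = TRUE,
      fibrosis_confined_to_radiation_field = TRUE,
      upper_lobe_predominance = TRUE, peripheral_subpleural = TRUE,
      ground_glass = TRUE),
    SARCOIDOSIS = patient_record("C-SARC", upper_lobe_predominance = TRUE,
      peribronchovascular = TRUE, perilymphatic_nodules = TRUE,
      consolidation_calcification = TRUE, lymphadenopathy_gt_1cm = TRUE,
      skin_erythema = TRUE, arthralgia = TRUE),
    PMF = patient_record("C-PMF", upper_lobe_predominance = TRUE,
      peribronchovascular = TRUE, air_trapping = TRUE,
      occupational_dust_exposure = TRUE,
      consolidation_calcification = TRUE)
  )
}

# Exact binomial-test inversion: an oracle for the Clopper-Pearson interval
# that never touches qbeta. The lower bound is the p solving
# P(X >= s | n, p) = alpha/2, the upper the p solving P(X <= s | n, p) =
# alpha/2, found by root bisection on the exact binomial tails.
ci_by_test_inversion <- function(s, n, confidence = 0.95) {
  alpha <- 1 - confidence
  lower <- if (s == 0) 0 else {
    stats::uniroot(function(p) stats::pbinom(s - 1, n, p,
                                             lower.tail = FALSE) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-9)$root
  }
  upper <- if (s == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(s, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-9)$root
  }
  c(lower, upper)
}
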