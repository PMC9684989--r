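test_that("2x2 chi-square matches its closed form and handles degeneracy", {
  ## perfectly discriminating feature: statistic equals the cohort size
  res <- chi_square_2x2(34, 0, 0, 116)
  expect_equal(res$statistic, 150)
  expect_lt(res$p_value, 0.001)
  ## smoking-vs-post-TB counts
  res <- chi_square_2x2(16, 5, 32, 97)
  expect_equal(res$statistic, 21.914, tolerance = 1e-4)
  expect_lt(res$p_value, 0.001)
  ## independence
  res <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  ## zero margin: not applicable, not an exception
  res <- chi_square_2x2(0, 0, 12, 30)
  expect_true(is.na(res$statistic) && is.na(res$p_value))
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(11)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    mine <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    mine_y <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                             correction = "yates")
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(mine_y$statistic, unname(ref_y$statistic), tolerance = 1e-10)
    ## Yates never exceeds the uncorrected statistic
    expect_lte(mine_y$statistic, mine$statistic)
    ## invariance under simultaneous row and column swap
    swapped <- chi_square_2x2(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1])
    expect_equal(swapped$statistic, mine$statistic, tolerance = 1e-12)
  }
})

test_that("p decreases as the association strengthens at fixed margins", {
  ## shifting k units along the diagonal keeps all margins fixed
  p <- vapply(0:5, function(k) {
    chi_square_2x2(10 + k, 10 - k, 10 - k, 10 + k)$p_value
  }, 0)
  expect_true(all(diff(p) < 0))
})

test_that("prevalence table counts positives over the disease denominator", {
  tab <- prevalence_table(step1_cohort())
  g <- function(d, f) tab[tab$disease == d & tab$feature == f, ]
  hc <- g("UIP_IPF", "honeycombing")
  expect_identical(as.integer(hc$count), 34L)
  expect_equal(hc$percent, 100)
  al <- g("CHRONIC_HP", "allergen_exposure")
  expect_identical(as.integer(al$count), 13L)
  expect_equal(al$percent, 81.2)
  ## tri-state: not_done contributes to the denominator, not the numerator
  bal <- g("UIP_IPF", "bal_lymphocytosis")
  expect_identical(as.integer(bal$count), 0L)
  expect_identical(as.integer(bal$n_disease), 34L)
  ## a feature absent everywhere is 0% for every disease
  expect_true(all(tab$count[tab$feature == "serum_ige_elevated"] == 0))

  unlabeled <- step1_cohort()
  unlabeled$true_label[3] <- NA
  expect_error(prevalence_table(unlabeled), unlabeled$patient_id[3])
})

test_that("one-vs-rest significance reproduces the published p-values", {
  sig <- significance_table(step1_cohort())
  g <- function(d, f) sig[sig$disease == d & sig$feature == f, ]
  ## cells printed with explicit p-values, recomputed to the printed
  ## precision from the printed counts
  cases <- list(
    list("UIP_IPF", "peripheral_subpleural", 0.007, 3),
    list("UIP_IPF", "air_trapping", 0.004, 3),
    list("FIBROSING_NSIP", "peripheral_subpleural", 0.06, 2),
    list("FIBROSING_NSIP", "peribronchovascular", 0.08, 2),
    list("FIBROSING_NSIP", "head_cheese_sign", 0.66, 2),
    list("FIBROSING_NSIP", "air_trapping", 0.72, 2),
    list("FIBROSING_NSIP", "traction_bronchiectasis", 0.001, 3),
    list("FIBROSING_NSIP", "pulmonary_hypertension", 0.049, 3),
    list("CHRONIC_HP", "pulmonary_hypertension", 0.6, 1),
    list("SARCOIDOSIS", "pulmonary_hypertension", 0.6, 1),
    list("PPFE", "upper_lobe_predominance", 0.17, 2),
    list("PPFE", "peripheral_subpleural", 0.57, 2),
    list("PMF", "peripheral_subpleural", 0.678, 3),
    list("PMF", "air_trapping", 0.001, 3),
    list("PMF", "lymphadenopathy_gt_1cm", 0.058, 3),
    list("PMF", "calcific_random_nodules", 0.051, 3),
    list("POST_TB", "peribronchovascular", 0.215, 3),
    list("POST_TB", "peripheral_subpleural", 0.046, 3),
    list("POST_IRRADIATION", "calcific_random_nodules", 0.93, 2),
    list("SARCOIDOSIS", "traction_bronchiectasis", 0.006, 3))
  for (cs in cases) {
    cell <- g(cs[[1]], cs[[2]])
    ## agree with the printed value to (3/4 of) its printed precision
    expect_lt(abs(cell$p_value - cs[[3]]), 0.75 * 10^(-cs[[4]]),
              label = paste(cs[[1]], cs[[2]], "recomputed p"))
  }
  ## significance flag is p < 0.05
  expect_true(g("UIP_IPF", "honeycombing")$significant)
  expect_false(g("CHRONIC_HP", "pulmonary_hypertension")$significant)
})

test_that("untestable cells are reported as not applicable", {
  sig <- significance_table(step1_cohort())
  g <- function(d, f) sig[sig$disease == d & sig$feature == f, ]
  ## BAL never performed outside chronic HP: N/A there, tested for HP
  expect_true(is.na(g("UIP_IPF", "bal_lymphocytosis")$p_value))
  expect_true(is.na(g("POST_TB", "bal_lymphocytosis")$p_value))
  expect_true(g("CHRONIC_HP", "bal_lymphocytosis")$significant)
  ## feature constant across the whole cohort: zero margin
  expect_true(all(is.na(sig$p_value[sig$feature == "serum_ige_elevated"])))
})

test_that("multiple-testing adjustment is available but off by default", {
  sig <- significance_table(step2_cohort())
  adj <- significance_table(step2_cohort(), adjust = "bonferroni")
  expect_true(all(adj$p_value >= sig$p_value, na.rm = TRUE))
  expect_lte(sum(adj$significant, na.rm = TRUE),
             sum(sig$significant, na.rm = TRUE))
})
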