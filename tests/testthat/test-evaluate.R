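test_that("spearman_rho equals the brute-force oracle on tie patterns", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1.0)
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))

  patterns <- list(
    list(x = c(1, 2, 2, 3), y = c(1, 3, 2, 4)),
    list(x = c(1, 1, 2), y = c(2, 2, 2.5)),
    list(x = c(5, 5, 5, 1, 2), y = c(1, 2, 3, 4, 5)),
    list(x = c(1, 2, 3, 4, 4, 4), y = c(2, 2, 1, 5, 5, 3)),
    list(x = c(0, 0, 1, 1, 2, 2), y = c(2, 1, 2, 1, 2, 1)),
    list(x = c(3, 1, 4, 1, 5), y = c(9, 2, 6, 5, 3)),
    list(x = c(1, 2, 3, 3), y = c(3, 3, 1, 2))
  )
  for (p in patterns) {
    expect_equal(spearman_rho(p$x, p$y), spearman_bruteforce(p$x, p$y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(p$x, p$y),
                 cor(p$x, p$y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("deviation summaries aggregate the absolute grade differences", {
  pred <- tibble::tibble(patient_id = c("A", "B", "C"), cycle = 2L,
                         analyte = "ANC", grade = c(3L, 2L, 4L))
  obs <- tibble::tibble(patient_id = c("A", "B", "C"), cycle = 2L,
                        analyte = "ANC", grade = c(2L, 2L, 2L))
  d <- deviation_summary(pred, obs)
  expect_equal(d$mean_abs_dev, 1.0)
  expect_equal(d$se, sd(c(1, 0, 2)) / sqrt(3))
  expect_equal(d$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(d$n, 3L)

  same <- deviation_summary(obs, obs)
  expect_equal(same$mean_abs_dev, 0)
  expect_equal(same$se, 0)

  # intersection rule: keys missing on one side are dropped
  pred5 <- rbind(pred, tibble::tibble(patient_id = "A", cycle = 5L,
                                      analyte = "ANC", grade = 1L))
  d5 <- deviation_summary(pred5, obs)
  expect_false(5 %in% d5$cycle)

  # invariant to patient order and to non-overlapping additions
  perm <- pred[c(3, 1, 2), ]
  expect_equal(deviation_summary(perm, obs)$mean_abs_dev, d$mean_abs_dev)
  extra <- rbind(obs, tibble::tibble(patient_id = "Z", cycle = 9L,
                                     analyte = "PLT", grade = 4L))
  expect_equal(deviation_summary(pred, extra)$mean_abs_dev, d$mean_abs_dev)

  expect_warning(
    deviation_summary(pred, tibble::tibble(patient_id = "Q", cycle = 3L,
                                           analyte = "WBC", grade = 1L))
  )
})

test_that("cycle 1 is flagged fitted-only in deviation summaries", {
  pred <- tibble::tibble(patient_id = "A", cycle = c(1L, 2L),
                         analyte = "PLT", grade = c(1L, 2L))
  obs <- pred
  d <- deviation_summary(pred, obs)
  expect_equal(d$fitted_only, c(TRUE, FALSE))
})

test_that("predicted grades reproduce a noise-free patient's observed grades", {
  nf <- noisefree_patient()
  observed <- grade_per_cycle(nf$observations, n_cycles = 4)
  predicted <- predict_grades(nf$truth, regimen = "FLOT", bsa = 1.8,
                              cycles = 1:4, n_cycles = 4,
                              params = pop_params())
  j <- dplyr::inner_join(observed, predicted, by = c("cycle", "analyte"),
                         suffix = c("_obs", "_pred"))
  expect_equal(nrow(j), 12)
  expect_equal(j$grade_obs, j$grade_pred)
  expect_equal(j$nadir_value_obs, j$nadir_value_pred, tolerance = 1e-6)
})

test_that("degenerate prediction inputs behave as contracted", {
  none <- predict_grades(c(b_S_act = 1), regimen = "FLOT", bsa = 1.8,
                         cycles = integer(0), params = pop_params())
  expect_equal(nrow(none), 0)

  benign <- predict_grades(c(PD_oxali = 0, PD_5FU = 0, PD_doc = 0),
                           regimen = "FLOT", bsa = 2.0, cycles = 2:4,
                           params = pop_params())
  expect_true(all(benign$grade == 0))
})

test_that("doubling fitted kill coefficients never lowers predicted grades", {
  withr::with_seed(31, {
    for (i in 1:10) {
      theta <- c(PD_oxali = exp(rnorm(1, 0, 0.2)),
                 PD_5FU = 0.35 * exp(rnorm(1, 0, 0.2)),
                 PD_doc = 0.4 * exp(rnorm(1, 0, 0.2)))
      g1 <- predict_grades(theta, regimen = "FLOT", bsa = 1.8, cycles = 2:4,
                           params = pop_params())
      g2 <- predict_grades(theta * 2, regimen = "FLOT", bsa = 1.8,
                           cycles = 2:4, params = pop_params())
      j <- dplyr::inner_join(g1, g2, by = c("cycle", "analyte"),
                             suffix = c("_1", "_2"))
      expect_true(all(j$grade_2 >= j$grade_1))
    }
  })
})

test_that("the covariate screen recovers a planted BSA association", {
  coh <- sample_cohort(cohort_config(n_patients = 30, noise_cv = 0,
                                     regimen_mix = c(FLO_mFOLFOX = 1),
                                     plant_bsa_effect = TRUE, seed = 13))
  estimates <- dplyr::rename(coh$truth, estimate = "value")
  scr <- covariate_screen(estimates, coh$patients)
  planted <- scr[scr$parameter == "b_S_act" & scr$covariate == "BSA", ]
  expect_gt(planted$rho, 0.8)
  expect_equal(planted$n, 30L)
  expect_lt(planted$p_value, 0.01)
})

test_that("the covariate screen stays near zero without planted signal", {
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 30
      est <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                            parameter = "b_S_act",
                            estimate = exp(rnorm(n, 0, 0.3)))
      cov <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                            age = runif(n, 43, 83), BMI = runif(n, 18, 45),
                            BSA = rnorm(n, 1.85, 0.18))
    })
    scr <- covariate_screen(est, cov)
    total <- total + nrow(scr)
    hits <- hits + sum(abs(scr$rho) < 0.5)
  }
  expect_gte(hits / total, 0.95)
})

test_that("the covariate screen requires at least three patients", {
  est <- tibble::tibble(patient_id = c("A", "B"), parameter = "b_S_act",
                        estimate = c(1, 2))
  cov <- tibble::tibble(patient_id = c("A", "B"), age = c(50, 60),
                        BMI = c(25, 30), BSA = c(1.7, 1.9))
  expect_error(covariate_screen(est, cov), class = "hematotox_data_error")
})

test_that("adverse-event tabulation counts worst grades and fractions", {
  wg <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:6),
    regimen = c("FLOT", "FLOT", "FLOT", "FLOT", "FOLFIRINOX", "FOLFIRINOX"),
    analyte = "ANC",
    worst_grade = c(0L, 2L, 3L, 4L, 4L, 1L)
  )
  ae <- summarize_adverse_events(wg)
  flot <- ae[ae$regimen == "FLOT", ]
  expect_equal(flot$grade2, 1L)
  expect_equal(flot$high_grade_n, 2L)
  expect_equal(flot$high_grade_frac, 0.5)
  overall <- ae[ae$regimen == "overall", ]
  expect_equal(overall$high_grade_frac, 3 / 6)

  zeros <- summarize_adverse_events(
    tibble::tibble(patient_id = "A", regimen = "FLOT", analyte = "PLT",
                   worst_grade = 0L)
  )
  expect_equal(zeros$high_grade_frac, c(0, 0))
  expect_equal(sum(zeros$grade1 + zeros$grade2 + zeros$grade3 + zeros$grade4), 0L)
})
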