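test_that("steady state is an exact fixed point with configured normals", {
  p <- pop_params()
  ss <- steady_state(p)
  dy <- hematotox:::model_derivatives(p, ss)
  expect_lt(max(abs(dy)), 1e-8)
  expect_equal(unname(ss["ANC"]), 3.0)
  expect_equal(sum(ss[paste0("P", 1:10)]), 250)
  expect_equal(unname(ss["ANC"] + ss["LYM"] + ss["MON"]), 5.5)

  bad <- p
  bad$individual$w_PLC <- -1
  expect_error(steady_state(bad))
})

test_that("drug-free simulation stays at homeostasis for a year", {
  tr <- simulate_hematopoiesis(pop_params(), NULL, seq(0, 365, by = 1))
  expect_lt(max(abs(tr$ANC / 3 - 1)), 1e-3)
  expect_lt(max(abs(tr$PLT / 250 - 1)), 1e-3)
  expect_lt(max(abs(tr$WBC / 5.5 - 1)), 1e-3)
})

test_that("perturbed counts return to steady state within 120 days", {
  p <- pop_params()
  for (dir in c(0.8, 1.2)) {
    y <- steady_state(p)
    y["ANC"] <- y["ANC"] * dir
    y[paste0("P", 1:10)] <- y[paste0("P", 1:10)] * dir
    tr <- simulate_hematopoiesis(p, NULL, seq(0, 120, by = 1), init = y)
    last <- tr[nrow(tr), ]
    expect_lt(abs(last$ANC / 3 - 1), 0.01)
    expect_lt(abs(last$PLT / 250 - 1), 0.01)
  }
})

test_that("G-CSF regulation is normalized, clamped and monotone", {
  expect_equal(regulation_gcsf(1, b = 2.7), 1)
  expect_equal(regulation_gcsf(c(0.1, 2, 7), b = 0), rep(1, 3))
  expect_equal(regulation_gcsf(4, b = 1, z_min = 0.2, z_max = 5), 4)
  expect_equal(regulation_gcsf(4, b = 2, z_min = 0.2, z_max = 5), 5)
  expect_equal(regulation_gcsf(0.01, b = 2, z_min = 0.2, z_max = 5), 0.2)
  g <- seq(0, 6, by = 0.05)
  for (b in c(0.3, 1, 2)) {
    vals <- regulation_gcsf(g, b)
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0.1 & vals <= 10))
  }
})

test_that("TPO stimulation is biphasic with an interior maximum", {
  expect_equal(stimulation_tpo_biphasic(1, h = 2, s = 1), 1)
  expect_equal(stimulation_tpo_biphasic(1, h = 3.3, s = 0.4), 1)
  expect_equal(stimulation_tpo_biphasic(0, h = 2, s = 1), 0)
  expect_equal(stimulation_tpo_biphasic(10, h = 2, s = 1), 200 / 10001,
               tolerance = 1e-12)
  # interior maximum for the model's default shape
  p <- pop_params()
  h <- p$constants$h_TPO; s <- p$constants$s_TPO
  u_star <- s^(-1 / (2 * h))
  f <- function(u) stimulation_tpo_biphasic(u, h, s)
  expect_gt(f(u_star), f(u_star * 10))
  expect_gt(f(u_star), f(u_star / 10))
  expect_gt(u_star, 1)
})

test_that("chemotherapy kill is linear and additive across drugs", {
  p <- pop_params()
  none <- chemo_kill(c(oxaliplatin = 0, fluorouracil = 0), p)
  expect_equal(unname(none), rep(0, length(none)))

  p05 <- default_parameters(list(PD_oxali = 0.5, PD_5FU = 1.0))
  one <- chemo_kill(c(oxaliplatin = 2), p05)
  expect_equal(unname(one["CMP"]), 1.0)
  both <- chemo_kill(c(oxaliplatin = 2, fluorouracil = 3), p05)
  sep <- chemo_kill(c(oxaliplatin = 2), p05) +
    chemo_kill(c(fluorouracil = 3), p05)
  expect_equal(both, sep)
  expect_equal(unname(both["CMP"]), 4.0)
  expect_error(chemo_kill(c(aspirin = 1), p))
})

test_that("one FLOT cycle produces a mid-cycle ANC nadir with recovery", {
  p <- pop_params()
  ev <- build_dosing_events("FLOT", 1.8, 1)
  tr <- simulate_hematopoiesis(p, ev, seq(0, 28, by = 0.25))
  expect_lt(min(tr$ANC), 3.0)
  t_min <- tr$time[which.min(tr$ANC)]
  expect_gte(t_min, 3)
  expect_lte(t_min, 14)
  expect_gte(tr$ANC[tr$time == 28], 0.9 * 3.0)
})

test_that("doubling kill coefficients never shallows the cycle nadir", {
  p <- pop_params()
  ev <- build_dosing_events("FLOT", 1.8, 1)
  grid <- seq(0, 14, by = 0.25)
  base <- simulate_hematopoiesis(p, ev, grid)
  p2 <- default_parameters(list(PD_oxali = 2, PD_5FU = 0.7, PD_doc = 0.8))
  doubled <- simulate_hematopoiesis(p2, ev, grid)
  expect_lte(min(doubled$ANC), min(base$ANC))
  expect_lte(min(doubled$PLT), min(base$PLT))
})

test_that("raising G-CSF sensitivities never deepens the ANC nadir", {
  withr::with_seed(42, {
    ev <- build_dosing_events("FLOT", 1.8, 1)
    grid <- seq(0, 14, by = 0.5)
    for (i in 1:10) {
      theta <- c(b_S_act = exp(rnorm(1, 0, 0.25)),
                 b_A_CM = exp(rnorm(1, 0, 0.25)))
      p_lo <- set_individual(pop_params(), theta)
      up <- sample(c("b_S_act", "b_A_CM"), 1)
      theta_hi <- theta
      theta_hi[up] <- theta[up] * 1.5
      p_hi <- set_individual(pop_params(), theta_hi)
      nad_lo <- min(simulate_hematopoiesis(p_lo, ev, grid)$ANC)
      nad_hi <- min(simulate_hematopoiesis(p_hi, ev, grid)$ANC)
      expect_gte(nad_hi, nad_lo - 1e-9)
    }
  })
})

test_that("state stays non-negative under random parameters and schedules", {
  withr::with_seed(7, {
    for (i in 1:100) {
      theta <- exp(rnorm(9, 0, 0.3)) *
        unlist(pop_params()$individual[hematotox:::INDIVIDUAL_PARAMS])
      names(theta) <- hematotox:::INDIVIDUAL_PARAMS
      p_i <- set_individual(pop_params(), theta)
      reg <- sample(c("FLOT", "FLO_mFOLFOX", "FOLFIRINOX"), 1)
      ev <- build_dosing_events(reg, runif(1, 1.5, 2.2), 1)
      tr <- simulate_hematopoiesis(p_i, ev, seq(0, 14, by = 1), full = TRUE)
      expect_gt(min(attr(tr, "state")), -1e-9)
    }
  })
})

test_that("repeated cycles erode the pre-cycle platelet baseline", {
  ev <- build_dosing_events("FLOT", 1.8, 4)
  tr <- simulate_hematopoiesis(pop_params(), ev, seq(0, 56, by = 1))
  pre <- tr$PLT[match(c(0, 14, 28, 42), tr$time)]
  expect_true(all(diff(pre) <= 1e-6))
})

test_that("platelet survival shows the Erlang shoulder, matching the closed form", {
  p <- pop_params()
  tau <- p$constants$tau_PLT
  grid <- seq(0, 2 * tau, by = 0.25)
  surv <- platelet_survival(p, grid)
  expect_gt(surv$survival[surv$time == 0.5 * tau], exp(-0.5))
  # fresh-cohort Erlang-10 survival closed form
  k_e <- 10 / tau
  oracle <- 1 - pgamma(grid, shape = 10, rate = k_e)
  expect_equal(surv$survival, oracle, tolerance = 1e-6)
})

test_that("simulation input validation catches bad grids and drugs", {
  p <- pop_params()
  expect_error(simulate_hematopoiesis(p, NULL, c(0, 0, 1)),
               class = "hematotox_input_error")
  ev <- tibble::tibble(drug = "aspirin", amount_mg = 1, start = 0,
                       duration = 1, rate = 1, cycle = 1L, inert = FALSE)
  expect_error(simulate_hematopoiesis(p, ev, 0:5),
               class = "hematotox_input_error")
})
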