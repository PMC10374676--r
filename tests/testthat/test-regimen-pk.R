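test_that("regimen definitions carry the expected drug compositions", {
  flot <- regimen_spec("FLOT")
  flo <- regimen_spec("FLO_mFOLFOX")
  ffx <- regimen_spec("FOLFIRINOX")
  expect_equal(flot$cycle_length, 14)
  expect_true("docetaxel" %in% flot$administrations$drug)
  expect_false("docetaxel" %in% flo$administrations$drug)
  expect_true("irinotecan" %in% ffx$administrations$drug)
  fu <- ffx$administrations[ffx$administrations$drug == "fluorouracil", ]
  expect_equal(nrow(fu), 2)  # bolus plus continuous infusion
  expect_true(any(fu$infusion_hours < 1) && any(fu$infusion_hours == 46))
  expect_error(regimen_spec("FOLFOX9000"), class = "hematotox_config_error")
})

test_that("dosing events carry absolute amounts on the study clock", {
  ev <- build_dosing_events("FLOT", bsa = 2.0, n_cycles = 1)
  fu <- ev[ev$drug == "fluorouracil", ]
  expect_equal(fu$amount_mg, 5200)
  expect_equal(fu$start, 0)
  expect_equal(fu$duration, 1.0)
  expect_equal(ev$amount_mg[ev$drug == "oxaliplatin"], 170)
  expect_true(ev$inert[ev$drug == "leucovorin"])
  expect_false(any(ev$inert[ev$drug != "leucovorin"]))

  ev2 <- build_dosing_events("FOLFIRINOX", bsa = 1.8, n_cycles = 2)
  cont <- ev2[ev2$drug == "fluorouracil" & ev2$duration > 1, ]
  expect_equal(cont$amount_mg, c(4320, 4320))
  expect_equal(cont$duration, rep(46 / 24, 2))
  expect_equal(cont$start, c(0, 14))
  expect_false(is.unsorted(ev2$start))
})

test_that("cycle k events are cycle 1 events shifted by the cycle length", {
  ev <- build_dosing_events("FLOT", bsa = 1.7, n_cycles = 3)
  for (k in 2:3) {
    e1 <- ev[ev$cycle == 1, ]
    ek <- ev[ev$cycle == k, ]
    expect_equal(ek$start, e1$start + (k - 1) * 14)
    expect_equal(ek$amount_mg, e1$amount_mg)
  }
})

test_that("invalid dosing inputs are rejected", {
  expect_error(build_dosing_events("FLOT", bsa = 0),
               class = "hematotox_input_error")
  expect_error(build_dosing_events("FLOT", bsa = -1.8),
               class = "hematotox_input_error")
  expect_error(build_dosing_events("NOPE", bsa = 1.8),
               class = "hematotox_config_error")
})

test_that("closed-form bolus solution matches scalar kinetics", {
  pk1 <- make_pk(2, V = 10, k10 = 1, k12 = 0, k21 = 0)
  t <- c(0, 0.5, 1, 2, 5)
  sol <- pk_closed_form(pk1, 100, t)
  expect_equal(sol$conc, 10 * exp(-t), tolerance = 1e-10)
  expect_equal(sol$A2, rep(0, length(t)), tolerance = 1e-10)
  zero <- pk_closed_form(pk_model("oxaliplatin"), 0, t)
  expect_equal(unlist(zero[, c("A1", "A2", "A3")]), rep(0, 15),
               ignore_attr = TRUE)
})

test_that("numeric PK integration agrees with the matrix-exponential oracle", {
  t_grid <- seq(0, 7, length.out = 50)
  for (drug in c("oxaliplatin", "fluorouracil", "irinotecan")) {
    pk <- pk_model(drug)
    # effectively-bolus event (1-minute infusion)
    ev <- tibble::tibble(drug = drug, amount_mg = 150, start = 0,
                         duration = 1 / 1440, rate = 150 * 1440,
                         cycle = 1L, inert = FALSE)
    num <- pk_concentration(pk, ev, t_grid, rtol = 1e-11, atol = 1e-13)
    oracle <- pk_infusion_oracle(pk, ev, t_grid)
    # relative to the curve scale: tail values below 1e-6 of Cmax carry no
    # meaningful relative precision
    rel <- abs(num$conc - oracle) / pmax(abs(oracle), 1e-6 * max(oracle))
    expect_lt(max(rel[-1]), 1e-6)

    # 2-hour infusion
    ev2 <- tibble::tibble(drug = drug, amount_mg = 150, start = 0.5,
                          duration = 2 / 24, rate = 150 * 12, cycle = 1L,
                          inert = FALSE)
    num2 <- pk_concentration(pk, ev2, t_grid, rtol = 1e-11, atol = 1e-13)
    oracle2 <- pk_infusion_oracle(pk, ev2, t_grid)
    rel2 <- abs(num2$conc - oracle2) / pmax(abs(oracle2), 1e-6 * max(oracle2))
    expect_lt(max(rel2, na.rm = TRUE), 1e-6)
  }
})

test_that("two independent solvers agree for a 2-compartment bolus", {
  pk <- pk_model("fluorouracil")
  M <- hematotox:::pk_matrix(pk)
  t <- c(0, 0.1, 0.25, 0.5)
  num <- deSolve::lsoda(
    y = c(1000, 0), times = t,
    func = function(tt, y, p) list(M %*% y),
    rtol = 1e-12, atol = 1e-14
  )
  cf <- pk_closed_form(pk, 1000, t)
  expect_equal(num[, 2] / pk$central_volume, cf$conc,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(cf$conc[1], 1000 / pk$central_volume)  # C(0) = D/V
  expect_equal(cf$A2[1], 0)
})

test_that("PK is linear: superposition and dose proportionality hold", {
  pk <- pk_model("oxaliplatin")
  t_grid <- seq(0, 10, by = 0.25)
  e1 <- tibble::tibble(drug = "oxaliplatin", amount_mg = 100, start = 0,
                       duration = 2 / 24, rate = 1200, cycle = 1L, inert = FALSE)
  e2 <- tibble::tibble(drug = "oxaliplatin", amount_mg = 50, start = 3,
                       duration = 1 / 24, rate = 1200, cycle = 1L, inert = FALSE)
  both <- pk_concentration(pk, rbind(e1, e2), t_grid)
  sep <- pk_concentration(pk, e1, t_grid)$conc +
    pk_concentration(pk, e2, t_grid)$conc
  expect_equal(both$conc, sep, tolerance = 1e-8)

  twice <- e1
  twice$amount_mg <- 200; twice$rate <- 2400
  expect_equal(pk_concentration(pk, twice, t_grid)$conc,
               2 * pk_concentration(pk, e1, t_grid)$conc, tolerance = 1e-8)

  expect_equal(pk_concentration(pk, e1[0, ], t_grid)$conc,
               rep(0, length(t_grid)))
})

test_that("time-shifting all events shifts the concentration series", {
  pk <- pk_model("irinotecan")
  e <- tibble::tibble(drug = "irinotecan", amount_mg = 300, start = 1,
                      duration = 2 / 24, rate = 3600, cycle = 1L, inert = FALSE)
  t_grid <- seq(0, 12, by = 0.5)
  base <- pk_concentration(pk, e, t_grid)
  sh <- e; sh$start <- e$start + 2
  shifted <- pk_concentration(pk, sh, t_grid + 2)
  expect_equal(shifted$conc, base$conc, tolerance = 1e-8)
})

test_that("central AUC after finite dosing equals dose / (k10 * V)", {
  for (drug in c("oxaliplatin", "fluorouracil", "docetaxel")) {
    pk <- pk_model(drug)
    ev <- tibble::tibble(drug = drug, amount_mg = 200, start = 0,
                         duration = 2 / 24, rate = 2400, cycle = 1L,
                         inert = FALSE)
    horizon <- 80 / min(c(pk$k10, pk$k21, if (pk$n_compartments == 3) pk$k31))
    t_grid <- sort(unique(c(seq(0, 3, by = 0.002), seq(3, 10, by = 0.02),
                            seq(10, horizon, by = 0.25))))
    conc <- pk_concentration(pk, ev, t_grid, rtol = 1e-11, atol = 1e-13)$conc
    auc <- pracma::trapz(t_grid, conc)
    expect_equal(auc, 200 / (pk$k10 * pk$central_volume), tolerance = 1e-3)
  }
})

test_that("events for a different drug are rejected", {
  pk <- pk_model("oxaliplatin")
  ev <- tibble::tibble(drug = "fluorouracil", amount_mg = 100, start = 0,
                       duration = 0.1, rate = 1000, cycle = 1L, inert = FALSE)
  expect_error(pk_concentration(pk, ev, 0:5),
               class = "hematotox_input_error")
  expect_error(pk_concentration(pk, ev[0, ], c(0, 0, 1)),
               class = "hematotox_input_error")  # non-increasing grid
})
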