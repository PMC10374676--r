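#' Scheduled blood-sampling days on the study clock
#'
#' The trial sampling scheme: draws on days 1, 3, 5, 8, 10 and 12 of cycles
#' 1 and 2, and on days 1 and 10 from cycle 3 on. Day `d` of cycle `k` maps
#' to `(k - 1) * cycle_length + (d - 1)` on the study clock (cycle 1 day 1 is
#' time 0).
#'
#' @param n_cycles number of cycles
#' @param cycle_length cycle length in days
#' @return sorted numeric vector of sampling days
#' @examples
#' study_schedule(3)
#' @export
study_schedule <- function(n_cycles, cycle_length = 14) {
  stopifnot(n_cycles >= 1)
  days <- lapply(seq_len(n_cycles), function(k) {
    within <- if (k <= 2) c(0, 2, 4, 7, 9, 11) else c(0, 9)
    (k - 1) * cycle_length + within
  })
  sort(unlist(days))
}

#' Configuration of a synthetic cohort
#'
#' Defines the virtual study population: cohort size, the regimen mix
#' (default mirroring a 28-patient cohort of 20 FLOT / 3 FLO-mFOLFOX /
#' 5 FOLFIRINOX), lognormal between-patient parameter heterogeneity,
#' multiplicative measurement noise, and an optional planted association
#' between body surface area and the stem-cell G-CSF sensitivity `b_S_act`
#' (used to exercise the covariate screen). FLOT and FLO patients receive 4
#' cycles, FOLFIRINOX patients 8.
#'
#' @param n_patients cohort size
#' @param regimen_mix named fractions over regimens (must sum to 1)
#' @param param_cv lognormal coefficient of variation of the individual
#'   parameters around their population centres
#' @param noise_cv multiplicative measurement noise CV
#' @param plant_bsa_effect plant a BSA -> `b_S_act` association
#' @param plant_slope slope of the planted effect on the log scale per
#'   standardized BSA unit
#' @param plant_resid_cv residual CV of the planted parameter
#' @param dropout per-observation missingness probability
#' @param randomize names of the individual parameters given between-patient
#'   heterogeneity (others stay at the population centre)
#' @param seed root seed for cohort generation
#' @return list of class `hematotox_cohort_config`
#' @export
cohort_config <- function(n_patients = 28,
                          regimen_mix = c(FLOT = 20 / 28,
                                          FLO_mFOLFOX = 3 / 28,
                                          FOLFIRINOX = 5 / 28),
                          param_cv = 0.3,
                          noise_cv = 0.15,
                          plant_bsa_effect = FALSE,
                          plant_slope = 0.5,
                          plant_resid_cv = 0.1,
                          dropout = 0,
                          randomize = INDIVIDUAL_PARAMS,
                          seed = 1L) {
  stopifnot(abs(sum(regimen_mix) - 1) < 1e-8, param_cv >= 0, noise_cv >= 0,
            dropout >= 0, dropout < 1,
            all(randomize %in% INDIVIDUAL_PARAMS))
  structure(
    list(n_patients = n_patients, regimen_mix = regimen_mix,
         param_cv = param_cv, noise_cv = noise_cv,
         plant_bsa_effect = plant_bsa_effect, plant_slope = plant_slope,
         plant_resid_cv = plant_resid_cv, dropout = dropout,
         randomize = randomize, seed = as.integer(seed)),
    class = "hematotox_cohort_config"
  )
}

# reference BSA distribution used for standardization of planted effects
BSA_MEAN <- 1.85
BSA_SD <- 0.18

#' Generate a synthetic patient cohort
#'
#' Draws covariates (age 43-83, BMI 17.8-44.9, BSA around 1.85 m2), assigns
#' regimens by largest-remainder apportionment of the configured mix, draws
#' true individual parameters lognormally around the population centres, and
#' simulates noisy scheduled blood counts for every patient. Truth is kept in
#' a separate table so the fitting pipeline can be run blind.
#'
#' @param config `hematotox_cohort_config`
#' @param params population parameters
#' @return object of class `hematotox_cohort`: list of tibbles `patients`
#'   (covariates and regimen), `observations` (patient, time, cycle, analyte,
#'   value) and `truth` (patient, parameter, value)
#' @examples
#' coh <- sample_cohort(cohort_config(n_patients = 2, seed = 7))
#' coh$patients
#' @export
sample_cohort <- function(config = cohort_config(),
                          params = default_parameters()) {
  stopifnot(inherits(config, "hematotox_cohort_config"))
  n <- config$n_patients
  if (n == 0) {
    return(structure(list(patients = tibble::tibble(),
                          observations = tibble::tibble(),
                          truth = tibble::tibble()),
                     class = "hematotox_cohort"))
  }
  withr::with_seed(config$seed, {
    counts <- largest_remainder(config$regimen_mix * n)
    regimens <- rep(names(config$regimen_mix), counts)
    patients <- tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n)),
      age = round(runif(n, 43, 83)),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.71, 0.29)),
      BMI = round(runif(n, 17.8, 44.9), 1),
      BSA = round(pmin(pmax(rnorm(n, BSA_MEAN, BSA_SD), 1.45), 2.35), 2),
      regimen = regimens,
      n_cycles = ifelse(regimens == "FOLFIRINOX", 8L, 4L)
    )

    sdlog <- sqrt(log(1 + config$param_cv^2))
    pop <- unlist(params$individual[INDIVIDUAL_PARAMS])
    truth <- purrr::map_dfr(seq_len(n), function(i) {
      draw <- rnorm(length(pop), 0, sdlog)
      draw[!names(pop) %in% config$randomize] <- 0
      lt <- log(pop) + draw
      if (config$plant_bsa_effect) {
        z <- (patients$BSA[i] - BSA_MEAN) / BSA_SD
        res <- sqrt(log(1 + config$plant_resid_cv^2))
        lt["b_S_act"] <- log(pop[["b_S_act"]]) + config$plant_slope * z +
          rnorm(1, 0, res)
      }
      tibble::tibble(patient_id = patients$patient_id[i],
                     parameter = names(pop), value = exp(unname(lt)))
    })

    obs_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    observations <- purrr::map_dfr(seq_len(n), function(i) {
      theta <- setNames(truth$value[truth$patient_id == patients$patient_id[i]],
                        truth$parameter[truth$patient_id == patients$patient_id[i]])
      p_i <- set_individual(params, theta)
      ev <- build_dosing_events(patients$regimen[i], patients$BSA[i],
                                patients$n_cycles[i])
      sched <- study_schedule(patients$n_cycles[i])
      grid <- sort(unique(c(0, sched, seq(0, max(sched) + 3, by = 1))))
      traj <- simulate_hematopoiesis(p_i, ev, grid)
      obs <- observe(traj, sched, config$noise_cv, seed = obs_seeds[i])
      if (config$dropout > 0) {
        keep <- runif(nrow(obs)) >= config$dropout
        obs <- obs[keep, , drop = FALSE]
      }
      dplyr::mutate(obs, patient_id = patients$patient_id[i], .before = 1)
    })
  })
  structure(list(patients = patients, observations = observations,
                 truth = truth),
            class = "hematotox_cohort")
}

largest_remainder <- function(target) {
  fl <- floor(target)
  rem <- round(sum(target)) - sum(fl)
  add <- order(target - fl, decreasing = TRUE)[seq_len(rem)]
  fl[add] <- fl[add] + 1
  as.integer(fl)
}

#' Sample noisy observations from a simulated trajectory
#'
#' The measurement model is multiplicative lognormal noise with unit mean:
#' `value = model * exp(e - s^2/2)`, `e ~ N(0, s^2)`,
#' `s^2 = log(1 + noise_cv^2)`. With `noise_cv = 0` the model values are
#' reproduced exactly.
#'
#' @param trajectory `hematotox_trajectory`
#' @param schedule sampling days, all of which must lie on the trajectory grid
#' @param noise_cv measurement coefficient of variation
#' @param seed RNG seed for the noise draws
#' @param cycle_length cycle length used to label cycles
#' @return tibble with `time`, `cycle`, `analyte`, `value`
#' @export
observe <- function(trajectory, schedule, noise_cv = 0.15, seed = 1L,
                    cycle_length = 14) {
  off <- setdiff(schedule, trajectory$time)
  if (length(off)) {
    abort(paste0("schedule days not on trajectory grid: ", toString(off)),
          class = "hematotox_input_error")
  }
  idx <- match(schedule, trajectory$time)
  long <- tidyr::pivot_longer(
    trajectory[idx, c("time", "PLT", "ANC", "WBC")],
    cols = c("PLT", "ANC", "WBC"), names_to = "analyte", values_to = "value"
  )
  sdlog <- sqrt(log(1 + noise_cv^2))
  withr::with_seed(seed, {
    noise <- exp(rnorm(nrow(long), 0, sdlog) - sdlog^2 / 2)
  })
  long$value <- pmax(long$value * noise, 1e-6)
  long$cycle <- as.integer(floor(long$time / cycle_length) + 1)
  dplyr::select(long, "time", "cycle", "analyte", "value")
}

# standardized exogenous kill pulse used by the virtual-experiment protocols
KILL_PULSE_RATE <- 2.0  # 1/day
KILL_PULSE_DAYS <- 1.0

kill_pulse_events <- function(rate = KILL_PULSE_RATE,
                              duration = KILL_PULSE_DAYS) {
  tibble::tibble(drug = "xkill", amount_mg = NA_real_, start = 0,
                 duration = duration, rate = rate, cycle = 1L, inert = FALSE)
}

# reference patient for the standard-chemotherapy-cycle protocol; the event
# table is built once per session (it sits inside the optimization loop)
CHEMO_PROTOCOL_BSA <- 1.85

chemo_protocol_events <- function() {
  ev <- .hematotox_cache[["flot_protocol_events"]]
  if (is.null(ev)) {
    ev <- build_dosing_events("FLOT", CHEMO_PROTOCOL_BSA, 1)
    assign("flot_protocol_events", ev, envir = .hematotox_cache)
  }
  ev
}

# model outputs of a virtual-experiment protocol at the requested times
simulate_protocol <- function(params, protocol, observables, times) {
  if (protocol == "drug_free") {
    con <- params$constants
    normals <- c(ANC = con$ANC_nor, PLT = con$PLT_nor,
                 WBC = con$ANC_nor + con$LYM_nor + con$MON_nor,
                 GCSF = 1, TPO = 1)
    return(tidyr::expand_grid(observable = observables, time = times) |>
             dplyr::mutate(value = unname(normals[.data$observable])))
  }
  events <- switch(protocol,
    kill_pulse = kill_pulse_events(),
    flot_cycle = chemo_protocol_events(),
    abort(paste0("unknown protocol: ", protocol))
  )
  grid <- sort(unique(c(0, times)))
  tr <- simulate_hematopoiesis(params, events, grid, full = TRUE)
  st <- attr(tr, "state")
  vals <- list(ANC = tr$ANC, PLT = tr$PLT, WBC = tr$WBC,
               GCSF = st[, "G"], TPO = st[, "T"])
  idx <- match(times, grid)
  purrr::map_dfr(observables, function(ob) {
    tibble::tibble(observable = ob, time = times, value = vals[[ob]][idx])
  })
}

#' Synthetic population virtual-experiment bank
#'
#' Builds a bank of population datasets used as penalty terms in the
#' virtual-participation objective: the recovery of ANC, PLT and G-CSF after
#' a standardized 1-day exogenous kill pulse, and the ANC/PLT/WBC course of
#' a standard FLOT cycle at reference body surface area, all simulated with
#' the population model. The chemotherapy-cycle datasets are what give the
#' per-drug kill coefficients population-level curvature; the pulse datasets
#' inform the cytokine-sensitivity and TPO-clearance parameters through the
#' large regulator excursions they provoke.
#'
#' Standard deviations are `sd_scale` times the individual residual scale on
#' a relative footing, so each population point carries `1/sd_scale^2` of an
#' individual point's weight — considerably smaller per point, while the
#' dense sampling gives the bank a meaningful total weight, mirroring the
#' role of large literature datasets in stabilizing sparse individual fits.
#'
#' @param params population parameters
#' @param seed recorded for provenance (means are noise-free model outputs)
#' @param sd_scale population SD as a multiple of `sigma_ind` on the relative
#'   scale
#' @param sigma_ind individual lognormal residual scale
#' @return tibble with `dataset_id`, `protocol`, `observable`, `time`,
#'   `mean`, `sd`
#' @export
make_virtual_experiments <- function(params = default_parameters(),
                                     seed = 1L, sd_scale = 1.8,
                                     sigma_ind = 0.15) {
  pulse_times <- seq(2, 22, by = 2)
  chemo_times <- seq(1, 13, by = 1)
  spec <- tibble::tibble(
    dataset_id = c("pulse_ANC", "pulse_PLT", "pulse_TPO",
                   "flot_ANC", "flot_PLT", "flot_WBC"),
    protocol = rep(c("kill_pulse", "flot_cycle"), each = 3),
    observable = c("ANC", "PLT", "TPO", "ANC", "PLT", "WBC")
  )
  out <- purrr::pmap_dfr(spec, function(dataset_id, protocol, observable) {
    times <- if (protocol == "kill_pulse") pulse_times else chemo_times
    sim <- simulate_protocol(params, protocol, observable, times)
    tibble::tibble(dataset_id = dataset_id, protocol = protocol,
                   observable = observable, time = times,
                   mean = sim$value, sd = pmax(sd_scale * sigma_ind * sim$value,
                                               1e-3))
  })
  attr(out, "seed") <- as.integer(seed)
  out
}
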