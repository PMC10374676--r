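#' Homeostatic steady state of the hematopoiesis model
#'
#' The model is written in normalized relaxation form, so the drug-free fixed
#' point is the all-normal state: every bone-marrow compartment at 1, blood
#' counts at their configured normal values (`ANC_nor`, `PLT_nor`, ...), the
#' platelet age chain uniformly filled, cytokines at 1, and all PK amounts at
#' zero. The returned state is verified against the compiled right-hand side:
#' the derivative max-norm on normalized scale must be below `1e-8`.
#'
#' @param params `hematotox_params`
#' @return named state vector
#' @export
steady_state <- function(params) {
  validate_parameters(params)
  con <- params$constants
  y <- steady_state_unchecked(params)
  dy <- model_derivatives(params, y)
  scale <- rep(1, 44)
  scale[match(c("ANC", "LYM", "MON"), state_names())] <-
    c(con$ANC_nor, con$LYM_nor, con$MON_nor)
  scale[match(paste0("P", 1:10), state_names())] <- con$PLT_nor / 10
  err <- max(abs(dy / scale))
  if (err >= 1e-8) {
    abort(paste0("steady state did not satisfy the model equations; ",
                 "normalized derivative max-norm = ", format(err)),
          class = "hematotox_numeric_error")
  }
  y
}

# evaluate the compiled right-hand side at a state (drug-free, no inputs)
model_derivatives <- function(params, state, rates = numeric(6)) {
  out <- deSolve::DLLfunc(
    y = unname(state), times = 0, func = "derivs", dllname = "hematotox",
    initfunc = "initmod", parms = param_vector(params, rates)
  )
  as.numeric(out$dy)
}

#' Clamped power-law regulation
#'
#' The feedback functional form used throughout the model:
#' `Z(x) = clamp(x^b, z_min, z_max)`. At the normal regulator level (`x = 1`)
#' it equals 1; `b = 0` switches the feedback off; it is non-decreasing in `x`
#' for `b >= 0`.
#'
#' @param g normalized regulator level (e.g. G-CSF), `>= 0`
#' @param b sensitivity exponent
#' @param z_min,z_max clamp bounds with `z_min <= 1 <= z_max`
#' @return amplification factor in `[z_min, z_max]`
#' @export
regulation_gcsf <- function(g, b, z_min = 0.1, z_max = 10) {
  stopifnot(all(g >= 0), z_min <= 1, 1 <= z_max)
  pmin(pmax(pmax(g, 1e-12)^b, z_min), z_max)
}

#' Biphasic TPO stimulation
#'
#' `f(u) = (1 + s) u^h / (1 + s u^(2h))` on the normalized TPO level `u`:
#' stimulation rises from 0, passes 1 at the normal level, peaks at an
#' interior optimum and falls again at supra-physiological levels.
#'
#' @param t_level normalized TPO level, `>= 0`
#' @param h shape exponent
#' @param s suppression weight
#' @return stimulation factor
#' @export
stimulation_tpo_biphasic <- function(t_level, h = 2, s = 1) {
  stopifnot(all(t_level >= 0))
  uh <- t_level^h
  (1 + s) * uh / (1 + s * uh^2)
}

#' First-order chemotherapy kill rates per proliferating compartment class
#'
#' The pharmacodynamic coupling is linear and additive across drugs: each
#' drug contributes `PD_drug * C_drug` to the kill pressure. Shared cycling
#' compartments (stem cells, CMP, lymphoid progenitors, osteoblasts) see the
#' unweighted sum scaled by their vulnerability (`f_kill_S`, `f_kill_L`,
#' `f_kill_O`); the granulopoietic and thrombopoietic branches see
#' lineage-weighted sums (fixed per-drug vulnerability weights reflecting,
#' e.g., the predominantly thrombotoxic profile of oxaliplatin and the
#' neutropenic profile of docetaxel). Mature circulating cells are not
#' killed.
#'
#' @param concentrations named vector of central concentrations in mg/L, with
#'   names among `oxaliplatin`, `fluorouracil`, `irinotecan`, `docetaxel`
#' @param params `hematotox_params`
#' @return named kill-rate vector (1/day) per compartment class
#' @export
chemo_kill <- function(concentrations, params = default_parameters()) {
  stopifnot(all(concentrations >= 0))
  bad <- setdiff(names(concentrations), PK_DRUGS)
  if (length(bad)) abort(paste0("unknown drugs: ", toString(bad)))
  pd <- unlist(params$individual[c("PD_oxali", "PD_5FU", "PD_iri", "PD_doc")])
  names(pd) <- PK_DRUGS
  con <- params$constants
  wg <- unlist(con[c("w_gran_oxa", "w_gran_fu", "w_gran_iri", "w_gran_doc")])
  wt <- unlist(con[c("w_thr_oxa", "w_thr_fu", "w_thr_iri", "w_thr_doc")])
  names(wg) <- names(wt) <- PK_DRUGS
  per_drug <- pd[names(concentrations)] * concentrations
  base <- sum(per_drug)
  c(S = con$f_kill_S * base, CMP = base,
    G_prol = sum(wg[names(concentrations)] * per_drug),
    CM = sum(wt[names(concentrations)] * per_drug),
    MKC = sum(wt[names(concentrations)] * per_drug),
    LYM_prol = con$f_kill_L * base, osteoblast = con$f_kill_O * base)
}

# The model state is non-negative by construction; stiff decays (notably the
# fast 5-FU elimination) can undershoot zero within the integrator tolerance
# band. Tiny negatives are numerical and clamped; larger ones are real errors
# and surface in the trajectory checks.
clamp_undershoot <- function(x, band = 1e-3) {
  x[x < 0 & x > -band] <- 0
  x
}

# slot index of each input rate in the trailing block of the parameter vector
RATE_SLOTS <- c(oxaliplatin = 1L, fluorouracil = 2L, irinotecan = 3L,
                docetaxel = 4L, gcsf = 5L, xkill = 6L)

empty_events <- function() {
  tibble::tibble(drug = character(), amount_mg = numeric(), start = numeric(),
                 duration = numeric(), rate = numeric(), cycle = integer(),
                 inert = logical())
}

#' Simulate the hematopoiesis model under a chemotherapy schedule
#'
#' Forward-simulates the full model (stem cells, granulopoiesis,
#' thrombopoiesis with ploidy classes and osteoblast niche, lymphocytes,
#' monocytes, G-CSF/TPO feedback, and drug PK) with a stiff-capable
#' integrator, restarting at every infusion on/off breakpoint so the
#' piecewise-constant inputs are handled exactly. Starts at the homeostatic
#' steady state unless `init` is given.
#'
#' Besides the cytotoxic drugs, events may use the pseudo-drugs `gcsf`
#' (exogenous G-CSF input, normalized units/day) and `xkill` (an exogenous
#' kill-rate pulse in 1/day, used by the virtual-experiment protocols).
#'
#' @param params `hematotox_params`
#' @param events dosing events as from [build_dosing_events()], or `NULL`
#' @param t_grid increasing output times in days
#' @param init optional full initial state (named as [steady_state()])
#' @param full keep the full state matrix as attribute `state`
#' @param rtol,atol integrator tolerances (absolute tolerance is applied on
#'   the normalized scale)
#' @return a `hematotox_trajectory` tibble with columns `time`, `PLT`, `ANC`,
#'   `WBC` (all counts in 1e9/L)
#' @examples
#' ev <- build_dosing_events("FLOT", bsa = 1.8, n_cycles = 1)
#' tr <- simulate_hematopoiesis(default_parameters(), ev, t_grid = 0:28)
#' @export
simulate_hematopoiesis <- function(params, events = NULL, t_grid,
                                   init = NULL, full = FALSE,
                                   rtol = 1e-8, atol = NULL) {
  if (is.null(events)) events <- empty_events()
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort("t_grid must be strictly increasing", class = "hematotox_input_error")
  }
  events <- events[!events$inert, , drop = FALSE]
  bad <- setdiff(events$drug, names(RATE_SLOTS))
  if (length(bad)) {
    abort(paste0("no model input for drug(s): ", toString(bad)),
          class = "hematotox_input_error")
  }
  y <- if (is.null(init)) steady_state(params) else {
    stopifnot(length(init) == 44L)
    setNames(as.numeric(init), state_names())
  }
  con <- params$constants
  if (is.null(atol)) {
    atol <- rep(1e-10, 44)
    atol[match(c("ANC", "LYM", "MON"), state_names())] <-
      1e-10 * c(con$ANC_nor, con$LYM_nor, con$MON_nor)
    atol[match(paste0("P", 1:10), state_names())] <- 1e-10 * con$PLT_nor
    atol[34:44] <- 1e-6
  }

  t0 <- min(t_grid[1], if (nrow(events)) min(events$start) else Inf)
  t_end <- t_grid[length(t_grid)]
  ends <- events$start + events$duration
  brk <- sort(unique(c(t0, t_end,
                       events$start[events$start > t0 & events$start < t_end],
                       ends[ends > t0 & ends < t_end])))
  state <- matrix(NA_real_, length(t_grid), 44,
                  dimnames = list(NULL, state_names()))
  if (t_grid[1] == t0) state[1, ] <- y
  last_t <- t0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    mid <- (a + b) / 2
    active <- events[events$start <= mid & events$start + events$duration > mid, ,
                     drop = FALSE]
    rates <- numeric(6)
    if (nrow(active)) {
      for (j in seq_len(nrow(active))) {
        slot <- RATE_SLOTS[[active$drug[j]]]
        rates[slot] <- rates[slot] + active$rate[j]
      }
    }
    times <- sort(unique(c(a, t_grid[t_grid > a & t_grid < b], b)))
    sol <- try(deSolve::ode(
      y = y, times = times, func = "derivs", dllname = "hematotox",
      initfunc = "initmod", parms = param_vector(params, rates),
      method = "lsoda", rtol = rtol, atol = atol, maxsteps = 20000
    ), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
        anyNA(sol[nrow(sol), ])) {
      abort(paste0("integration failed in [", a, ", ", b, "]; last good time ",
                   last_t), class = "hematotox_numeric_error")
    }
    y <- setNames(clamp_undershoot(as.numeric(sol[nrow(sol), -1])),
                  state_names())
    last_t <- b
    keep <- t_grid > a & t_grid <= b
    if (any(keep)) {
      state[keep, ] <- clamp_undershoot(sol[match(t_grid[keep], sol[, 1]), -1,
                                            drop = FALSE])
    }
  }

  plt <- rowSums(state[, paste0("P", 1:10), drop = FALSE])
  anc <- state[, "ANC"]
  wbc <- anc + state[, "LYM"] + state[, "MON"]
  out <- tibble::tibble(time = t_grid, PLT = pmax(plt, 0),
                        ANC = pmax(anc, 0), WBC = pmax(wbc, 0))
  class(out) <- c("hematotox_trajectory", class(out))
  if (full) attr(out, "state") <- state
  out
}

#' Drug-free platelet survival after a production shutdown
#'
#' Simulates a labeled platelet cohort through the model's Erlang-10 age
#' chain: production is switched off (`plt_prod_scale = 0`) and the full
#' circulating platelet mass is placed in the first age stage. Because the
#' lifespan is a 10-stage Erlang rather than exponential, the survival curve
#' has a shoulder: survival at half the mean lifespan stays well above
#' `exp(-0.5)`.
#'
#' @param params `hematotox_params`
#' @param t_grid times in days starting at 0
#' @return tibble with `time` and `survival` (fraction of the initial cohort)
#' @export
platelet_survival <- function(params = default_parameters(),
                              t_grid = seq(0, 20, by = 0.25)) {
  params$constants$plt_prod_scale <- 0
  y <- steady_state_unchecked(params)
  y[paste0("P", 1:10)] <- c(params$constants$PLT_nor, rep(0, 9))
  tr <- simulate_hematopoiesis(params, NULL, t_grid, init = y)
  tibble::tibble(time = t_grid, survival = tr$PLT / params$constants$PLT_nor)
}

# all-normal state without the fixed-point check (used when a structural
# switch such as plt_prod_scale deliberately breaks homeostasis)
steady_state_unchecked <- function(params) {
  con <- params$constants
  y <- setNames(numeric(44), state_names())
  y[c("S", "O", "D", "CMP", "Gp", paste0("M", 1:4), "CM",
      paste0("K", c(2, 4, 8, 16, 32, 64)), "PPT", "Lp", "G", "T")] <- 1
  y["ANC"] <- con$ANC_nor
  y["LYM"] <- con$LYM_nor
  y["MON"] <- con$MON_nor
  y[paste0("P", 1:10)] <- con$PLT_nor / 10
  y
}
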