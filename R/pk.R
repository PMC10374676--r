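#' Linear compartmental PK model of a cytotoxic drug
#'
#' Returns the packaged PK model for a drug: a linear 2- or 3-compartment
#' system with first-order elimination `k10` from the central compartment and
#' inter-compartment exchange `k12/k21` (`k13/k31` for three compartments).
#' Docetaxel carries a generic placeholder parameterization.
#'
#' @param drug one of `oxaliplatin`, `fluorouracil`, `irinotecan`, `docetaxel`
#' @return object of class `hematotox_pk`
#' @export
pk_model <- function(drug) {
  models <- hematotox_config("pk")$pk
  if (!drug %in% names(models)) {
    abort(paste0("no PK model for drug: ", drug),
          class = "hematotox_config_error")
  }
  m <- models[[drug]]
  m$drug_id <- drug
  m <- structure(m, class = "hematotox_pk")
  if (isTRUE(m$placeholder)) {
    message("PK model for ", drug, " is a generic placeholder parameterization")
  }
  ev <- eigen(pk_matrix(m), only.values = TRUE)$values
  stopifnot(all(Re(ev) <= 1e-12))
  m
}

# system matrix of the linear PK model, d(amounts)/dt = M %*% amounts
pk_matrix <- function(pk) {
  n <- pk$n_compartments
  M <- matrix(0, n, n)
  M[1, 1] <- -(pk$k10 + pk$k12 + if (n == 3) pk$k13 else 0)
  M[1, 2] <- pk$k21
  M[2, 1] <- pk$k12
  M[2, 2] <- -pk$k21
  if (n == 3) {
    M[1, 3] <- pk$k31
    M[3, 1] <- pk$k13
    M[3, 3] <- -pk$k31
  }
  M
}

#' Closed-form bolus solution of a linear PK model
#'
#' Exact matrix-exponential solution for a bolus into the central compartment:
#' `A(t) = expm(M t) A(0)` with `A(0) = (bolus_amount, 0, ...)`. Serves as an
#' analytic cross-check for the numeric integrator.
#'
#' @param pk `hematotox_pk`
#' @param bolus_amount dose in mg given at `t = 0`
#' @param t times in days (vector, all `>= 0`)
#' @return tibble with `time`, per-compartment amounts `A1..An` (mg) and the
#'   central concentration `conc` (mg/L)
#' @export
pk_closed_form <- function(pk, bolus_amount, t) {
  stopifnot(inherits(pk, "hematotox_pk"), all(t >= 0), bolus_amount >= 0)
  M <- pk_matrix(pk)
  n <- nrow(M)
  a0 <- c(bolus_amount, rep(0, n - 1))
  amounts <- t(vapply(
    t,
    function(ti) as.numeric(Matrix::expm(M * ti) %*% a0),
    numeric(n)
  ))
  colnames(amounts) <- paste0("A", seq_len(n))
  out <- tibble::as_tibble(amounts)
  out$time <- t
  out$conc <- out$A1 / pk$central_volume
  dplyr::relocate(out, "time")
}

#' Central-compartment concentration under an infusion schedule
#'
#' Numerically integrates the linear PK system under piecewise-constant
#' infusion inputs, restarting the integrator at every infusion on/off
#' breakpoint. The system is linear, so concentrations superpose over events
#' and scale with dose.
#'
#' @param pk `hematotox_pk`
#' @param events dosing events tibble as from [build_dosing_events()],
#'   restricted to `pk$drug_id` (an event for another drug is an error)
#' @param t_grid strictly increasing times in days
#' @param rtol,atol integrator tolerances
#' @return tibble with `time` and `conc` (mg/L)
#' @export
pk_concentration <- function(pk, events, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pk, "hematotox_pk"))
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort("t_grid must be strictly increasing", class = "hematotox_input_error")
  }
  if (nrow(events) > 0 && any(events$drug != pk$drug_id)) {
    abort(paste0("events contain drugs other than ", pk$drug_id),
          class = "hematotox_input_error")
  }
  M <- pk_matrix(pk)
  n <- nrow(M)
  rhs <- function(t, y, parms) list(M %*% y + c(parms$rate, rep(0, n - 1)))

  sol <- integrate_chunked(
    y0 = rep(0, n), t_grid = t_grid,
    events = events, rhs = rhs,
    rate_fun = function(active) sum(active$rate),
    rtol = rtol, atol = atol
  )
  tibble::tibble(time = t_grid, conc = pmax(sol[, 1], 0) / pk$central_volume)
}

# Integrate an ODE whose only time dependence is piecewise-constant input
# rates, by splitting the time axis at event on/off breakpoints. `rate_fun`
# maps the set of active events to the parameter object handed to `rhs`
# (wrapped as list(rate = ...)). Returns the state matrix on t_grid.
integrate_chunked <- function(y0, t_grid, events, rhs, rate_fun,
                              rtol, atol, method = "lsoda") {
  # dosing may begin before the first requested output time
  t0 <- min(t_grid[1], if (nrow(events)) min(events$start) else Inf)
  t_end <- t_grid[length(t_grid)]
  brk <- sort(unique(c(
    t0, t_end,
    events$start[events$start > t0 & events$start < t_end],
    (events$start + events$duration)[(events$start + events$duration) > t0 &
                                       (events$start + events$duration) < t_end]
  )))
  out <- matrix(NA_real_, length(t_grid), length(y0))
  if (t_grid[1] == t0) out[1, ] <- y0
  y <- y0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    mid <- (a + b) / 2
    active <- events[events$start <= mid & events$start + events$duration > mid, ,
                     drop = FALSE]
    times <- sort(unique(c(a, t_grid[t_grid > a & t_grid < b], b)))
    sol <- deSolve::ode(
      y = y, times = times, func = rhs,
      parms = list(rate = rate_fun(active)),
      method = method, rtol = rtol, atol = atol
    )
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- t_grid > a & t_grid <= b
    if (any(keep)) {
      idx <- match(t_grid[keep], sol[, 1])
      out[keep, ] <- sol[idx, -1, drop = FALSE]
    }
  }
  out
}
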