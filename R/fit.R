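#' Fitting settings for individual parameter learning
#'
#' @param free names of the free individual parameters; `NULL` selects the
#'   default set `b_S_act`, `b_A_CM`, `b_MKC64`, `w_PLC`, `d_Osteo_loss` plus
#'   the kill coefficients of the drugs in the patient's regimen
#' @param lower_mult,upper_mult plausibility box bounds as multiples of the
#'   population value (the defaults span about +/- 4.6 lognormal SDs at the
#'   default between-patient CV of 0.3)
#' @param n_starts number of local optimizations (Latin-hypercube multistart
#'   in log-parameter space; the first start is the population centre)
#' @param start_spread half-width of the multistart box on the log scale
#' @param maxit,reltol Nelder-Mead control
#' @param polish_rounds extra simplex restarts from the incumbent optimum
#'   while the search has not converged
#' @param sigma_ind lognormal residual scale of individual observations
#' @param min_obs minimum number of cycle-1 observations per fitted analyte
#' @param seed RNG seed for the multistart draw
#' @param rtol integrator relative tolerance used inside the objective
#' @return list of class `hematotox_fit_settings`
#' @export
fit_settings <- function(free = NULL, lower_mult = 0.25, upper_mult = 4,
                         n_starts = 8, start_spread = 0.7, maxit = 400,
                         reltol = 1e-10, polish_rounds = 2, sigma_ind = 0.15,
                         min_obs = 4, seed = 1L, rtol = 1e-8) {
  structure(
    list(free = free, lower_mult = lower_mult, upper_mult = upper_mult,
         n_starts = n_starts, start_spread = start_spread, maxit = maxit,
         reltol = reltol, polish_rounds = polish_rounds,
         sigma_ind = sigma_ind, min_obs = min_obs,
         seed = as.integer(seed), rtol = rtol),
    class = "hematotox_fit_settings"
  )
}

regimen_pd_params <- function(regimen) {
  drugs <- regimen_spec(regimen)$administrations$drug
  pd <- c(oxaliplatin = "PD_oxali", fluorouracil = "PD_5FU",
          irinotecan = "PD_iri", docetaxel = "PD_doc")
  unname(pd[intersect(names(pd), drugs)])
}

default_free_set <- function(regimen) {
  c("b_S_act", "b_A_CM", "b_MKC64", "w_PLC", "d_Osteo_loss",
    regimen_pd_params(regimen))
}

#' Penalized virtual-participation objective
#'
#' The objective combines an individual lognormal residual term over the
#' patient's cycle-1 observations with population penalty terms over
#' virtual-experiment datasets:
#' `sum(((log(y_obs) - log(y_model)) / sigma_ind)^2) +
#'  sum(((mean - y_model_pop) / sd)^2)`.
#' It is zero iff the model reproduces all data exactly, and reduces to the
#' individual term when `experiments` is empty. A failed simulation returns a
#' large finite penalty instead of throwing, keeping optimizers total.
#'
#' @param theta named vector of individual parameters to evaluate
#' @param observations cycle-1 observations (`time`, `analyte`, `value`);
#'   times at or beyond the cycle-1 window are rejected
#' @param events dosing events of the patient's first cycle
#' @param experiments virtual-experiment bank from
#'   [make_virtual_experiments()], or `NULL`
#' @param params population parameters completing `theta`
#' @param sigma_ind individual residual scale
#' @param cycle_length cycle-1 window length in days
#' @param rtol integrator relative tolerance
#' @return non-negative scalar
#' @export
penalized_objective <- function(theta, observations, events,
                                experiments = NULL,
                                params = default_parameters(),
                                sigma_ind = 0.15, cycle_length = 14,
                                rtol = 1e-8) {
  if (any(observations$time >= cycle_length)) {
    abort("individual term uses cycle-1 observations only",
          class = "hematotox_input_error")
  }
  p_i <- try(set_individual(params, theta), silent = TRUE)
  if (inherits(p_i, "try-error")) return(1e12 + sum(abs(unlist(theta))))

  total <- 0
  obs_times <- sort(unique(observations$time))
  grid <- sort(unique(c(0, obs_times, cycle_length)))
  tr <- try(simulate_hematopoiesis(p_i, events, grid, rtol = rtol),
            silent = TRUE)
  if (inherits(tr, "try-error")) {
    return(1e12 + sum(abs(log(pmax(unlist(theta), 1e-12)))))
  }
  model_vals <- list(PLT = tr$PLT, ANC = tr$ANC, WBC = tr$WBC)
  idx <- match(observations$time, grid)
  y_mod <- vapply(seq_len(nrow(observations)),
                  function(i) model_vals[[observations$analyte[i]]][idx[i]],
                  numeric(1))
  r <- (log(pmax(observations$value, 1e-9)) - log(pmax(y_mod, 1e-9))) / sigma_ind
  total <- total + sum(r^2)

  if (!is.null(experiments) && nrow(experiments) > 0) {
    for (prot in unique(experiments$protocol)) {
      ex <- experiments[experiments$protocol == prot, , drop = FALSE]
      sim <- try(simulate_protocol(p_i, prot, unique(ex$observable),
                                   sort(unique(ex$time))), silent = TRUE)
      if (inherits(sim, "try-error")) {
        return(1e12 + sum(abs(log(pmax(unlist(theta), 1e-12)))))
      }
      key <- paste(sim$observable, sim$time)
      y_pop <- sim$value[match(paste(ex$observable, ex$time), key)]
      total <- total + sum(((ex$mean - y_pop) / ex$sd)^2)
    }
  }
  total
}

#' Fit individual model parameters to first-cycle blood counts
#'
#' Learns the patient's free parameters by minimizing the penalized
#' virtual-participation objective with a bounded multistart Nelder-Mead
#' search in log-parameter space. The best of `n_starts` local optimizations
#' wins (ties broken by the first start index); the result is deterministic
#' for a fixed seed. Identifiability is quantified by relative standard
#' errors from the inverse finite-difference Hessian of the objective in
#' log-parameter space; parameters with RSE above 50% are flagged
#' non-identifiable.
#'
#' @param patient list with elements `observations` (cycle-1 rows are used),
#'   `regimen` (name) and `BSA`; optionally `patient_id`
#' @param experiments virtual-experiment bank or `NULL`
#' @param settings [fit_settings()]
#' @param params population parameters
#' @return object of class `hematotox_fit` with elements `estimates`, `rse`,
#'   `objective`, `converged`, `n_starts_used`, `free`, plus patient context
#' @export
fit_individual <- function(patient, experiments = NULL,
                           settings = fit_settings(),
                           params = default_parameters()) {
  stopifnot(is.list(patient), !is.null(patient$observations),
            !is.null(patient$regimen), !is.null(patient$BSA))
  obs1 <- patient$observations[patient$observations$time < 14, , drop = FALSE]
  counts <- table(obs1$analyte)
  need <- c("PLT", "ANC", "WBC")
  short <- need[!(need %in% names(counts)) |
                  counts[need] < settings$min_obs]
  short <- short[!is.na(short)]
  if (length(short)) {
    abort(paste0("too few cycle-1 observations for analyte(s): ",
                 toString(short), " (need >= ", settings$min_obs, ")"),
          class = "hematotox_data_error")
  }
  free <- settings$free %||% default_free_set(patient$regimen)
  events <- build_dosing_events(patient$regimen, patient$BSA, n_cycles = 1)
  pop <- unlist(params$individual[free])
  lb <- log(pop * settings$lower_mult)
  ub <- log(pop * settings$upper_mult)

  obj_log <- function(u) {
    if (any(u < lb) || any(u > ub)) {
      return(1e12 + sum(pmax(lb - u, 0) + pmax(u - ub, 0)))
    }
    penalized_objective(setNames(exp(u), free), obs1, events, experiments,
                        params, sigma_ind = settings$sigma_ind,
                        rtol = settings$rtol)
  }

  n_starts <- settings$n_starts
  starts <- matrix(rep(log(pop), n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    withr::with_seed(settings$seed, {
      u01 <- lhs::randomLHS(n_starts - 1, length(free))
    })
    starts[-1, ] <- starts[-1, , drop = FALSE] +
      (2 * u01 - 1) * settings$start_spread
  }

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    runs[[s]] <- tryCatch(
      optim(starts[s, ], obj_log, method = "Nelder-Mead",
            control = list(maxit = settings$maxit,
                           reltol = settings$reltol)),
      error = function(e) list(value = Inf, par = starts[s, ],
                               convergence = 99L)
    )
  }
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(values))) {
    abort("all optimization starts failed",
          class = "hematotox_convergence_error")
  }
  best_i <- which.min(values)  # ties: first index
  best <- runs[[best_i]]
  # polish: restart the simplex at the incumbent until it reports
  # convergence (a fresh simplex escapes the collapsed one)
  for (r in seq_len(settings$polish_rounds)) {
    if (best$convergence == 0L) break
    nxt <- tryCatch(
      optim(best$par, obj_log, method = "Nelder-Mead",
            control = list(maxit = settings$maxit,
                           reltol = settings$reltol)),
      error = function(e) NULL
    )
    if (is.null(nxt) || nxt$value > best$value) break
    best <- nxt
  }
  estimates <- setNames(exp(best$par), free)

  # curvature of the (unbounded) objective: finite differences around a
  # bound-adjacent estimate must not cross the plausibility wall; the large
  # fixed step in relative_standard_errors keeps solver noise below the
  # curvature signal
  rse <- relative_standard_errors(
    function(th) {
      penalized_objective(th, obs1, events, experiments, params,
                          sigma_ind = settings$sigma_ind,
                          rtol = settings$rtol)
    },
    estimates
  )

  structure(
    list(patient_id = patient$patient_id %||% "patient",
         regimen = patient$regimen, BSA = patient$BSA,
         estimates = estimates, rse = rse,
         objective = best$value, converged = best$convergence == 0L,
         n_starts_used = n_starts, free = free,
         n_obs = nrow(obs1), settings = settings,
         start_values = values),
    class = "hematotox_fit"
  )
}

#' Relative standard errors from the objective curvature
#'
#' Computes a central finite-difference Hessian of the objective in
#' log-parameter space at the estimate; the standard error of `log(theta)` —
#' approximately the relative standard error of `theta` — is the square root
#' of the diagonal of the inverse Hessian. The step (`h`, default 0.05 log
#' units, i.e. 5% parameter perturbations) is deliberately large relative to
#' the integration error of an ODE-based objective; adaptive
#' machine-precision steps would amplify solver noise into spurious
#' curvature. A non-positive-definite Hessian flags the affected parameters
#' non-identifiable (RSE reported as `Inf`) instead of raising an error.
#'
#' @param objective function of a named parameter vector on the natural scale
#' @param estimates named estimates at which curvature is evaluated
#' @param h central-difference step on the log scale
#' @return named numeric vector of RSEs (fractions)
#' @export
relative_standard_errors <- function(objective, estimates, h = 0.05) {
  nm <- names(estimates)
  k <- length(estimates)
  u0 <- log(unname(estimates))
  f_log <- function(u) objective(setNames(exp(u), nm))
  bad <- setNames(rep(Inf, k), nm)

  H <- matrix(NA_real_, k, k)
  f0 <- f_log(u0)
  ok <- TRUE
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    fp <- f_log(u0 + ei); fm <- f_log(u0 - ei)
    H[i, i] <- (fp - 2 * f0 + fm) / h^2
    for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f_log(u0 + ei + ej) - f_log(u0 + ei - ej) -
           f_log(u0 - ei + ej) + f_log(u0 - ei - ej)) / (4 * h^2)
    }
    if (anyNA(H[i, seq_len(i)]) || !all(is.finite(H[i, seq_len(i)]))) ok <- FALSE
  }
  if (!ok) return(bad)
  Hi <- try(solve(H), silent = TRUE)
  if (inherits(Hi, "try-error")) return(bad)
  d <- diag(Hi)
  rse <- ifelse(d > 0, sqrt(pmax(d, 0)), Inf)
  setNames(rse, nm)
}

#' @export
print.hematotox_fit <- function(x, ...) {
  cat("<hematotox_fit> patient ", x$patient_id, " (", x$regimen, ")\n",
      "objective ", format(x$objective, digits = 6),
      ", converged: ", x$converged, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted patient model
#'
#' @param x `hematotox_fit`
#' @param ... unused
#' @return tibble with `term`, `estimate`, `rse`, `identifiable`
#' @export
tidy.hematotox_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 rse = unname(x$rse),
                 identifiable = unname(x$rse) <= 0.5)
}

#' One-row fit summary
#'
#' @param x `hematotox_fit`
#' @param ... unused
#' @return tibble with objective, convergence and size information
#' @export
glance.hematotox_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_starts_used = x$n_starts_used, n_obs = x$n_obs,
                 n_free = length(x$free))
}
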