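#' Predict per-cycle toxicity grades from a fitted patient model
#'
#' Simulates the full treatment course with the fitted parameters and grades
#' the per-cycle minimum of the model trajectory. By default the minimum is
#' taken over the cycle's scheduled sampling days, so that predicted and
#' observed grades are compared on the same information grid; set
#' `continuous = TRUE` to grade the continuous trajectory minimum on a daily
#' grid instead.
#'
#' @param fit `hematotox_fit` (or a named parameter vector)
#' @param regimen regimen name; defaults to the fit's regimen
#' @param bsa body surface area; defaults to the fit's
#' @param cycles integer cycles to report (empty vector gives an empty
#'   result)
#' @param n_cycles simulated treatment length in cycles
#' @param continuous grade continuous minima instead of scheduled-day minima
#' @param params population parameters
#' @param rules grading rules
#' @return `GradeSeries` tibble: `cycle`, `analyte`, `nadir_value`,
#'   `nadir_time`, `n_observations`, `grade`
#' @export
predict_grades <- function(fit, regimen = NULL, bsa = NULL,
                           cycles = NULL, n_cycles = NULL,
                           continuous = FALSE,
                           params = default_parameters(),
                           rules = grading_rules()) {
  if (inherits(fit, "hematotox_fit")) {
    theta <- fit$estimates
    regimen <- regimen %||% fit$regimen
    bsa <- bsa %||% fit$BSA
  } else {
    theta <- fit
  }
  stopifnot(!is.null(regimen), !is.null(bsa))
  spec <- regimen_spec(regimen)
  n_cycles <- n_cycles %||% spec$default_cycles
  cycles <- cycles %||% seq(2, n_cycles)
  if (length(cycles) == 0) {
    return(tibble::tibble(cycle = integer(), analyte = character(),
                          nadir_value = numeric(), nadir_time = numeric(),
                          n_observations = integer(), grade = integer()))
  }
  stopifnot(all(cycles >= 1), all(cycles <= n_cycles))

  p_i <- set_individual(params, theta)
  ev <- build_dosing_events(spec, bsa, n_cycles)
  sched <- if (continuous) {
    seq(0, n_cycles * spec$cycle_length, by = 0.5)
  } else {
    study_schedule(n_cycles, spec$cycle_length)
  }
  grid <- sort(unique(c(0, sched)))
  tr <- simulate_hematopoiesis(p_i, ev, grid)
  pseudo <- observe(tr, sched, noise_cv = 0, cycle_length = spec$cycle_length)
  out <- grade_per_cycle(pseudo, cycle_length = spec$cycle_length,
                         n_cycles = n_cycles, rules = rules)
  out[out$cycle %in% cycles, , drop = FALSE]
}

#' Agreement of predicted and observed toxicity grades
#'
#' Joins predicted and observed grade series on their shared keys and
#' summarizes the absolute grade deviation `|predicted - observed|` per
#' group: mean, standard error (sample SD / sqrt(n)) and the number of
#' patients. Cycle-1 rows are kept but flagged `fitted_only` (that cycle is
#' used for parameter fitting and shown for comparison only); headline
#' summaries should exclude them.
#'
#' @param predicted,observed grade tibbles sharing `cycle`, `analyte` and —
#'   when present in both — `patient_id` and `regimen` columns
#' @param by grouping columns of the summary
#' @return `hematotox_deviation` tibble with `mean_abs_dev`, `se`, `n` and
#'   `fitted_only` per group
#' @export
deviation_summary <- function(predicted, observed,
                              by = c("cycle", "analyte")) {
  keys <- intersect(intersect(names(predicted), names(observed)),
                    c("patient_id", "regimen", "cycle", "analyte"))
  joined <- dplyr::inner_join(
    dplyr::select(predicted, dplyr::all_of(c(keys, "grade"))),
    dplyr::select(observed, dplyr::all_of(c(keys, "grade"))),
    by = keys, suffix = c("_pred", "_obs")
  )
  if (nrow(joined) == 0) {
    warn("no overlapping (patient, cycle, analyte) keys")
  }
  out <- joined |>
    dplyr::mutate(abs_dev = abs(.data$grade_pred - .data$grade_obs)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_abs_dev = mean(.data$abs_dev),
      se = if (dplyr::n() >= 2) sd(.data$abs_dev) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  if ("cycle" %in% names(out)) {
    out$fitted_only <- out$cycle == 1L
  } else {
    out$fitted_only <- FALSE
  }
  class(out) <- c("hematotox_deviation", class(out))
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their average rank).
#' Constant input yields `NA` (an absent value, not an error).
#'
#' @param x,y numeric vectors of equal length `>= 3`
#' @return rho in `[-1, 1]`, or `NA` for degenerate input
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cor(rx, ry, method = "pearson")
}

# two-sided p-value for Spearman's rho: exact permutation distribution for
# small n, t-approximation otherwise
spearman_pvalue <- function(x, y, rho, exact_max = 7) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n <= exact_max) {
    perms <- pracma::perms(seq_len(n))
    rhos <- apply(perms, 1, function(p) spearman_rho(x, y[p]))
    return(mean(abs(rhos) >= abs(rho) - 1e-12))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-15))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Screen parameter estimates against clinical covariates
#'
#' Spearman rank correlations between per-patient parameter estimates and the
#' clinical risk factors age, BMI and BSA, reported with the sample size and
#' a two-sided p-value (exact permutation for small n, t-approximation
#' otherwise; optionally Benjamini-Hochberg adjusted).
#'
#' @param estimates tibble with `patient_id`, `parameter`, `estimate` (e.g.
#'   stacked [tidy()] outputs, renaming `term` to `parameter`)
#' @param covariates tibble with `patient_id` and covariate columns
#' @param vars covariate columns to screen
#' @param adjust apply Benjamini-Hochberg adjustment across tests
#' @return `CovariateScreen` tibble: `parameter`, `covariate`, `rho`, `n`,
#'   `p_value`
#' @export
covariate_screen <- function(estimates, covariates,
                             vars = c("age", "BMI", "BSA"),
                             adjust = FALSE) {
  merged <- dplyr::inner_join(estimates, covariates, by = "patient_id")
  if (length(unique(merged$patient_id)) < 3) {
    abort("covariate screen needs at least 3 patients",
          class = "hematotox_data_error")
  }
  out <- tidyr::expand_grid(parameter = unique(merged$parameter),
                            covariate = vars) |>
    purrr::pmap_dfr(function(parameter, covariate) {
      d <- merged[merged$parameter == parameter, , drop = FALSE]
      ok <- is.finite(d$estimate) & is.finite(d[[covariate]])
      d <- d[ok, , drop = FALSE]
      rho <- if (nrow(d) >= 3) spearman_rho(d$estimate, d[[covariate]]) else NA_real_
      p <- if (nrow(d) >= 3 && !is.na(rho)) {
        spearman_pvalue(d$estimate, d[[covariate]], rho)
      } else NA_real_
      tibble::tibble(parameter = parameter, covariate = covariate,
                     rho = rho, n = nrow(d), p_value = p)
    })
  if (adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Tabulate worst-grade hematologic adverse events
#'
#' Counts patients by worst CTCAE grade (1-4) per regimen and analyte, and
#' derives the high-grade (grade 3/4) fraction per group and overall.
#'
#' @param worst_grades tibble with `patient_id`, `regimen`, `analyte` and
#'   `worst_grade` (0-4); one row per patient and analyte
#' @return `AESummary` tibble with per-regimen and `overall` rows: counts
#'   `grade1..grade4`, `n_patients`, `high_grade_n`, `high_grade_frac`
#' @export
summarize_adverse_events <- function(worst_grades) {
  stopifnot(all(worst_grades$worst_grade %in% 0:4))
  tab <- function(df, label) {
    df |>
      dplyr::group_by(.data$analyte) |>
      dplyr::summarise(
        regimen = label,
        n_patients = dplyr::n(),
        grade1 = sum(.data$worst_grade == 1),
        grade2 = sum(.data$worst_grade == 2),
        grade3 = sum(.data$worst_grade == 3),
        grade4 = sum(.data$worst_grade == 4),
        high_grade_n = sum(.data$worst_grade >= 3),
        high_grade_frac = .data$high_grade_n / .data$n_patients,
        .groups = "drop"
      )
  }
  per_reg <- worst_grades |>
    dplyr::group_split(.data$regimen) |>
    purrr::map_dfr(function(df) tab(df, df$regimen[1]))
  overall <- tab(worst_grades, "overall")
  dplyr::relocate(dplyr::bind_rows(per_reg, overall), "regimen")
}

#' Worst grade per patient and analyte from a grade series
#'
#' @param grade_series tibble with `patient_id`, `analyte`, `grade`
#' @return tibble with `patient_id`, `analyte`, `worst_grade`
#' @export
worst_grades <- function(grade_series) {
  grade_series |>
    dplyr::group_by(.data$patient_id, .data$analyte) |>
    dplyr::summarise(worst_grade = max(.data$grade), .groups = "drop")
}
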