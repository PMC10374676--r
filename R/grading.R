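#' CTCAE v5 grading rules for hematologic laboratory toxicities
#'
#' Thresholds (1e9/L) for neutropenia (ANC), thrombocytopenia (PLT) and
#' leukocytopenia (WBC), read from the packaged `ctcae.yaml`. Grade `g`
#' applies on the half-open interval `[threshold_g, threshold_{g-1})`; a value
#' exactly on a boundary takes the milder grade; values at or above the lower
#' limit of normal (LLN) are grade 0. Sites using different LLNs can pass a
#' modified rules object anywhere a `rules` argument is accepted.
#'
#' @return tibble with columns `analyte`, `lln`, `g1`, `g2`, `g3`
#' @export
grading_rules <- function() {
  cfg <- hematotox_config("ctcae")$ctcae
  rules <- purrr::imap_dfr(cfg, \(x, nm) tibble::tibble(
    analyte = nm, lln = x$lln, g1 = x$g1, g2 = x$g2, g3 = x$g3
  ))
  stopifnot(all(rules$lln > rules$g1), all(rules$g1 > rules$g2),
            all(rules$g2 > rules$g3), all(rules$g3 > 0))
  rules
}

#' CTCAE toxicity grade of a blood count
#'
#' @param analyte `"PLT"`, `"ANC"` or `"WBC"` (recycled against `value`)
#' @param value counts in 1e9/L, `>= 0`
#' @param rules grading rules as from [grading_rules()]
#' @return integer grades 0-4
#' @examples
#' ctcae_grade("ANC", c(2.0, 1.0, 0.4))
#' @export
ctcae_grade <- function(analyte, value, rules = grading_rules()) {
  stopifnot(all(value >= 0))
  bad <- setdiff(unique(analyte), rules$analyte)
  if (length(bad)) {
    abort(paste0("no grading rule for analyte: ", toString(bad)),
          class = "hematotox_config_error")
  }
  df <- tibble::tibble(analyte = analyte, value = value)
  idx <- match(df$analyte, rules$analyte)
  brk <- cbind(rules$g3[idx], rules$g2[idx], rules$g1[idx], rules$lln[idx])
  grade <- 4L - rowSums(df$value >= brk)
  as.integer(grade)
}

#' Nadir of observations within a cycle window
#'
#' Returns the lowest observed value in the half-open window
#' `[start, end)`; ties are broken by the earliest time. With no observation
#' in the window an empty tibble is returned (missing cycles propagate as
#' absent entries, not errors).
#'
#' @param observations tibble with `time` and `value`
#' @param cycle_window numeric `c(start, end)` in days
#' @return tibble with `nadir_value`, `nadir_time`, `n_observations`
#'   (zero rows if the window is empty)
#' @export
cycle_nadir <- function(observations, cycle_window) {
  stopifnot(length(cycle_window) == 2L, cycle_window[1] < cycle_window[2])
  w <- observations[observations$time >= cycle_window[1] &
                      observations$time < cycle_window[2], , drop = FALSE]
  if (nrow(w) == 0) {
    return(tibble::tibble(nadir_value = numeric(), nadir_time = numeric(),
                          n_observations = integer()))
  }
  i <- order(w$value, w$time)[1]
  tibble::tibble(nadir_value = w$value[i], nadir_time = w$time[i],
                 n_observations = nrow(w))
}

#' Per-cycle nadir values and CTCAE grades
#'
#' Maps sparse observations to cycle windows `[(k-1)*L, k*L)` on the study
#' clock, extracts the per-cycle nadir of each analyte, and grades it. Only
#' (cycle, analyte) combinations with at least one observation appear.
#'
#' @param observations tibble with columns `patient_id` (optional), `time`,
#'   `analyte`, `value`
#' @param cycle_length cycle length in days
#' @param n_cycles number of cycles to consider (default: up to the last
#'   observed time)
#' @param rules grading rules
#' @return tibble with `patient_id` (if present), `cycle`, `analyte`,
#'   `nadir_value`, `nadir_time`, `n_observations`, `grade`
#' @export
grade_per_cycle <- function(observations, cycle_length = 14, n_cycles = NULL,
                            rules = grading_rules()) {
  obs <- tibble::as_tibble(observations)
  if (!"patient_id" %in% names(obs)) obs$patient_id <- "patient"
  n_cycles <- n_cycles %||% max(1L, ceiling((max(obs$time) + 1e-9) / cycle_length))
  grid <- tidyr::expand_grid(
    patient_id = unique(obs$patient_id),
    cycle = seq_len(n_cycles),
    analyte = unique(obs$analyte)
  )
  out <- purrr::pmap_dfr(grid, function(patient_id, cycle, analyte) {
    nd <- cycle_nadir(
      obs[obs$patient_id == patient_id & obs$analyte == analyte, ],
      c((cycle - 1) * cycle_length, cycle * cycle_length)
    )
    if (nrow(nd) == 0) return(NULL)
    tibble::tibble(patient_id = patient_id, cycle = cycle, analyte = analyte, nd)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(patient_id = character(), cycle = integer(),
                          analyte = character(), nadir_value = numeric(),
                          nadir_time = numeric(), n_observations = integer())
  }
  out$grade <- ctcae_grade(out$analyte, out$nadir_value, rules)
  if (!"patient_id" %in% names(observations)) out$patient_id <- NULL
  out
}
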