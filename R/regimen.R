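#' Load a chemotherapy regimen definition
#'
#' Regimens are declarative dosing schemes read from the packaged
#' `regimens.yaml`: per-drug dose in mg/m2 body surface area, start offset
#' within the 14-day cycle, and infusion duration. Supported regimens are
#' `FLOT` (docetaxel, oxaliplatin, leucovorin, 5-FU 24-h infusion),
#' `FLO_mFOLFOX` (the same without docetaxel) and `FOLFIRINOX`
#' (oxaliplatin, irinotecan, leucovorin, 5-FU bolus plus 46-h infusion).
#'
#' @param name regimen name
#' @return object of class `hematotox_regimen`: list with `name`,
#'   `cycle_length` (days), `default_cycles` and an `administrations` tibble
#' @examples
#' regimen_spec("FLOT")$administrations
#' @export
regimen_spec <- function(name) {
  defs <- hematotox_config("regimens")$regimens
  if (!name %in% names(defs)) {
    abort(paste0("unknown regimen: ", name, " (available: ",
                 toString(names(defs)), ")"), class = "hematotox_config_error")
  }
  def <- defs[[name]]
  adm <- purrr::map_dfr(def$administrations, tibble::as_tibble)
  adm <- dplyr::rename(adm, dose_per_bsa = "dose_mg_per_m2")
  stopifnot(all(adm$dose_per_bsa >= 0), all(adm$infusion_hours > 0),
            all(adm$start_day >= 0))
  structure(
    list(name = name, cycle_length = def$cycle_length_days,
         default_cycles = def$default_cycles, administrations = adm),
    class = "hematotox_regimen"
  )
}

#' @export
print.hematotox_regimen <- function(x, ...) {
  cat("<regimen ", x$name, ">: every ", x$cycle_length, " days, default ",
      x$default_cycles, " cycles\n", sep = "")
  print(x$administrations)
  invisible(x)
}

#' Build absolute-dose infusion events for a patient
#'
#' Converts per-BSA doses into absolute infusion events on the study clock
#' (day 0 = cycle 1 day 1); cycle `k` events are the cycle-1 events shifted
#' by `(k - 1) * cycle_length`. Leucovorin events are flagged inert and carry
#' no myelotoxicity downstream.
#'
#' @param regimen `hematotox_regimen` or regimen name
#' @param bsa body surface area in m2
#' @param n_cycles number of treatment cycles
#' @return tibble with one row per administration per cycle: `drug`,
#'   `amount_mg`, `start` and `duration` (days), `rate` (mg/day), `cycle`,
#'   `inert`; sorted by start time
#' @examples
#' build_dosing_events("FLOT", bsa = 2.0, n_cycles = 1)
#' @export
build_dosing_events <- function(regimen, bsa, n_cycles = NULL) {
  if (is.character(regimen)) regimen <- regimen_spec(regimen)
  stopifnot(inherits(regimen, "hematotox_regimen"))
  if (!is.numeric(bsa) || length(bsa) != 1L || !is.finite(bsa) || bsa <= 0) {
    abort("bsa must be a single positive number", class = "hematotox_input_error")
  }
  n_cycles <- n_cycles %||% regimen$default_cycles
  stopifnot(n_cycles >= 1)

  adm <- regimen$administrations
  events <- tidyr::expand_grid(cycle = seq_len(n_cycles), adm) |>
    dplyr::mutate(
      amount_mg = .data$dose_per_bsa * bsa,
      start = (.data$cycle - 1) * regimen$cycle_length + .data$start_day,
      duration = .data$infusion_hours / 24,
      rate = .data$amount_mg / .data$duration,
      inert = .data$drug == "leucovorin"
    ) |>
    dplyr::select("drug", "amount_mg", "start", "duration", "rate",
                  "cycle", "inert") |>
    dplyr::arrange(.data$start, .data$drug)
  events
}
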