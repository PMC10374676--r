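#' Study configuration
#'
#' Drives [run_study()]. Exactly one of `synthetic` (a [cohort_config()]) or
#' `input` (paths to patient and observation CSVs) must be given.
#'
#' @param synthetic `hematotox_cohort_config` for a simulated study
#' @param input list with `patients` and `observations` CSV paths
#' @param out_dir output directory (created if missing); `NULL` disables
#'   writing
#' @param fit [fit_settings()] applied to every patient
#' @param seed root seed; per-patient fitting seeds are derived from it
#' @param use_experiments include the virtual-experiment penalty bank
#' @return list of class `hematotox_study_config`
#' @export
study_config <- function(synthetic = NULL, input = NULL, out_dir = NULL,
                         fit = fit_settings(), seed = 1L,
                         use_experiments = TRUE) {
  if (is.null(synthetic) == is.null(input)) {
    abort("exactly one of `synthetic` and `input` must be given",
          class = "hematotox_config_error")
  }
  structure(
    list(synthetic = synthetic, input = input, out_dir = out_dir,
         fit = fit, seed = as.integer(seed),
         use_experiments = use_experiments),
    class = "hematotox_study_config"
  )
}

#' Read a blood-count observation table
#'
#' Expected header: `patient_id,time_days,cycle,analyte,value` with analyte
#' in PLT/ANC/WBC and value in 1e9/L. Malformed analyte rows are rejected
#' with their row numbers; an empty file yields an empty table with a
#' warning.
#'
#' @param path CSV file
#' @return tibble with `patient_id`, `time`, `cycle`, `analyte`, `value`
#' @export
read_observations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("patient_id", "time_days", "cycle", "analyte", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", toString(missing_cols)),
          class = "hematotox_parse_error")
  }
  if (nrow(df) == 0) {
    warn("observation file is empty")
    return(tibble::tibble(patient_id = character(), time = numeric(),
                          cycle = integer(), analyte = character(),
                          value = numeric()))
  }
  bad <- which(!df$analyte %in% c("PLT", "ANC", "WBC"))
  if (length(bad)) {
    abort(paste0("unknown analyte in row(s): ", toString(bad)),
          class = "hematotox_parse_error")
  }
  bad_val <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad_val)) {
    abort(paste0("invalid value in row(s): ", toString(bad_val)),
          class = "hematotox_parse_error")
  }
  tibble::tibble(patient_id = as.character(df$patient_id),
                 time = as.numeric(df$time_days),
                 cycle = as.integer(df$cycle),
                 analyte = df$analyte, value = as.numeric(df$value))
}

#' Write a blood-count observation table
#'
#' Inverse of [read_observations()]; the round trip is stable up to float
#' formatting.
#'
#' @param observations tibble with `patient_id`, `time`, `cycle`, `analyte`,
#'   `value`
#' @param path CSV file
#' @export
write_observations <- function(observations, path) {
  out <- tibble::tibble(patient_id = observations$patient_id,
                        time_days = observations$time,
                        cycle = observations$cycle,
                        analyte = observations$analyte,
                        value = observations$value)
  readr::write_csv(out, path)
  invisible(path)
}

#' Run the end-to-end hematotoxicity study
#'
#' Generates or ingests the cohort, fits every patient's free parameters on
#' cycle-1 data, predicts toxicity grades of the remaining cycles by model
#' simulation, grades the observed nadirs, and summarizes prediction
#' deviations, parameter-covariate correlations and worst-grade adverse
#' events. Per-patient fit failures are logged and skipped, with the count
#' recorded in the manifest.
#'
#' @param config [study_config()]
#' @param params population parameters
#' @return report bundle (list) with elements `cohort`, `fits`,
#'   `observed_grades`, `predicted_grades`, `deviations`, `covariates`,
#'   `ae_summary`, `manifest`; written to `config$out_dir` when set
#' @export
run_study <- function(config, params = default_parameters()) {
  stopifnot(inherits(config, "hematotox_study_config"))
  if (!is.null(config$synthetic)) {
    cohort <- sample_cohort(config$synthetic, params)
  } else {
    pat <- readr::read_csv(config$input$patients, show_col_types = FALSE)
    obs <- read_observations(config$input$observations)
    cohort <- structure(list(patients = tibble::as_tibble(pat),
                             observations = obs, truth = NULL),
                        class = "hematotox_cohort")
  }
  patients <- cohort$patients
  experiments <- if (config$use_experiments) {
    make_virtual_experiments(params)
  } else NULL

  fits <- list()
  failed <- character()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    p_obs <- cohort$observations[cohort$observations$patient_id == pid, ]
    patient <- list(patient_id = pid, regimen = patients$regimen[i],
                    BSA = patients$BSA[i], observations = p_obs)
    settings <- config$fit
    settings$seed <- config$seed + i
    fit <- tryCatch(
      fit_individual(patient, experiments, settings, params),
      error = function(e) {
        warn(paste0("fit failed for ", pid, ": ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) failed <- c(failed, pid) else fits[[pid]] <- fit
  }

  observed <- grade_per_cycle(cohort$observations)
  predicted <- purrr::imap_dfr(fits, function(fit, pid) {
    n_cyc <- if ("n_cycles" %in% names(patients)) {
      patients$n_cycles[patients$patient_id == pid]
    } else {
      regimen_spec(fit$regimen)$default_cycles
    }
    pg <- predict_grades(fit, n_cycles = n_cyc,
                         cycles = seq_len(n_cyc), params = params)
    dplyr::mutate(pg, patient_id = pid, .before = 1)
  })
  key <- patients[, c("patient_id", "regimen")]
  deviations <- deviation_summary(
    dplyr::left_join(predicted, key, by = "patient_id"),
    dplyr::left_join(observed, key, by = "patient_id"),
    by = c("regimen", "cycle", "analyte")
  )
  estimates <- purrr::imap_dfr(fits, function(fit, pid) {
    dplyr::mutate(dplyr::rename(tidy(fit), parameter = "term"),
                  patient_id = pid, .before = 1)
  })
  covariates <- if (length(fits) >= 3) {
    covariate_screen(estimates, patients[, c("patient_id", "age", "BMI", "BSA")])
  } else NULL
  ae <- summarize_adverse_events(
    dplyr::left_join(worst_grades(observed), key, by = "patient_id")
  )

  manifest <- list(
    seed = config$seed,
    n_patients = nrow(patients),
    n_fitted = length(fits),
    failed_fits = failed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("hematotox"))
  )
  bundle <- list(cohort = cohort, fits = fits, observed_grades = observed,
                 predicted_grades = predicted, deviations = deviations,
                 covariates = covariates, ae_summary = ae,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  invisible(bundle)
}

#' Write a study report bundle to disk
#'
#' @param bundle result of [run_study()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$observed_grades, file.path(dir, "observed_grades.csv"))
  readr::write_csv(bundle$predicted_grades, file.path(dir, "predicted_grades.csv"))
  readr::write_csv(bundle$deviations, file.path(dir, "deviation_summary.csv"))
  if (!is.null(bundle$covariates)) {
    readr::write_csv(bundle$covariates, file.path(dir, "covariate_screen.csv"))
  }
  readr::write_csv(bundle$ae_summary, file.path(dir, "ae_summary.csv"))
  if (!is.null(bundle$cohort$observations) &&
      nrow(bundle$cohort$observations) > 0) {
    write_observations(bundle$cohort$observations,
                       file.path(dir, "observations.csv"))
  }
  fits_json <- purrr::map(bundle$fits, function(f) {
    list(patient_id = f$patient_id, regimen = f$regimen,
         estimates = as.list(f$estimates), rse = as.list(f$rse),
         objective = f$objective, converged = f$converged,
         n_starts_used = f$n_starts_used,
         seed = f$settings$seed)
  })
  jsonlite::write_json(fits_json, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
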