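#' Read a packaged configuration file
#'
#' Configuration lives in versioned YAML under `inst/extdata`: model constants
#' (`model.yaml`), PK constants (`pk.yaml`), regimen definitions
#' (`regimens.yaml`) and CTCAE thresholds (`ctcae.yaml`).
#'
#' @param name config file base name without extension
#' @return parsed list
#' @keywords internal
hematotox_config <- function(name) {
  cached <- .hematotox_cache[[name]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "hematotox")
  if (!nzchar(path)) abort(paste0("config file not found: ", name))
  cfg <- yaml::read_yaml(path)
  assign(name, cfg, envir = .hematotox_cache)
  cfg
}

# packaged configs are read once per session; objective evaluations inside
# the optimizer must not touch the filesystem
.hematotox_cache <- new.env(parent = emptyenv())

# individual (per-patient) parameter names, in the order of the compiled model
INDIVIDUAL_PARAMS <- c(
  "b_S_act", "b_A_CM", "b_MKC64", "w_PLC", "d_Osteo_loss",
  "PD_oxali", "PD_5FU", "PD_iri", "PD_doc"
)

# model constants following the individual block in the parameter vector
MODEL_CONSTANTS <- c(
  "ANC_nor", "PLT_nor", "LYM_nor", "MON_nor", "k_S", "b_MKC_S", "k_O", "k_D",
  "k_CMP", "k_Gp", "k_mat", "k_ANC", "b_G_amp", "k_CM", "k_pl", "k_PPT",
  "k_e", "k_Lp", "k_L", "k_MON", "h_TPO", "s_TPO", "k_G_ren", "k_G_anc",
  "k_T_ren", "w_mkc", "f_kill_S", "f_kill_O", "f_kill_L", "z_min", "z_max",
  "plt_prod_scale",
  "w_gran_oxa", "w_gran_fu", "w_gran_iri", "w_gran_doc",
  "w_thr_oxa", "w_thr_fu", "w_thr_iri", "w_thr_doc"
)

PK_DRUGS <- c("oxaliplatin", "fluorouracil", "irinotecan", "docetaxel")

#' Default model parameters
#'
#' Assembles the full parameter set of the hematopoiesis model: population
#' constants (normal counts, transit and clearance rates, cytokine kinetics,
#' regulation clamps), the per-patient parameters at their population centres
#' (G-CSF/TPO sensitivities, TPO clearance capacity `w_PLC`, osteoblast-loss
#' rate, and the per-drug linear kill coefficients), and the compartmental PK
#' constants of all four cytotoxic drugs.
#'
#' @param overrides named list of values replacing defaults (e.g.
#'   `list(b_S_act = 1.4)`); PK constants are addressed as
#'   `pk.<drug>.<constant>` is not supported here — pass a modified `pk`
#'   element instead.
#' @return an object of class `hematotox_params`: a list with elements
#'   `individual`, `constants` and `pk`
#' @examples
#' p <- default_parameters(list(w_PLC = 2.5))
#' p$individual$w_PLC
#' @export
default_parameters <- function(overrides = list()) {
  cfg <- hematotox_config("model")
  constants <- cfg$model
  constants$k_e <- 10 / constants$tau_PLT
  individual <- cfg$individual
  pk <- hematotox_config("pk")$pk

  for (nm in names(overrides)) {
    if (nm %in% names(individual)) {
      individual[[nm]] <- overrides[[nm]]
    } else if (nm %in% names(constants)) {
      constants[[nm]] <- overrides[[nm]]
      if (nm == "tau_PLT") constants$k_e <- 10 / overrides[[nm]]
    } else if (nm == "pk") {
      pk <- modifyList(pk, overrides$pk)
    } else {
      abort(paste0("unknown parameter: ", nm))
    }
  }
  params <- structure(
    list(individual = individual, constants = constants, pk = pk),
    class = "hematotox_params"
  )
  validate_parameters(params)
  params
}

validate_parameters <- function(params) {
  ind <- unlist(params$individual)
  if (any(!is.finite(ind)) || any(ind < 0)) {
    abort("individual parameters must be finite and non-negative")
  }
  con <- params$constants
  num <- unlist(con[MODEL_CONSTANTS])
  if (any(!is.finite(num)) || any(num < 0)) {
    abort("model constants must be finite and non-negative")
  }
  if (!(con$z_min <= 1 && 1 <= con$z_max)) {
    abort("regulation clamps must satisfy z_min <= 1 <= z_max")
  }
  for (d in PK_DRUGS) {
    m <- params$pk[[d]]
    ks <- unlist(m[c("k10", "k12", "k21", "k13", "k31")])
    if (m$central_volume <= 0 || any(ks < 0)) {
      abort(paste0("invalid PK constants for ", d))
    }
  }
  invisible(params)
}

#' Update the individual parameters of a parameter set
#'
#' @param params `hematotox_params`
#' @param theta named numeric vector of individual parameters
#' @return updated `hematotox_params`
#' @export
set_individual <- function(params, theta) {
  stopifnot(inherits(params, "hematotox_params"))
  bad <- setdiff(names(theta), INDIVIDUAL_PARAMS)
  if (length(bad)) abort(paste0("unknown individual parameters: ", toString(bad)))
  params$individual[names(theta)] <- as.list(unname(theta))
  validate_parameters(params)
  params
}

# flat numeric vector in the order the compiled right-hand side expects;
# the trailing six slots are the chunk-constant input rates
param_vector <- function(params, rates = numeric(6)) {
  con <- params$constants
  pk <- params$pk
  v <- c(
    unlist(params$individual[INDIVIDUAL_PARAMS]),
    unlist(con[MODEL_CONSTANTS[1:40]]),
    with(pk$oxaliplatin, c(central_volume, k10, k12, k21, k13, k31)),
    with(pk$fluorouracil, c(central_volume, k10, k12, k21)),
    with(pk$irinotecan, c(central_volume, k10, k12, k21, k13, k31)),
    with(pk$docetaxel, c(central_volume, k10, k12, k21, k13, k31)),
    rates
  )
  stopifnot(length(v) == 77L)
  unname(v)
}

state_names <- function() {
  c("S", "O", "D", "CMP", "Gp", paste0("M", 1:4), "ANC", "CM",
    paste0("K", c(2, 4, 8, 16, 32, 64)), "PPT", paste0("P", 1:10),
    "Lp", "LYM", "MON", "G", "T",
    paste0("oxa", 1:3), paste0("fu", 1:2), paste0("iri", 1:3), paste0("doc", 1:3))
}
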