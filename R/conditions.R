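#' Solution conditions for in-situ Gibbs energy calculations
#'
#' Holds temperature, per-species molalities and pH. pH sets the proton
#' activity directly (a_H+ = 10^-pH); all other dissolved species get
#' activities a_i = gamma_i * (C_i / C_i_theta) with the standard-state
#' concentration C_i_theta fixed at 1 molal. If `ionic_strength` is omitted
#' it is computed as I = 1/2 * sum(C_i * z_i^2) over the charged species in
#' `concentrations`.
#'
#' @param concentrations named numeric vector of molalities (mol/kg).
#' @param pH dimensionless; default 8.0 (bicarbonate-buffered seawater-like
#'   medium).
#' @param temperature Kelvin; default 298.15. The pinned formation energies
#'   are 25 C values, so a warning is issued more than a few degrees away.
#' @param ionic_strength mol/kg, optional override.
#' @return object of class `ecophys_conditions`.
#' @export
solution_conditions <- function(concentrations = numeric(), pH = 8,
                                temperature = 298.15, ionic_strength = NULL) {
  stopifnot(is.numeric(concentrations))
  if (length(concentrations) && is.null(names(concentrations))) {
    stop("concentrations must be a named vector")
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (abs(temperature - T_REF_K) > 5) {
    warning("reference data are 25 C values; results at ",
            round(temperature, 1), " K are an extrapolation")
  }
  if (!is.null(ionic_strength) && ionic_strength < 0) {
    stop("ionic strength must be >= 0")
  }
  structure(list(concentrations = concentrations, pH = pH,
                 temperature = temperature, ionic_strength = ionic_strength),
            class = "ecophys_conditions")
}

#' Ionic strength of a solution
#'
#' Returns the stored override when present, otherwise
#' I = 1/2 * sum(C_i * z_i^2) over charged species.
#'
#' @param conditions an `ecophys_conditions`.
#' @param species species table supplying charges.
#' @return mol/kg.
#' @export
ionic_strength <- function(conditions, species = species_data()) {
  if (!is.null(conditions$ionic_strength)) return(conditions$ionic_strength)
  conc <- conditions$concentrations
  if (!length(conc)) return(0)
  z <- vapply(names(conc), function(sp) .species_row(sp, species)$charge, 0)
  0.5 * sum(conc * z^2)
}

#' Default seawater-like experimental conditions
#'
#' The medium conditions of the culturing experiments: air-saturated oxygen
#' (205 umol/kg at 25 C), seawater bicarbonate (2 mmol/kg), composite
#' dissolved organic carbon at 66.6 umol C/kg, thiosulfate at the
#' experimental 100 umol/kg, seawater sulfate (28 mmol/kg), oxic-seawater
#' sulfide (0.5 nmol/kg), pH 8.0 and a fixed seawater ionic strength of
#' 0.7 mol/kg.
#'
#' @param pH,ionic_strength overrides for the two quantities the experiments
#'   did not pin down exactly.
#' @param ... further arguments passed to [solution_conditions()], e.g.
#'   `concentrations` to replace the default set.
#' @return an `ecophys_conditions`.
#' @export
seawater_conditions <- function(pH = 8, ionic_strength = 0.7, ...) {
  args <- list(...)
  if (is.null(args$concentrations)) {
    args$concentrations <- c("O2" = 205e-6, "HCO3-" = 2e-3, "DOC" = 66.6e-6,
                             "S2O3-2" = 100e-6, "SO4-2" = 28e-3,
                             "HS-" = 0.5e-9)
  }
  do.call(solution_conditions,
          c(args, list(pH = pH, ionic_strength = ionic_strength)))
}

#' Read solution conditions from a key-value TSV file
#'
#' Two tab-separated columns `key` and `value`; recognized keys are
#' `temperature_C`, `pH`, `ionic_strength` and `conc.<species>` entries
#' giving molalities.
#'
#' @param path file path.
#' @return an `ecophys_conditions`.
#' @export
read_conditions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  kv <- stats::setNames(as.numeric(tab$value), tab$key)
  conc_keys <- grep("^conc\\.", names(kv), value = TRUE)
  conc <- stats::setNames(as.numeric(kv[conc_keys]),
                          sub("^conc\\.", "", conc_keys))
  solution_conditions(
    concentrations = conc,
    pH = if ("pH" %in% names(kv)) kv[["pH"]] else 8,
    temperature = if ("temperature_C" %in% names(kv)) kv[["temperature_C"]] + 273.15 else 298.15,
    ionic_strength = if ("ionic_strength" %in% names(kv)) kv[["ionic_strength"]] else NULL
  )
}
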