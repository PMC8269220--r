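#' Convert chlorinity to practical salinity
#'
#' S (permil) = 1.80655 x Cl (g/kg), the Knudsen-style conversion used for
#' artificial seawater media.
#'
#' @param chlorinity g Cl per kg solution, >= 0.
#' @return salinity in permil.
#' @examples
#' salinity_from_chlorinity(19.374)  # 35.0, open-ocean seawater
#' @export
salinity_from_chlorinity <- function(chlorinity) {
  if (any(chlorinity < 0)) stop("chlorinity must be >= 0")
  SALINITY_PER_CHLORINITY * chlorinity
}

#' Salinity of a medium amended with NaCl
#'
#' Adding p % (w/v) NaCl means 10 p g NaCl per litre; with solution density
#' taken as 1 kg/L this adds 10 p x 35.453/58.443 g/kg of chlorinity, which
#' converts to salinity and is added to the base-medium salinity. The series
#' is affine in the percentage with slope
#' 1.80655 x 10 x 35.453/58.443 = 10.96 permil per % w/v.
#'
#' @param base_salinity permil of the unamended medium.
#' @param nacl_percent_wv added NaCl in % w/v, >= 0 (vectorized).
#' @return salinity in permil.
#' @examples
#' nacl_series(8.66, c(0, 2.5, 5))
#' @export
nacl_series <- function(base_salinity, nacl_percent_wv) {
  if (base_salinity < 0) stop("base salinity must be >= 0")
  if (any(nacl_percent_wv < 0)) stop("NaCl percentage must be >= 0")
  added_cl <- 10 * nacl_percent_wv * CL_MASS_FRACTION_NACL # g/kg chlorinity
  base_salinity + salinity_from_chlorinity(added_cl)
}

#' Major-ion composition of a medium
#'
#' Bookkeeping object for proportional-dilution salinity series. Salinity is
#' taken from `base_salinity` when given, otherwise computed from the
#' chlorine mass via the chlorinity conversion.
#'
#' @param ions named numeric vector, g per kg solution (names are ion
#'   labels; `"Cl"` is used for chlorinity when no base salinity is given).
#' @param base_salinity optional permil of the full-strength composition.
#' @return object of class `ecophys_ions`.
#' @export
ion_composition <- function(ions = numeric(), base_salinity = NULL) {
  if (any(ions < 0)) stop("ion masses must be >= 0")
  sal <- if (!is.null(base_salinity)) {
    base_salinity
  } else if ("Cl" %in% names(ions)) {
    salinity_from_chlorinity(ions[["Cl"]])
  } else {
    stop("need either base_salinity or a Cl entry")
  }
  structure(list(ions = ions, base_salinity = sal), class = "ecophys_ions")
}

#' Salinity series from proportional dilution of all major ions
#'
#' Diluting every major ion by a common factor scales salinity linearly, so
#' the series is exactly factor x salinity(full strength).
#'
#' @param full_strength an [ion_composition()] or a plain salinity (permil).
#' @param dilution_factors numeric factors in (0, 1].
#' @return salinities in permil.
#' @examples
#' proportional_series(34.8, c(1, 0.5, 0.36 / 34.8))
#' @export
proportional_series <- function(full_strength, dilution_factors) {
  sal <- if (inherits(full_strength, "ecophys_ions")) {
    full_strength$base_salinity
  } else {
    full_strength
  }
  if (sal < 0) stop("salinity must be >= 0")
  if (any(dilution_factors <= 0) || any(dilution_factors > 1)) {
    stop("dilution factors must lie in (0, 1]")
  }
  dilution_factors * sal
}
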