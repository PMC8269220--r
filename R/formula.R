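#' Parse a chemical formula string into element counts
#'
#' Understands Hill-style formula strings such as `"C6H12O6"`, `"S2O3"` or
#' `"HCO3"`. Counts may be fractional (e.g. `"CH2.26O"`), which is how
#' composite organic-carbon pseudo-species with a prescribed nominal oxidation
#' state of carbon are written.
#'
#' @param formula a single formula string, or an already-parsed named numeric
#'   vector of element counts (returned unchanged).
#' @return named numeric vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CH2.26O")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  elem <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  num <- sub("^[A-Z][a-z]?", "", parts)
  count <- ifelse(nzchar(num), as.numeric(num), 1)
  if (anyNA(count) || any(count < 0)) stop("cannot parse formula: ", formula)
  out <- tapply(count, elem, sum)
  counts <- as.numeric(out)
  names(counts) <- names(out)
  if (all(counts == 0)) stop("formula has no atoms: ", formula)
  counts
}

#' Nominal oxidation state of carbon (NOSC)
#'
#' For a compound C_a H_b N_c O_d P_e S_f with net charge Z,
#' \deqn{NOSC = 4 - \frac{-Z + 4a + b - 3c - 2d + 5e - 2f}{a}.}
#' NOSC ranges from -4 (methane, fully reduced carbon) to +4 (CO2, fully
#' oxidized) and predicts the Gibbs energy of oxidation of the compound.
#'
#' @param formula formula string or named element-count vector.
#' @param charge net charge in elementary units (default 0).
#' @return NOSC, dimensionless.
#' @examples
#' nosc("CH4")            # -4
#' nosc("CO2")            # +4
#' nosc("C6H12O6")        #  0
#' nosc("C2H3O2", -1)     #  0 (acetate)
#' @export
nosc <- function(formula, charge = 0) {
  counts <- parse_formula(formula)
  pick <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  a <- pick("C")
  if (a < 1) stop("NOSC is undefined for carbon-free compounds")
  z <- charge
  4 - (-z + 4 * a + pick("H") - 3 * pick("N") - 2 * pick("O") +
         5 * pick("P") - 2 * pick("S")) / a
}
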