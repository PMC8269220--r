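#' Medium recipe of organic compounds
#'
#' A table of organic compounds with formula, charge and concentration, used
#' to characterize the dissolved organic carbon of a defined growth medium by
#' its carbon-weighted mean nominal oxidation state.
#'
#' @param compounds data frame with columns `compound`, `formula`, `charge`,
#'   `concentration` (mol/kg).
#' @return object of class `ecophys_recipe`.
#' @export
medium_recipe <- function(compounds) {
  needed <- c("compound", "formula", "charge", "concentration")
  if (!all(needed %in% names(compounds))) {
    stop("recipe needs columns: ", paste(needed, collapse = ", "))
  }
  if (!nrow(compounds)) stop("empty medium recipe")
  if (any(compounds$concentration < 0)) stop("concentrations must be >= 0")
  structure(as.data.frame(compounds), class = c("ecophys_recipe", "data.frame"))
}

#' Read a medium recipe from TSV
#'
#' @param path file with columns `compound`, `formula`, `charge`,
#'   `concentration`.
#' @return an `ecophys_recipe`.
#' @export
read_medium_recipe <- function(path) {
  medium_recipe(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Carbon-weighted mean NOSC of a medium recipe
#'
#' Each compound contributes its NOSC weighted by its molar carbon
#' concentration (concentration times carbon atoms per formula), i.e.
#' sum(C_i a_i NOSC_i) / sum(C_i a_i). The composite therefore always lies
#' within the range of the component NOSC values.
#'
#' @param recipe an `ecophys_recipe` (or compatible data frame).
#' @return list with `nosc` (dimensionless composite NOSC) and
#'   `carbon_molality` (total mol C/kg).
#' @export
medium_nosc <- function(recipe) {
  if (!nrow(recipe)) stop("empty medium recipe")
  per <- lapply(seq_len(nrow(recipe)), function(i) {
    counts <- parse_formula(recipe$formula[i])
    a <- if ("C" %in% names(counts)) counts[["C"]] else 0
    if (a < 1) {
      return(list(carbon = 0, weighted = 0))
    }
    n <- nosc(counts, recipe$charge[i])
    c_mol <- recipe$concentration[i] * a
    list(carbon = c_mol, weighted = c_mol * n)
  })
  carbon <- sum(vapply(per, `[[`, 0, "carbon"))
  if (carbon <= 0) stop("recipe contains no carbon-bearing compound")
  list(nosc = sum(vapply(per, `[[`, 0, "weighted")) / carbon,
       carbon_molality = carbon)
}
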