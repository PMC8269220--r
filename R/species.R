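#' Read a table of chemical species thermodynamic data
#'
#' The table must have columns `name`, `formula` (Hill-notation string),
#' `charge`, `dGf0_kJ_mol` (standard molal Gibbs energy of formation at
#' 25 C, 1 bar), `ion_size_A` (Debye-Huckel a-ring parameter in Angstrom;
#' `NA` for neutral or pure-phase species) and `phase`
#' (`aqueous`, `liquid` or `gas`).
#'
#' @param path file path; defaults to the reference compilation shipped with
#'   the package (SUPCRT92-consistent 25 C values).
#' @return data frame of class `ecophys_species`.
#' @export
read_species_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_thermo.tsv", package = "ecophys")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "formula", "charge", "dGf0_kJ_mol", "ion_size_A", "phase")
  if (!all(needed %in% names(tab))) {
    stop("species table must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(tab$name)) stop("duplicated species names in table")
  rownames(tab) <- tab$name
  class(tab) <- c("ecophys_species", "data.frame")
  tab
}

## Cached copy of the packaged reference data; reading it is cheap but this
## avoids repeated disk access in tight simulation loops.
.species_cache <- new.env(parent = emptyenv())

#' Pinned 25 C reference thermodynamic data
#'
#' @return the packaged species table (see [read_species_table()]).
#' @export
species_data <- function() {
  if (is.null(.species_cache$tab)) .species_cache$tab <- read_species_table()
  .species_cache$tab
}

.species_row <- function(name, species) {
  i <- match(name, species$name)
  if (is.na(i)) stop("unknown species: ", name)
  species[i, , drop = FALSE]
}

#' Add a species to a species table
#'
#' Used for pseudo-species such as composite dissolved organic carbon.
#'
#' @param species a species table.
#' @param name,formula,charge,dGf0_kJ_mol,ion_size_A,phase fields of the new
#'   species (see [read_species_table()]).
#' @return the augmented table.
#' @export
add_species <- function(species, name, formula, charge, dGf0_kJ_mol,
                        ion_size_A = NA_real_, phase = "aqueous") {
  if (name %in% species$name) stop("species already present: ", name)
  parse_formula(formula) # validates
  row <- data.frame(name = name, formula = formula, charge = charge,
                    dGf0_kJ_mol = dGf0_kJ_mol, ion_size_A = ion_size_A,
                    phase = phase, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(species), row)
  rownames(out) <- out$name
  class(out) <- c("ecophys_species", "data.frame")
  out
}
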