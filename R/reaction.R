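#' Define a chemical reaction by signed stoichiometry
#'
#' Products carry positive coefficients, reactants negative. Unless
#' `check = FALSE`, element and charge balance are verified against the
#' species table (to a numeric tolerance, so fractional composite-carbon
#' stoichiometries are allowed) and an informative error reports the
#' per-element residuals of an unbalanced reaction.
#'
#' @param stoichiometry named numeric vector: species name -> signed
#'   coefficient.
#' @param n_electrons electrons transferred per formula reaction (mol e-);
#'   must be > 0 for redox reactions.
#' @param species species table, default [species_data()].
#' @param check verify element/charge balance (default `TRUE`).
#' @return object of class `ecophys_reaction`.
#' @examples
#' thiosulfate_oxidation()
#' @export
reaction <- function(stoichiometry, n_electrons = 0, species = species_data(),
                     check = TRUE) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)),
            all(nzchar(names(stoichiometry))))
  if (anyDuplicated(names(stoichiometry))) stop("duplicated species in stoichiometry")
  if (n_electrons < 0) stop("n_electrons must be >= 0")
  rxn <- structure(list(stoichiometry = stoichiometry,
                        n_electrons = n_electrons),
                   class = "ecophys_reaction")
  if (check) check_balance(rxn, species)
  rxn
}

#' Check element and charge balance of a reaction
#'
#' @param rxn an `ecophys_reaction`.
#' @param species species table.
#' @param tol numeric tolerance on residuals (accommodates fractional
#'   composite stoichiometry).
#' @return invisibly `TRUE`; errors with per-element residuals otherwise.
#' @export
check_balance <- function(rxn, species = species_data(), tol = 1e-6) {
  nu <- rxn$stoichiometry
  elements <- list()
  charge <- 0
  for (sp in names(nu)) {
    row <- .species_row(sp, species)
    counts <- parse_formula(row$formula)
    for (el in names(counts)) {
      elements[[el]] <- (if (is.null(elements[[el]])) 0 else elements[[el]]) +
        nu[[sp]] * counts[[el]]
    }
    charge <- charge + nu[[sp]] * row$charge
  }
  res <- unlist(elements)
  bad <- abs(res) > tol
  if (any(bad) || abs(charge) > tol) {
    msg <- c(
      if (any(bad)) paste0("element ", names(res)[bad], ": residual ",
                           signif(res[bad], 6)),
      if (abs(charge) > tol) paste0("charge: residual ", signif(charge, 6))
    )
    stop("reaction is not balanced\n  ", paste(msg, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Aerobic thiosulfate oxidation to sulfate
#'
#' S2O3^2- + 2 O2(aq) + H2O -> 2 SO4^2- + 2 H+, an 8-electron oxidation:
#' the lithotrophic catabolism tested experimentally with thiosulfate as the
#' sole electron donor.
#'
#' @param species species table.
#' @return an `ecophys_reaction`.
#' @export
thiosulfate_oxidation <- function(species = species_data()) {
  reaction(c("S2O3-2" = -1, "O2" = -2, "H2O" = -1, "SO4-2" = 2, "H+" = 2),
           n_electrons = 8, species = species)
}

#' @export
print.ecophys_reaction <- function(x, ...) {
  nu <- x$stoichiometry
  side <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                   paste0(signif(abs(v), 6), " ", names(v))),
                            collapse = " + ")
  cat(side(nu[nu < 0]), "->", side(nu[nu > 0]), "\n")
  cat("electrons transferred:", x$n_electrons, "\n")
  invisible(x)
}

#' Read a reaction from a two-column TSV file
#'
#' Expected format: a comment line `# n_electrons = <number>` followed by a
#' header `species<TAB>coefficient` and one row per species with signed
#' coefficients (products positive).
#'
#' @param path file path.
#' @param species species table used for balance checking.
#' @return an `ecophys_reaction`.
#' @export
read_reaction <- function(path, species = species_data()) {
  lines <- readLines(path)
  ne_line <- grep("^#\\s*n_electrons", lines, value = TRUE)
  if (!length(ne_line)) stop("reaction file lacks '# n_electrons = <n>' line")
  ne <- as.numeric(sub("^#\\s*n_electrons\\s*=\\s*", "", ne_line[1]))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  nu <- stats::setNames(as.numeric(tab$coefficient), tab$species)
  reaction(nu, n_electrons = ne, species = species)
}
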