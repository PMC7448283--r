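# Package-level cache for constant tables read from inst/extdata.
.nodulomics <- new.env(parent = emptyenv())

#' Monoisotopic mass constants
#'
#' Returns the set of monoisotopic atomic masses (Da) used by every mass
#' computation in the package, together with the proton and electron masses.
#' Atomic masses are IUPAC monoisotopic values to at least six decimals,
#' shipped as a versioned plain-text table. The proton mass is derived as
#' H atom mass minus electron mass, which matters at the sub-ppm level for
#' Orbitrap-class accuracy.
#'
#' @return A list with elements `atomic` (named numeric vector of atomic
#'   masses, Da), `proton` (Da) and `electron` (Da).
#' @examples
#' mc <- mass_constants()
#' mc$proton          # 1.007276...
#' mc$atomic[["Na"]]  # 22.98977...
#' @export
mass_constants <- function() {
  if (is.null(.nodulomics$constants)) {
    path <- system.file("extdata", "atomic_masses.tsv", package = "nodulomics",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             colClasses = c("character", "numeric"))
    atomic <- stats::setNames(tab$mass, tab$element)
    electron <- 0.00054857990907
    proton <- atomic[["H"]] - electron
    stopifnot(abs(proton - 1.007276) < 1e-6)  # consistency assertion
    .nodulomics$constants <- list(atomic = atomic, proton = proton,
                                  electron = electron)
  }
  .nodulomics$constants
}

#' Built-in amino-acid residue table
#'
#' The 20 proteinogenic residues plus ornithine (Orn, found in tyrocidines),
#' each with its residue formula (the -H2O form that appears inside a peptide
#' chain) and its monoisotopic mass computed from that formula. Residue masses
#' are always derived from the formula, never stored independently, so the
#' residue table and the elemental constants cannot drift apart.
#'
#' D- and L-residues are mass-identical and are not distinguished here.
#'
#' @return A data.frame with columns `name`, `one_letter` (`NA` where no
#'   standard symbol exists), `formula` and `mass` (Da).
#' @examples
#' rt <- residue_table()
#' rt[rt$name == "Gly", "mass"]  # 57.02146
#' @export
residue_table <- function() {
  if (is.null(.nodulomics$residues)) {
    path <- system.file("extdata", "residue_formulas.tsv",
                        package = "nodulomics", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             colClasses = "character")
    tab$one_letter[tab$one_letter == "-"] <- NA_character_
    tab$mass <- vapply(tab$formula,
                       function(f) formula_mz(parse_formula(f), z = 0),
                       numeric(1), USE.NAMES = FALSE)
    .nodulomics$residues <- tab
  }
  .nodulomics$residues
}

# Resolve residue identifiers (3-letter names or one-letter symbols) to rows
# of residue_table(); errors on unknown residues, naming them.
resolve_residues <- function(residues) {
  tab <- residue_table()
  idx <- match(residues, tab$name)
  one <- match(residues, tab$one_letter)
  idx[is.na(idx)] <- one[is.na(idx)]
  if (anyNA(idx)) {
    stop("unknown residue(s): ",
         paste(unique(residues[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}
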