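#' Specify a peptide for mass computation
#'
#' A peptide is an ordered residue list plus terminal state. Linear peptides
#' may carry an N-terminal formyl cap and/or a C-terminal ethanolamide cap
#' (both found in gramicidin-family nonribosomal peptides); cyclic peptides
#' (e.g. tyrocidines) have no termini and therefore admit no terminal
#' modifications. Stereochemistry is not represented: D- and L-residues are
#' mass-identical.
#'
#' @param residues Character vector of residue names (3-letter, e.g. `"Ile"`)
#'   or one-letter symbols, N- to C-terminus.
#' @param n_term `"free"` or `"formyl"`.
#' @param c_term `"free-acid"` or `"ethanolamide"`.
#' @param cyclic Logical; cyclic backbone (head-to-tail, no water).
#' @return A `peptide_spec` object.
#' @examples
#' peptide_spec(c("Val", "Orn", "Leu"), cyclic = FALSE)
#' britacidin_a()
#' @export
peptide_spec <- function(residues, n_term = c("free", "formyl"),
                         c_term = c("free-acid", "ethanolamide"),
                         cyclic = FALSE) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  if (length(residues) < 1L) stop("peptide needs at least one residue")
  if (cyclic && (n_term != "free" || c_term != "free-acid")) {
    stop("cyclic peptides cannot carry terminal modifications")
  }
  rows <- resolve_residues(residues)  # errors on unknown residues
  structure(list(residues = rows$name, n_term = n_term, c_term = c_term,
                 cyclic = cyclic),
            class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  if (x$cyclic) {
    cat("cyclo[", paste(x$residues, collapse = "-"), "]\n", sep = "")
  } else {
    pre <- if (x$n_term == "formyl") "formyl-" else ""
    post <- if (x$c_term == "ethanolamide") "-ethanolamide" else ""
    cat(pre, paste(x$residues, collapse = "-"), post, "\n", sep = "")
  }
  invisible(x)
}

# Elemental formula of the neutral peptide.
peptide_formula <- function(p) {
  stopifnot(inherits(p, "peptide_spec"))
  rows <- resolve_residues(p$residues)
  args <- lapply(rows$formula, parse_formula)
  f <- do.call(combine_formulas, args)
  if (!p$cyclic) {
    f <- combine_formulas(f, parse_formula("H2O"))
    if (p$n_term == "formyl") f <- combine_formulas(f, parse_formula("CO"))
    if (p$c_term == "ethanolamide") {
      f <- combine_formulas(f, parse_formula("C2H5N"))
    }
  }
  f
}

#' Neutral monoisotopic mass of a peptide
#'
#' Linear free-termini mass is the residue-mass sum plus one water; an
#' N-formyl cap adds CO; a C-terminal ethanolamide replaces the C-terminal
#' OH by NH-CH2-CH2-OH (net +C2H5N); a cyclic backbone is the bare residue
#' sum (no water).
#'
#' @param p A [peptide_spec()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass(peptide_spec("Gly"))  # 75.03203
#' peptide_neutral_mass(britacidin_a())       # 2042.1757
#' @export
peptide_neutral_mass <- function(p) {
  formula_mz(peptide_formula(p), z = 0L)
}

#' Britacidin A peptide specification
#'
#' The 17-residue linear gramicidin-family nonribosomal peptide produced by
#' Brevibacillus brevis Ag35: isoleucine at position 1, extra Ala/Val at
#' positions 7 and 8, tyrosine at position 11, N-formyl and C-terminal
#' ethanolamide caps. Exact neutral mass 2042.1757 Da.
#' @return A `peptide_spec`.
#' @export
britacidin_a <- function() {
  peptide_spec(c("Ile", "Gly", "Ala", "Leu", "Ala", "Val", "Ala", "Val",
                 "Val", "Val", "Tyr", "Leu", "Trp", "Leu", "Trp", "Leu",
                 "Trp"),
               n_term = "formyl", c_term = "ethanolamide")
}

#' Gramicidin A peptide specification
#'
#' The canonical 15-residue linear NRP from B. brevis (valine gramicidin A),
#' formyl/ethanolamide capped; the structural reference for britacidin.
#' @return A `peptide_spec`.
#' @export
gramicidin_a <- function() {
  peptide_spec(c("Val", "Gly", "Ala", "Leu", "Ala", "Val", "Val", "Val",
                 "Trp", "Leu", "Trp", "Leu", "Trp", "Leu", "Trp"),
               n_term = "formyl", c_term = "ethanolamide")
}

#' Tyrocidine A peptide specification
#'
#' The cyclic decapeptide from B. brevis; ornithine at position 2.
#' Neutral mass 1269.6546 Da, [M+H]+ 1270.66.
#' @return A `peptide_spec`.
#' @export
tyrocidine_a <- function() {
  peptide_spec(c("Val", "Orn", "Leu", "Phe", "Pro", "Phe", "Phe", "Asn",
                 "Gln", "Tyr"),
               cyclic = TRUE)
}
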