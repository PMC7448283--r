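#' Predict backbone fragment ions of a linear peptide
#'
#' Computes a/b/x/y product-ion series for a linear peptide. b ions are
#' acylium-type N-terminal fragments (prefix residue sum plus the N-terminal
#' cap, protonated); a = b - CO. y ions are C-terminal fragments carrying the
#' C-terminal cap plus water; x = y + CO - H2. For ethanolamide-capped
#' peptides the C-terminal series retains the cap and is labelled `Y`
#' (capital), following the gramicidin-literature convention. All m/z values
#' are electron-corrected (one electron removed per charge).
#'
#' @param p A linear [peptide_spec()] (cyclic input is an error).
#' @param series Character vector from `c("a","b","x","y","Y")`. `"y"` and
#'   `"Y"` both denote the C-terminal series; the emitted label is `"Y"`
#'   when the peptide carries an ethanolamide cap, `"y"` otherwise.
#' @param max_charge Maximum fragment charge (default 1).
#' @return A data.frame with columns `series`, `index` (1-based residue count
#'   from the relevant terminus), `charge`, `mz`, `formula` (protonated-ion
#'   formula string).
#' @examples
#' head(fragment_ions(britacidin_a(), series = c("a", "b")))
#' @export
fragment_ions <- function(p, series = c("b", "y"), max_charge = 1L) {
  stopifnot(inherits(p, "peptide_spec"))
  if (p$cyclic) stop("cyclic peptides are not supported by the fragment predictor")
  series <- unique(series)
  bad <- setdiff(series, c("a", "b", "x", "y", "Y"))
  if (length(bad)) stop("unknown series: ", paste(bad, collapse = ", "))
  n <- length(p$residues)
  if (n < 2L) stop("need at least two residues to fragment")
  rows <- resolve_residues(p$residues)
  res_f <- lapply(rows$formula, parse_formula)
  H <- chem_formula(c(H = 1L))
  CO <- parse_formula("CO")
  H2O <- parse_formula("H2O")
  Ea <- parse_formula("C2H5N")
  c_label <- if (p$c_term == "ethanolamide") "Y" else "y"

  out <- list()
  add_ion <- function(ser, i, z, f) {
    f_ion <- combine_formulas(f, H, multipliers = c(1L, z))
    out[[length(out) + 1L]] <<- data.frame(
      series = ser, index = i, charge = z,
      mz = formula_mz(f_ion, z = z, n_electrons_removed = z),
      formula = format_formula(f_ion), stringsAsFactors = FALSE)
  }

  for (i in seq_len(n - 1L)) {
    # N-terminal fragments: residues 1..i (+ formyl CO if present)
    pre <- do.call(combine_formulas, res_f[seq_len(i)])
    if (p$n_term == "formyl") pre <- combine_formulas(pre, CO)
    # C-terminal fragments: residues (n-i+1)..n + H2O (+ ethanolamide cap)
    suf <- do.call(combine_formulas, res_f[seq.int(n - i + 1L, n)])
    suf <- combine_formulas(suf, H2O)
    if (p$c_term == "ethanolamide") suf <- combine_formulas(suf, Ea)
    for (z in seq_len(max_charge)) {
      if ("b" %in% series) add_ion("b", i, z, pre)
      if ("a" %in% series) {
        add_ion("a", i, z, combine_formulas(pre, CO, multipliers = c(1L, -1L)))
      }
      if (any(c("y", "Y") %in% series)) add_ion(c_label, i, z, suf)
      if ("x" %in% series) {
        xf <- combine_formulas(suf, CO, chem_formula(c(H = 2L)),
                               multipliers = c(1L, 1L, -1L))
        add_ion("x", i, z, xf)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$series, res$index, res$charge), , drop = FALSE]
}

#' Check b/y complementarity of a fragment pair
#'
#' For singly charged ions of the same peptide with indices summing to the
#' peptide length, `b_i + y_(n-i)` must equal `[M+H]+ + proton` within
#' tolerance.
#'
#' @param p The parent [peptide_spec()].
#' @param b_mz m/z of the b_i ion (1+).
#' @param y_mz m/z of the complementary y/Y_(n-i) ion (1+).
#' @param tol Absolute tolerance in Da (default 0.002).
#' @return `TRUE` iff the complementarity identity holds within `tol`.
#' @export
complementarity_check <- function(p, b_mz, y_mz, tol = 0.002) {
  mc <- mass_constants()
  mh <- adduct_mz(peptide_neutral_mass(p), adduct_spec(1L))
  abs((b_mz + y_mz) - (mh + mc$proton)) <= tol
}
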