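#' Parse an elemental formula string
#'
#' Parses strings such as `"C34H32FeN4O4"` into a named vector of element
#' counts. Parsing is case-sensitive on element symbols (an uppercase letter
#' optionally followed by one lowercase letter); a trailing charge marker
#' (e.g. `"+"`, `"2+"`, `"^+^"`) is stripped and ignored — charge is handled
#' by [formula_mz()], not by the formula itself.
#'
#' @param text A formula string.
#' @return A `chem_formula`: a named integer vector of per-element counts.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C53H71N10O7")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  # strip a trailing charge marker ("+", "2+", "^+^", "^2+^") without eating
  # a final element count: bare digits only count as charge when caret-marked
  body <- sub("(\\^[0-9]*[+-]\\^?|[+-])$", "", text)
  if (!nzchar(body)) stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  tokens <- regmatches(body, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(body)) {
    stop("cannot parse formula: ", text)
  }
  symbols <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- names(mass_constants()$atomic)
  bad <- setdiff(symbols, known)
  if (length(bad)) stop("unknown element symbol(s): ",
                        paste(bad, collapse = ", "))
  out <- tapply(counts, factor(symbols, levels = unique(symbols)), sum)
  chem_formula(stats::setNames(as.integer(out), names(out)))
}

#' Construct a chem_formula from named counts
#'
#' @param counts Named integer vector of element counts (non-negative;
#'   at least one positive).
#' @return A `chem_formula` object.
#' @export
chem_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts) == 0L || any(counts < 0L)) {
    stop("formula needs at least one element with positive count")
  }
  known <- names(mass_constants()$atomic)
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("unknown element symbol(s): ",
                        paste(bad, collapse = ", "))
  structure(as.integer(counts), names = names(counts),
            class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Format a chem_formula in Hill-like order
#' @param f A `chem_formula`.
#' @return A single string, e.g. `"C2H5N"`.
#' @export
format_formula <- function(f) {
  els <- names(f)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(f[ord] == 1L, "", f[ord]), collapse = "")
}

# Elementwise sum of formulas (and subtraction via negative multipliers).
# Intermediate negative counts are an error only if they survive in the sum.
combine_formulas <- function(..., multipliers = NULL) {
  fs <- list(...)
  if (is.null(multipliers)) multipliers <- rep(1L, length(fs))
  acc <- integer(0)
  for (i in seq_along(fs)) {
    f <- fs[[i]]
    for (el in names(f)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0L) +
        multipliers[i] * f[[el]]
    }
  }
  if (any(acc < 0L)) stop("negative element count in combined formula")
  chem_formula(acc)
}

#' m/z of an elemental formula
#'
#' Computes monoisotopic mass-to-charge for a formula, with explicit
#' electron-mass bookkeeping: removing electrons (cation formation) subtracts
#' `n_electrons_removed` electron masses before dividing by the charge. With
#' `z = 0` the neutral monoisotopic mass is returned.
#'
#' @param f A `chem_formula` (or named count vector).
#' @param z Charge (non-negative integer; 0 = neutral mass).
#' @param n_electrons_removed Electrons removed on ionization (default `z`
#'   when `z > 0`, otherwise 0 — i.e. an even-electron cation).
#' @return m/z in Da.
#' @examples
#' formula_mz(parse_formula("H2O"))                      # 18.01056
#' formula_mz(parse_formula("C34H32FeN4O4"), z = 1)      # 616.18 (heme B ion)
#' @export
formula_mz <- function(f, z = 0L, n_electrons_removed = if (z > 0L) z else 0L) {
  if (any(f < 0L)) stop("negative element counts are not allowed")
  mc <- mass_constants()
  bad <- setdiff(names(f), names(mc$atomic))
  if (length(bad)) stop("unknown element symbol(s): ",
                        paste(bad, collapse = ", "))
  m <- sum(mc$atomic[names(f)] * as.numeric(f)) -
    n_electrons_removed * mc$electron
  m / max(z, 1L)
}

#' Parts-per-million mass error
#'
#' Signed relative deviation of an observed from a theoretical m/z, in ppm.
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da; must be > 0).
#' @return Signed ppm error; take `abs()` for reporting.
#' @examples
#' ppm_error(959.5511, 959.5502)  # ~0.94 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}
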