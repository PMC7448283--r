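#' Specify an ESI adduct species
#'
#' Positive-mode electrospray adducts formed by protonation and/or sodium
#' cationization. The charge equals the number of charge carriers
#' (protons + sodiums); each sodium contributes its atomic mass minus one
#' electron mass.
#'
#' @param n_protons Number of protons (integer >= 0).
#' @param n_sodiums Number of sodium cations (integer >= 0).
#' @return An `adduct_spec` with fields `n_protons`, `n_sodiums`, `z`,
#'   `label` (e.g. `"[M+H+Na]2+"`).
#' @examples
#' adduct_spec(2, 0)  # [M+2H]2+
#' standard_adducts()[["M+H+Na"]]
#' @export
adduct_spec <- function(n_protons, n_sodiums = 0L) {
  n_protons <- as.integer(n_protons)
  n_sodiums <- as.integer(n_sodiums)
  if (n_protons < 0L || n_sodiums < 0L) stop("carrier counts must be >= 0")
  z <- n_protons + n_sodiums
  if (z < 1L) stop("adduct charge must be >= 1")
  part <- c(if (n_protons == 1L) "H" else if (n_protons > 1L)
              paste0(n_protons, "H"),
            if (n_sodiums == 1L) "Na" else if (n_sodiums > 1L)
              paste0(n_sodiums, "Na"))
  label <- paste0("[M+", paste(part, collapse = "+"), "]",
                  if (z > 1L) z else "", "+")
  structure(list(n_protons = n_protons, n_sodiums = n_sodiums, z = z,
                 label = label),
            class = "adduct_spec")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct>", x$label, "\n")
  invisible(x)
}

#' The five standard positive-mode adducts
#'
#' The proton/sodium species observed for britacidin A: `[M+H]+`, `[M+2H]2+`,
#' `[M+H+Na]2+`, `[M+2Na]2+`, `[M+Na]+`.
#'
#' @return Named list of `adduct_spec` objects; names are `"M+H"`, `"M+2H"`,
#'   `"M+H+Na"`, `"M+2Na"`, `"M+Na"`.
#' @export
standard_adducts <- function() {
  list("M+H"    = adduct_spec(1L, 0L),
       "M+2H"   = adduct_spec(2L, 0L),
       "M+H+Na" = adduct_spec(1L, 1L),
       "M+2Na"  = adduct_spec(0L, 2L),
       "M+Na"   = adduct_spec(0L, 1L))
}

# Total mass added by the adduct's charge carriers (Da, before division by z).
adduct_offset <- function(a) {
  mc <- mass_constants()
  a$n_protons * mc$proton + a$n_sodiums * (mc$atomic[["Na"]] - mc$electron)
}

#' m/z of an adduct of a neutral mass
#'
#' `m/z = (M + n_protons * m_p + n_sodiums * (m_Na - m_e)) / z`.
#'
#' @param M Neutral monoisotopic mass (Da, > 0).
#' @param a An [adduct_spec()].
#' @return m/z in Da.
#' @examples
#' adduct_mz(2042.1757, adduct_spec(1))  # 2043.1830
#' @export
adduct_mz <- function(M, a) {
  stopifnot(inherits(a, "adduct_spec"))
  if (any(M <= 0)) stop("neutral mass must be positive")
  (M + adduct_offset(a)) / a$z
}

#' Neutral mass implied by an observed adduct ion
#'
#' Exact algebraic inverse of [adduct_mz()].
#'
#' @param mz Observed m/z (Da).
#' @param a An [adduct_spec()].
#' @return Implied neutral monoisotopic mass (Da).
#' @examples
#' neutral_from_adduct(2043.1830, adduct_spec(1))     # 2042.1757
#' neutral_from_adduct(635.83, adduct_spec(2))        # ~1269.645 (tyrocidine A)
#' @export
neutral_from_adduct <- function(mz, a) {
  stopifnot(inherits(a, "adduct_spec"))
  M <- mz * a$z - adduct_offset(a)
  if (any(M <= 0)) stop("non-physical neutral mass (<= 0) implied by adduct")
  M
}
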