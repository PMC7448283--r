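#' Construct an MS2 spectrum record
#'
#' A minimal container for a centroided peak list with precursor metadata.
#' Peaks are stored sorted ascending by m/z.
#'
#' @param mz Numeric vector of peak m/z values (Da).
#' @param intensity Numeric vector of intensities (>= 0); recycled to 1 if
#'   omitted.
#' @param precursor_mz Precursor m/z (Da) or `NA`.
#' @param precursor_z Precursor charge or `NA` (unknown).
#' @param collision_energy Metadata string, e.g. `"NCE 15"`.
#' @return A `spectrum_record`.
#' @export
spectrum_record <- function(mz, intensity = NULL, precursor_mz = NA_real_,
                            precursor_z = NA_integer_,
                            collision_energy = NA_character_) {
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  if (length(intensity) != length(mz)) stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  ord <- order(mz)
  structure(list(peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
                 precursor_mz = precursor_mz,
                 precursor_z = as.integer(precursor_z),
                 collision_energy = collision_energy),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat("<spectrum>", nrow(x$peaks), "peaks; precursor m/z",
      format(x$precursor_mz), "\n")
  invisible(x)
}

#' Read a two-column delimited peak list
#'
#' Reads `m/z<TAB>intensity` (header optional, `#` comments allowed) into a
#' [spectrum_record()].
#'
#' @param path File path.
#' @param ... Passed on to [spectrum_record()] (precursor metadata).
#' @return A `spectrum_record`.
#' @export
read_peak_list <- function(path, ...) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("mz", "intensity"),
                           colClasses = "character")
  keep <- grepl("^[0-9.eE+-]+$", tab$mz)
  spectrum_record(as.numeric(tab$mz[keep]), as.numeric(tab$intensity[keep]),
                  ...)
}

#' Infer charge state from isotope spacing
#'
#' The spacing between successive isotopologue peaks of a z-charged ion is
#' ~1.00335/z Da (the C13-C12 mass difference divided by charge). Given at
#' least two resolved isotope peaks of one envelope, returns
#' `z = round(1.00335 / median spacing)` with the residual spacing error.
#'
#' @param mz m/z values of >= 2 isotope peaks from one envelope.
#' @param max_z Largest charge considered (default 6).
#' @param tol Maximum tolerated deviation of any spacing from the fitted
#'   `1.00335/z` (Da, default 0.01).
#' @return List with `z` (integer) and `residual` (Da, median absolute
#'   deviation of spacings from 1.00335/z).
#' @examples
#' charge_from_isotopes(c(1022.0960, 1022.5977, 1023.0994))$z  # 2
#' @export
charge_from_isotopes <- function(mz, max_z = 6L, tol = 0.01) {
  if (length(mz) < 2L) stop("need at least two isotope peaks")
  spacing <- diff(sort(mz))
  med <- stats::median(spacing)
  z <- as.integer(round(1.00335 / med))
  if (z < 1L || z > max_z) stop("ambiguous charge: spacing ", format(med),
                                " Da outside supported range")
  dev <- abs(spacing - 1.00335 / z)
  if (any(dev > tol)) {
    stop("ambiguous charge: inconsistent isotope spacings")
  }
  list(z = z, residual = stats::median(dev))
}

#' Group MS1 ions into neutral-mass hypotheses
#'
#' Every (ion, adduct) pair whose charges agree yields an implied neutral
#' mass; implied masses are clustered by single linkage within a ppm
#' tolerance, and every cluster supported by at least two distinct ions
#' becomes a neutral-mass hypothesis. Each ion may support at most one
#' emitted hypothesis (best-scoring hypothesis wins); hypotheses are ranked
#' by mean absolute ppm error of their supporters.
#'
#' @param ions A data.frame with columns `mz` and `z` (`NA` z = unknown, all
#'   adduct charges tried).
#' @param adducts Named list of [adduct_spec()]s (default the five standard
#'   positive-mode species).
#' @param tol_ppm Clustering tolerance in ppm (default 5).
#' @return A list of hypotheses, each a list with `M` (consensus neutral
#'   mass, mean of implied masses), `supporters` (data.frame `mz`, `z`,
#'   `adduct`, `ppm`), `score` (mean |ppm|) and `ambiguous` (`TRUE` when an
#'   exactly tied alternative adduct reading exists, which happens for small
#'   proton/sodium ion sets offset by Na - H); ranked best first.
#' @examples
#' ions <- data.frame(mz = c(2043.1830, 1022.0960), z = c(1, 2))
#' group_adducts(ions)[[1]]$M  # ~2042.176
#' @export
group_adducts <- function(ions, adducts = standard_adducts(), tol_ppm = 5) {
  if (is.null(ions) || nrow(ions) == 0L) stop("empty ion list")
  if (tol_ppm <= 0) stop("tolerance must be positive")
  cand <- list()
  for (i in seq_len(nrow(ions))) {
    for (nm in names(adducts)) {
      a <- adducts[[nm]]
      if (!is.na(ions$z[i]) && ions$z[i] != a$z) next
      M <- tryCatch(neutral_from_adduct(ions$mz[i], a), error = function(e) NA)
      if (is.na(M)) next
      cand[[length(cand) + 1L]] <- data.frame(
        ion = i, mz = ions$mz[i], z = a$z, adduct = nm, M = M)
    }
  }
  if (!length(cand)) return(list())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$M), , drop = FALSE]
  # single-linkage clustering of implied masses at tol_ppm
  gap <- diff(cand$M) / cand$M[-nrow(cand)] * 1e6
  cand$cluster <- cumsum(c(1L, as.integer(gap > tol_ppm)))

  hyps <- list()
  for (cl in unique(cand$cluster)) {
    sub <- cand[cand$cluster == cl, , drop = FALSE]
    # keep one candidate per ion: the one closest to the cluster median
    medM <- stats::median(sub$M)
    sub <- sub[order(abs(sub$M - medM)), , drop = FALSE]
    sub <- sub[!duplicated(sub$ion), , drop = FALSE]
    if (nrow(sub) < 2L) next
    M_hat <- mean(sub$M)
    ppm <- vapply(seq_len(nrow(sub)), function(k) {
      ppm_error(sub$mz[k], adduct_mz(M_hat, adducts[[sub$adduct[k]]]))
    }, numeric(1))
    hyps[[length(hyps) + 1L]] <- list(
      M = M_hat,
      supporters = data.frame(mz = sub$mz, z = sub$z, adduct = sub$adduct,
                              ppm = ppm, ion = sub$ion),
      score = mean(abs(ppm)))
  }
  if (!length(hyps)) return(list())
  # Proton/sodium ladders create phantom clusters offset by +-(Na-H) from
  # the true neutral mass; the true cluster is the one explaining the most
  # ions, so rank by supporter count first, then by mean |ppm|.
  n_sup <- vapply(hyps, function(h) nrow(h$supporters), integer(1))
  hyps <- hyps[order(-n_sup, vapply(hyps, `[[`, numeric(1), "score"))]
  # enforce "each ion supports at most one hypothesis", best hypothesis
  # first. A hypothesis whose ions were all consumed is still emitted when
  # it ties the consumer exactly (same supporter count, same score): small
  # proton/sodium ion sets can be genuinely ambiguous between M and
  # M +- (Na - H), and both readings are then reported (flagged ambiguous).
  used <- integer(0)
  kept <- list()
  for (h in hyps) {
    sup <- h$supporters[!(h$supporters$ion %in% used), , drop = FALSE]
    if (nrow(sup) >= 2L) {
      used <- c(used, sup$ion)
      h$supporters <- sup[, c("mz", "z", "adduct", "ppm")]
      h$ambiguous <- FALSE
      kept[[length(kept) + 1L]] <- h
    } else if (length(kept)) {
      tied <- nrow(h$supporters) == nrow(kept[[1]]$supporters) &&
        abs(h$score - kept[[1]]$score) < 1e-6
      if (tied) {
        h$supporters <- h$supporters[, c("mz", "z", "adduct", "ppm")]
        h$ambiguous <- TRUE
        kept[[1]]$ambiguous <- TRUE
        kept[[length(kept) + 1L]] <- h
      }
    }
  }
  kept
}
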