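#' De novo sequence reconstruction by mass-ladder walking
#'
#' Walks an MS2 peak list along successive amino-acid losses: a step from one
#' peak to a higher-mass peak is accepted when the m/z difference matches a
#' residue mass within tolerance. The walk starts at any peak interpretable
#' as a first-residue terminal ion (b1-type for the N-to-C direction, y1-type
#' for C-to-N), explores ties as branches (depth-first, bounded), emits
#' mass-degenerate residues (Leu/Ile) as ambiguity classes, and — when the
#' precursor m/z is known — closes the final residue against the precursor.
#' When no single-residue step is available from a peak, a two-residue jump
#' is attempted and reported as an unresolved gap.
#'
#' Ambiguity classes are never silently resolved; supply external evidence
#' (e.g. a 13C-feeding result) via `evidence` to collapse a class to the
#' confirmed residue.
#'
#' @param spectrum A [spectrum_record()].
#' @param direction `"b"` (N-to-C, the default: the b series dominates
#'   low-energy NRP spectra) or `"y"`.
#' @param residues Residue table (default [residue_table()]).
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @param tol_floor Absolute tolerance floor in Da (default 0.002), protecting
#'   low-mass fragments.
#' @param max_branches Branch budget for the depth-first walk (default 50).
#' @param evidence Character vector of residue names confirmed by external
#'   evidence; an ambiguity class containing exactly one confirmed member is
#'   collapsed to it.
#' @return A list of sequence hypotheses ranked by explained length then
#'   cumulative |ppm|. Each hypothesis is a list with `assignments` (a list
#'   whose elements are either a character vector of residue names — length
#'   > 1 marks an ambiguity class — or an unresolved gap of class
#'   `ladder_gap` carrying the jumped mass), `ppm` (per-step signed errors),
#'   `complete` (closed against the precursor), `n_term`/`c_term`
#'   (terminal-cap interpretation) and `score` (cumulative |ppm|).
#' @examples
#' sp <- gen_ms2_spectrum(peptide_spec(c("Ile", "Gly", "Ala", "Val"),
#'                                     n_term = "formyl"), seed = 1)
#' ladder_sequence(sp)[[1]]$assignments
#' @export
ladder_sequence <- function(spectrum, direction = c("b", "y"),
                            residues = residue_table(), tol_ppm = 10,
                            tol_floor = 0.002, max_branches = 50L,
                            evidence = character()) {
  direction <- match.arg(direction)
  if (tol_ppm <= 0 || tol_floor <= 0) stop("tolerances must be positive")
  stopifnot(inherits(spectrum, "spectrum_record"))
  mz <- spectrum$peaks$mz
  if (!length(mz)) return(list())
  mc <- mass_constants()
  res_mass <- stats::setNames(residues$mass, residues$name)
  tol_at <- function(m) pmax(tol_floor, tol_ppm * 1e-6 * m)

  # candidate residue classes matching a mass difference; degenerate residues
  # (equal mass) form one class, distinct masses within tolerance are ties
  match_classes <- function(delta, tol) {
    hit <- which(abs(res_mass - delta) <= tol)
    if (!length(hit)) return(list())
    key <- round(res_mass[hit], 6)
    lapply(split(names(res_mass)[hit], key), function(nm) {
      m <- res_mass[[nm[1]]]
      list(residues = sort(nm), ppm = (delta - m) / m * 1e6)
    })
  }

  # terminal-cap offsets defining the first-residue ion interpretation
  H2O <- formula_mz(parse_formula("H2O"))
  CO <- formula_mz(parse_formula("CO"))
  EA <- formula_mz(parse_formula("C2H5N"))
  start_offsets <- if (direction == "b") {
    c(free = mc$proton, formyl = CO + mc$proton)
  } else {
    c("free-acid" = H2O + mc$proton, ethanolamide = H2O + EA + mc$proton)
  }
  close_offsets <- if (direction == "b") {
    c("free-acid" = H2O, ethanolamide = H2O + EA)
  } else {
    c(free = 0, formyl = CO)
  }

  # singly-protonated precursor equivalent, for ladder closure
  mh <- NA_real_
  if (!is.na(spectrum$precursor_mz) && !is.na(spectrum$precursor_z)) {
    z <- spectrum$precursor_z
    mh <- spectrum$precursor_mz * z - (z - 1L) * mc$proton
  }

  hyps <- new.env(parent = emptyenv())
  hyps$out <- list()
  hyps$branches <- 0L

  collapse <- function(class) {
    if (length(class$residues) > 1L) {
      conf <- intersect(class$residues, evidence)
      if (length(conf) == 1L) class$residues <- conf
    }
    class
  }

  emit <- function(path, ppm, complete, caps) {
    sig <- paste(vapply(path, function(el) {
      if (inherits(el, "ladder_gap")) sprintf("gap%.4f", el$mass)
      else paste(el, collapse = "|")
    }, character(1)), collapse = "-")
    n_expl <- sum(vapply(path, function(el)
      if (inherits(el, "ladder_gap")) 2L else 1L, integer(1)))
    if (n_expl < 2L && !complete) return(invisible())
    if (!is.null(hyps$out[[sig]]) && hyps$out[[sig]]$score <= sum(abs(ppm))) {
      return(invisible())
    }
    hyps$out[[sig]] <- list(assignments = path, ppm = ppm,
                            complete = complete,
                            n_term = caps$n_term, c_term = caps$c_term,
                            score = sum(abs(ppm)), n_explained = n_expl)
  }

  walk <- function(i, path, ppm, caps) {
    if (hyps$branches > max_branches) return(invisible())
    # closure against the precursor: last residue + closing cap
    closed <- FALSE
    if (!is.na(mh)) {
      for (cap in names(close_offsets)) {
        dc <- mh - mz[i] - close_offsets[[cap]]
        for (cl in match_classes(dc, tol_at(mh))) {
          cl <- collapse(cl)
          caps2 <- caps
          if (direction == "b") caps2$c_term <- cap else caps2$n_term <- cap
          emit(c(path, list(cl$residues)), c(ppm, cl$ppm), TRUE, caps2)
          closed <- TRUE
        }
      }
    }
    steps <- list()
    for (j in seq_along(mz)) {
      if (mz[j] <= mz[i]) next
      delta <- mz[j] - mz[i]
      for (cl in match_classes(delta, tol_at(mz[j]))) {
        steps[[length(steps) + 1L]] <- c(cl, list(j = j, gap = FALSE))
      }
    }
    if (!length(steps)) {
      # no single-residue continuation: try one two-residue jump to the
      # nearest admissible peak, reported as an unresolved gap
      for (j in seq_along(mz)) {
        if (mz[j] <= mz[i]) next
        delta <- mz[j] - mz[i]
        pair_ok <- any(abs(outer(res_mass, res_mass, "+") - delta) <=
                         tol_at(mz[j]))
        if (pair_ok) {
          steps[[length(steps) + 1L]] <- list(residues = NULL, ppm = 0,
                                              j = j, gap = TRUE,
                                              mass = delta)
          break
        }
      }
    }
    if (!length(steps)) {
      if (!closed) emit(path, ppm, FALSE, caps)
      return(invisible())
    }
    ord <- order(vapply(steps, function(s) abs(s$ppm), numeric(1)),
                 vapply(steps, function(s)
                   if (is.null(s$residues)) "~gap" else s$residues[1],
                   character(1)))
    for (s in steps[ord]) {
      hyps$branches <- hyps$branches + 1L
      if (hyps$branches > max_branches) break
      el <- if (s$gap) {
        structure(list(mass = s$mass, n_residues = 2L), class = "ladder_gap")
      } else {
        collapse(s)$residues
      }
      walk(s$j, c(path, list(el)), c(ppm, s$ppm), caps)
    }
    if (!closed && !length(steps)) emit(path, ppm, FALSE, caps)
    invisible()
  }

  for (i in seq_along(mz)) {
    for (cap in names(start_offsets)) {
      d0 <- mz[i] - start_offsets[[cap]]
      for (cl in match_classes(d0, tol_at(mz[i]))) {
        cl <- collapse(cl)
        caps <- if (direction == "b") {
          list(n_term = cap, c_term = NA_character_)
        } else {
          list(n_term = NA_character_, c_term = cap)
        }
        hyps$branches <- hyps$branches + 1L
        walk(i, list(cl$residues), cl$ppm, caps)
      }
    }
  }

  out <- unname(as.list(hyps$out))
  if (!length(out)) return(list())
  # drop hypotheses strictly contained in a longer one; rank remaining
  n_expl <- vapply(out, `[[`, integer(1), "n_explained")
  score <- vapply(out, `[[`, numeric(1), "score")
  complete <- vapply(out, `[[`, logical(1), "complete")
  out[order(-as.integer(complete), -n_expl, score)]
}

#' @export
print.ladder_gap <- function(x, ...) {
  cat(sprintf("<unresolved gap: %.4f Da, %d residues>\n", x$mass,
              x$n_residues))
  invisible(x)
}

#' Format a ladder hypothesis as a string
#'
#' @param h One hypothesis from [ladder_sequence()].
#' @return A string such as `"{Ile|Leu}-Gly-Ala-Val"`; unresolved gaps render
#'   as `"[gap 170.11]"`.
#' @export
format_hypothesis <- function(h) {
  paste(vapply(h$assignments, function(el) {
    if (inherits(el, "ladder_gap")) sprintf("[gap %.2f]", el$mass)
    else if (length(el) > 1L) paste0("{", paste(el, collapse = "|"), "}")
    else el
  }, character(1)), collapse = "-")
}
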