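# Independent oracle values and brute-force helpers. Residue and small-
# molecule masses were computed independently (IUPAC monoisotopic sums) and
# frozen here; they deliberately do not go through the package's own
# constant tables.

oracle <- list(
  H2O   = 18.0105646,
  CO    = 27.9949146,
  C2H5N = 43.0421991,
  proton = 1.00727646,
  electron = 0.00054858,
  Na = 22.98976928,
  residue = c(
    Gly = 57.02146, Ala = 71.03711, Ser = 87.03203, Pro = 97.05276,
    Val = 99.06841, Thr = 101.04768, Cys = 103.00919, Leu = 113.08406,
    Ile = 113.08406, Asn = 114.04293, Asp = 115.02694, Gln = 128.05858,
    Lys = 128.09496, Glu = 129.04259, Met = 131.04049, His = 137.05891,
    Phe = 147.06841, Arg = 156.10111, Tyr = 163.06333, Trp = 186.07931,
    Orn = 114.07931)
)

# brute-force neutral peptide mass from the frozen residue masses
oracle_peptide_mass <- function(residues, n_term = "free",
                                c_term = "free-acid", cyclic = FALSE) {
  m <- sum(oracle$residue[residues])
  if (cyclic) return(m)
  m <- m + oracle$H2O
  if (n_term == "formyl") m <- m + oracle$CO
  if (c_term == "ethanolamide") m <- m + oracle$C2H5N
  m
}

# exhaustive recursion over all monotone global alignments of two code
# lists: matched pairs score code_identity, every unmatched module costs gap
oracle_align_score <- function(qc, rc, gap) {
  if (!length(qc) || !length(rc)) {
    return(-gap * (length(qc) + length(rc)))
  }
  max(oracle_align_score(qc[-1], rc[-1], gap) + code_identity(qc[1], rc[1]),
      oracle_align_score(qc[-1], rc, gap) - gap,
      oracle_align_score(qc, rc[-1], gap) - gap)
}

# does any top-ranked ladder hypothesis match the true residue sequence,
# allowing mass-degenerate ambiguity classes (truth member of each class)?
ladder_recovers <- function(hyps, truth) {
  if (!length(hyps)) return(FALSE)
  top <- hyps[[1]]
  ties <- Filter(function(h) {
    h$complete == top$complete && h$n_explained == top$n_explained &&
      h$score <= top$score + 1e-9
  }, hyps)
  for (h in ties) {
    if (length(h$assignments) != length(truth)) next
    if (any(vapply(h$assignments, inherits, logical(1), "ladder_gap"))) next
    hit <- all(vapply(seq_along(truth), function(k) {
      truth[k] %in% h$assignments[[k]]
    }, logical(1)))
    if (hit) return(TRUE)
  }
  FALSE
}
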