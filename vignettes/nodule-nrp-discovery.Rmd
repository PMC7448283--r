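---
title: "Methods: mass arithmetic, feature attribution and community recovery in a simplified root-nodule microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass arithmetic, feature attribution and community recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulomics)
```

# Scope

`nodulomics` implements the computational backbone of a natural-product
discovery workflow in a five-member legume root-nodule community: the
nitrogen-fixing symbiont *Sinorhizobium meliloti* plus four accessory
bacteria, among them *Brevibacillus brevis* Ag35, the producer of the
gramicidin-family nonribosomal peptides (NRPs) called britacidins and of the
tyrocidines. Four analysis stages are covered — exact-mass arithmetic,
MS2 fragment prediction and ladder sequencing, nested subtractive Venn
attribution of LC-MS features, and nodule recovery/CFU statistics — plus a
seeded synthetic-data module that generates inputs with the same statistical
structure, so the entire pipeline is testable without any external data.

# Mass arithmetic

All masses are monoisotopic, built from IUPAC atomic masses stored to at
least six decimals in one shipped constant table. The electron is handled
explicitly: a cation formed by removing $n$ electrons weighs
$n \cdot m_e \approx n \cdot 0.000549$ Da less than its neutral formula,
and the proton mass is derived as $m_H - m_e$. Sub-ppm agreement with
Orbitrap-measured ions (the working accuracy throughout) is impossible
without this correction; at $m/z$ 1000 the electron alone is 0.55 ppm.

A peptide is an ordered residue list with terminal state. Residue masses
are always computed from residue formulas (the $-\mathrm{H_2O}$ form), never
stored separately, so the residue table cannot drift from the element
table. The neutral mass rules are:

* linear, free termini: $\sum_i m_i + \mathrm{H_2O}$;
* N-formyl cap: $+\mathrm{CO}$;
* C-terminal ethanolamide: the OH is replaced by NH–CH$_2$–CH$_2$–OH, a net
  $+\mathrm{C_2H_5N}$ (+43.0422 Da);
* cyclic (head-to-tail): $\sum_i m_i$, no water, and no terminal
  modifications are representable.

D- and L-residues are mass-identical and not distinguished. Ornithine is a
first-class residue (the tyrocidines need it). Positive-mode adducts are
parameterised by proton and sodium counts; each sodium contributes
$m_{Na} - m_e$ and the charge is the carrier count. With these rules the
17-residue britacidin A spec (formyl-Ile-Gly-Ala-Leu-Ala-Val-Ala-Val-Val-
Val-Tyr-Leu-Trp-Leu-Trp-Leu-Trp-ethanolamide) evaluates to 2042.1757 Da
and its five observed adduct ions to within 2 ppm of the measured values.

# Fragment prediction and ladder sequencing

For a linear NRP the b ions are acylium-type N-terminal fragments
($\sum_{1..i} m_j$ + N-terminal cap + $z$ protons, electron-corrected),
a = b − CO, and the C-terminal series carries the C-terminal cap
(y = suffix + H$_2$O + cap; x = y + CO − H$_2$). When the cap is an
ethanolamide the C-terminal series is labelled *Y*, following the
gramicidin literature. Cyclic peptides are rejected by the fragmenter:
tyrocidines are handled at intact-mass level only, which mirrors how such
compounds are verified against authentic standards rather than sequenced
de novo.

## Grouping MS1 ions into neutral masses

Every (ion, adduct) pair with matching charge implies a neutral mass;
implied masses are clustered by single linkage at 5 ppm and clusters with
at least two distinct supporting ions become hypotheses. Two numerical
choices matter:

* **Ranking is by supporter count first, then mean |ppm|.** The
  proton/sodium ladder creates phantom clusters offset by
  $\pm(m_{Na} - m_H) = \pm 21.9819$ Da whose internal spread can be
  *tighter* than the true cluster's; the true neutral mass is the reading
  that explains the most ions, not the tightest one.
* **Exact ties are reported, flagged `ambiguous`.** An ion set drawn
  entirely from $\{[M+H]^+, [M+2H]^{2+}, [M+H+Na]^{2+}\}$ (or its sodium
  mirror image) is mathematically consistent with both $M$ and
  $M \pm (m_{Na}-m_H)$, with identical error structure. Suppressing one
  reading would be arbitrary, so both are emitted and flagged. Adding any
  ion from the opposite end of the ladder breaks the tie.

## Ladder walking

The sequencer walks successive peak differences: a step is accepted when a
difference matches a residue mass within tolerance (default 10 ppm with a
0.002 Da absolute floor protecting low-mass fragments). Anchoring
interprets a peak as a first-residue terminal ion under both cap
hypotheses (free/formyl for b walks, free-acid/ethanolamide for y walks);
when the precursor is known the walk closes the final residue against it.
Ties within tolerance branch; the search is depth-first with a budget of
50 branches and deterministic ordering (lowest |ppm| first, then
alphabetical residue). When no single-residue continuation exists, one
two-residue jump to the nearest admissible peak is attempted and reported
as an unresolved gap — never silently interpolated.

Mass-degenerate residues (Leu/Ile always; Gln/Lys only at coarse
tolerance) are emitted as ambiguity classes and never auto-resolved; an
explicit `evidence` argument (standing in for orthogonal experiments such
as $^{13}$C amino-acid feeding) collapses a class to a confirmed member.
Two degeneracies couple residues to caps and are irreducible from a b
series plus precursor alone: Asp $\equiv$ Ser + CO (free vs formyl start)
and Orn $\equiv$ Ala + C$_2$H$_5$N (free-acid vs ethanolamide closure).
Hypotheses are ranked by completeness, explained residues, then cumulative
|ppm|; exact ties co-rank, which is how these cap degeneracies surface to
the user.

# Nested Venn feature attribution

Features from all samples are aligned by single-linkage clustering under a
joint tolerance (defaults 10 ppm m/z and 0.2 min RT; alignment-software
parameters are never published for this kind of export, so the defaults
are explicit and configurable). Single linkage can chain distinct features
through intermediates; clusters whose m/z span exceeds twice the tolerance
are flagged rather than split. A feature is *present* in a treatment when
detected in at least 50% of its replicates (inclusive) — a declared
default robust to one dropout in quadruplicate designs, not a published
rule. Samples in which nothing was detected can be declared via the
`samples` argument so they still count in the denominator.

The three stages for microbe $m$:

1. **Attribution**: features present in $m$'s in vitro culture, its
   single-inoculation nodules and the full-community nodules, minus
   everything present in baseline (symbiont-only) nodules. For the
   symbiont itself the single-inoculation treatment *is* the baseline, so
   the subtraction is skipped — literally subtracting would force the
   symbiont's set empty by construction, while its in vitro leg already
   excludes plant-derived background.
2. **Uniqueness**: each microbe's stage-1 set minus the union of all other
   microbes' stage-1 sets; the outputs are pairwise disjoint.
3. **Exclusion filter**: a focal microbe's unique set minus everything
   seen in communities that did not include it.

Stage nesting (3 ⊆ 2 ⊆ 1) and stage-2 disjointness are asserted on every
run of the wrapper, not just in tests.

# Recovery and CFU statistics

Recovery rate is the percentage of a treatment's nodules yielding at least
one CFU of a strain (threshold configurable). Relative recovery subtracts
the strain's single-accessory baseline rate, with a ±1 percentage-point
zero band (the zero class exists in the source design but with no stated
tolerance). Mean CFU averages over *all* nodules of a treatment, zeros
included; fold changes between treatments are ratios of such means, with a
zero denominator reported as undefined rather than an error. Co-occurrence
partitions nodules by the exact recovered subset, so counts always sum to
the nodules assayed. Interaction labels follow the ecological definitions:
*cooperation* when both pair members rise above their single-accessory
baselines, *competition* when adding a third member depresses a pair
member below its pair-treatment rate, and *mixed* when recovery rises
while mean abundance falls — the disparate-effects case.

# The synthetic-data module

The generators define the study conditions; they are not tuning knobs.

* `venn_design_spec()` defaults encode the five-member community design:
  per-microbe unique-feature counts 0 (Ag47), 4 (Ag15), 5 (Ag54),
  16 (Ag35) and 37 (SM); two exclusion communities lacking Ag35 with 3 of
  Ag35's unique features leaked into them (13 survive the filter);
  4 replicates per treatment; m/z drawn uniformly on 200–2000 (the
  acquisition scan range), RT on 1–20 min; 5 ppm m/z and 0.02 min RT
  jitter under 10 ppm / 0.2 min matching. Counts the source design leaves
  unstated were fixed once at realistic values: 25 plant-derived baseline
  features present in every in-planta sample, and 6 shared features per
  adjacent accessory pair (enough to exercise the stage-2 subtraction
  without dominating the tables).
* True feature coordinates are drawn with a minimum mutual separation of
  four matching tolerances, so sub-tolerance jitter can never merge two
  planted features — generation refuses jitter at or above the matching
  tolerance outright.
* `gen_ms2_spectrum()` plants predicted fragment series with optional
  dropout, jitter and decoy peaks kept at least three tolerances off the
  true ladder; the precursor is the singly protonated peptide.
* `gen_nodule_table()` draws per-nodule Bernoulli colonization and
  log-normal CFU counts whose conditional mean is set so the overall
  (zeros-included) mean matches the target; the preset encodes the key
  treatments: 40%/64%/0%/0% single-accessory recovery over 15 nodules,
  the cooperative pair at 10/12 with target means 280 (alone) and 69
  (with partner) CFU/nodule, and the collapsed trio.
* One global seed expands to per-stream child seeds by stable string
  hashing, so adding a generator never perturbs existing streams; child
  seeds stay below $2^{31}$.

What the generators deliberately do **not** emulate: chromatographic peak
shape, isotope envelopes (beyond the spacing used for charge inference),
intensity structure, retention-time drift between batches, or correlated
dropout. Passing the planted-truth tests therefore demonstrates the
correctness of the set algebra, matching and statistics under the stated
noise model — not robustness to every artefact of real LC-MS data.

# Stachelhaus-code comparison

Adenylation-domain substrate prediction is nearest-neighbour lookup of a
10-character binding-pocket signature against a reference table, with
fraction-identical scoring ('-' never matches), ties reported as multiple
substrates and a 0.8 minimum identity for a call. Cluster-to-cluster
mapping is global Needleman–Wunsch alignment over module-ordered code
lists (match score = code identity, linear gap penalty 0.4 — low enough to
admit a genuine two-module insertion between high-identity flanks, high
enough to forbid spurious gaps; verified against exhaustive enumeration on
small clusters). Query modules aligned to gaps are reported as additional
domains with predicted substrates. The shipped two-cluster code table is a
constructed synthetic stand-in (see its file header): it preserves the
structural relationships that matter — a 15-module reference versus a
17-module query with insertions at chemical positions 7 and 8, a sharply
divergent code at position 11, and predictions that concatenate to the
britacidin A residue sequence — without claiming to be transcribed genome
annotation. This module never touches sequence data; codes are inputs.

# Problem sizes and runtime

The shipped tests and the acceptance script run the Venn pipeline on the
full community design (105 planted features, 17 treatments × 4
replicates, ~3000 feature observations), the ladder property on 100
random peptides of length 3–10, the recovery binomial check on 500–600
nodules, and the alignment oracle on clusters of up to 6 modules. These
sizes were chosen so the whole suite completes in well under a minute
while every statistical check retains at least 3-standard-error
resolution.

# Known limitations

* The ladder sequencer handles singly charged fragment series only;
  multiply charged MS2 peaks must be deconvolved upstream.
* Single-linkage feature matching is order-independent but can chain;
  chained clusters are flagged, not resolved.
* Adduct grouping considers the five standard positive-mode proton/sodium
  species; ammonium, potassium and negative-mode species are out of scope.
* Interaction classification is rule-based labelling, not hypothesis
  testing; no inferential statistics are attached to recovery differences.
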