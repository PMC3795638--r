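---
title: "Interpreting peptide mass fingerprints for phosphorylation and polyglycylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting peptide mass fingerprints for phosphorylation and polyglycylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmladder)
```

## The measurement model

A MALDI reflector instrument observes singly protonated peptide ions. For a
tryptic peptide with residue sequence $r_1 \dots r_k$ the theoretical
observable is

$$\mathrm{MH}^+ = \sum_{i=1}^{k} m(r_i) + m_{\mathrm{H_2O}} + m_{\mathrm{H^+}},$$

with monoisotopic residue masses $m(r)$, $m_{\mathrm{H_2O}} = 18.010565$ Da
and $m_{\mathrm{H^+}} = 1.007276$ Da. Two modifications shift this mass in
characteristic, integer-multiplicity ways:

* **phosphorylation** adds $79.96633$ Da per event, at most one per
  Ser/Thr/Tyr site;
* **polyglycylation** adds $n \times 57.02146$ Da for a chain of $n$
  glycines on a glutamate side chain, so a heterogeneously modified peptide
  population produces a *ladder* of peaks at 57-Da intervals.

Everything downstream — variant enumeration, peak matching, pair detection,
ladder calling — is arithmetic on this model plus a tolerance describing
calibration precision. The package deliberately models nothing else about
the instrument: no isotope envelopes, no charge states beyond +1, no
intensity physics. Inputs are centroided peak lists (TSV/CSV/MGF); raw
spectrum processing is out of scope.

Masses are kept at full precision internally. Reference values in the
literature are typically printed at one or two decimals and rounded
inconsistently, so agreement is assessed at ±0.1 Da, the realistic
reflector calibration precision. One labelling quirk is worth knowing: for
the giardial 230–248 peptide the widely quoted value 2104.92 corresponds to
the *neutral* monoisotopic mass, not MH⁺ (which computes to 2105.93). The
package always exposes both (`neutral_mass`, `mh_plus`) and never guesses
which one a printed number meant.

## Digestion

`digest()` applies the strict trypsin rule — cleave C-terminal to K or R
unless the next residue is proline — because the reference peptides are all
consistent with it. Coordinates are 1-based and inclusive, matching the
superscript residue numbering used in protein literature (the protein
N-terminal Met is residue 1 and is not removed). The default of 2 missed
cleavages is the conventional search setting for in-gel digests. Two
structural properties define correctness and are property-tested: the
zero-missed peptide set tiles the parent exactly, and every k-missed
peptide is the concatenation of at most k+1 consecutive zero-missed
fragments.

## Peak matching and ladder calling

`match_variants()` assigns each theoretical variant to the nearest peak
within the tolerance (default 0.1 Da); a peak claimed by several isobaric
variants (e.g. alternative phospho site assignments) is flagged ambiguous
rather than arbitrated — MS1 masses cannot localize a site. Intensity is
ignored for matching: presence/absence at the reported mass is the
evidence level this analysis operates at, and an optional minimum-intensity
filter defaults to off.

`detect_phospho_pair()` distinguishes three informative outcomes: both
unmodified and +80 Da peaks (`pair`), the shifted peak alone
(`exclusive` — a fully occupied phosphosite), or no shifted peak.

`call_ladder()` walks the grid $\mathrm{MH}^+_0 + n \cdot 57.02146$ upward
from $n = 0$, accepting a rung when a peak lies within tolerance and
tolerating up to `max_gap` consecutive missing rungs (default 1). Two
design choices matter:

* **Anchoring.** The search is anchored at the unmodified MH⁺ even when
  that rung is absent, because a constitutively modified peptide shows a
  ladder *without* its $n = 0$ rung; the call then reports 0 among its
  gaps. This is exactly the observed behaviour of the giardial C-terminal
  peptide, whose unmodified form is undetectable while rungs 1–24 are
  present.
* **`min_rungs = 3`.** Two peaks 57 Da apart arise easily by chance among
  tryptic peptides (57.02146 is the glycine residue mass, so any pair of
  peptides differing by one glycine co-produces such a spacing); requiring
  three rungs suppresses these coincidences.

## The polyglycylation signature motif

The discrete signature scanned by `scan_motif()` is

$$[T/G]\; X_{0,1}\; [D/E]\; X_{1,3}\; G\; [D/E]\; X_{1,2}\; E_{2,4}$$

where the terminal glutamate run carries the candidate glycylation sites.
"X is a polar or negatively charged amino acid" does not pin down a set, so
the X alphabet is a configuration knob; the default is
$\{S, T, N, Q, C, Y\} \cup \{D, E\}$, excluding G, A and H. Summing element
bounds gives a minimal match of 8 and maximal of 14 residues.

Matching reports *every* feasible span (overlaps allowed); when several
element-length assignments produce the same span, the canonical one has
minimal violations with ties broken greedy-longest per element, which the
recursive matcher realizes by exploring lengths longest-first with full
backtracking. A fuzzy mode admits a bounded number of out-of-class residue
positions (element length bounds are never relaxed) and records each
violation. The fuzzy mode exists for a substantive reason: the canonical
giardial glycylation site context (…TDSAGDDNAEEK around the modified
glutamate) does not satisfy the strict pattern under any plausible X set —
alanines intervene — and the epsilon-type C-terminal peptide EQIQDVEDQDVS
contains no glycine at all. The pattern is implemented exactly as published
and this discrepancy is documented rather than patched, because inventing a
corrected pattern would change the hypothesis being tested. Strict matches
are provably a subset of fuzzy matches at any budget, and the scanner is
validated against a flat brute-force enumeration of every element-length
combination at every offset.

## Conservation statistics

`global_align()` computes the optimal end-to-end alignment under affine
gaps (a gap of length $L$ costs $\mathrm{open} + L \cdot \mathrm{extend}$;
defaults 10 and 0.5 with BLOSUM62). Alignment is delegated to Biostrings;
correctness is checked against an independent implementation of the Gotoh
recurrence, itself validated by exhaustive enumeration of all alignment
paths on short sequences. Identity is the fraction of identical columns and
similarity additionally counts positive-scoring substitutions; the
denominator is the full alignment length including gap columns, with a
`denominator = "shorter"` switch because conventions differ between tools
and the convention behind published percentages is rarely stated. A PAM250
preset is included as the alternative matrix; historical ClustalW defaults
(Gonnet series) are not shipped, so published percentages computed with
other tools may differ by a few points from either preset.

`classify_columns()` reproduces the conventional rendering of family
alignments: `invariant` (all rows identical, no gap), `conserved` (at least
k rows agree, default 2), `divergent`. `map_position()` carries 1-based
residue positions across an alignment, returning `NA` at gaps; composed
with the reverse map it is the identity on non-gap positions.

## Dimer compatibility

14-3-3 dimerization is stabilized by a small number of N-terminal salt
bridges, and isoform compatibility can be argued at the residue-identity
level: a bridge position pair is `intact` when one residue is basic
\{K, R\} and the other acidic \{D, E\}, `repulsive` when both carry the
same charge, `neutral` otherwise. Histidine is excluded from the basic set
by default (physiological pH); both charge sets are arguments. The
compatibility score is intact − repulsive. No geometry, distances or
energetics are modeled — deliberately, since the underlying argument is
purely sequence-based. The packaged `reference_bridges()` table carries the
published interface pairs for human zeta, the two fly isoforms, the
giardial protein and the two giardial heterodimer mappings; with it,
`rank_partners()` reproduces the observed preference order: zeta-type
pairings (3 intact bridges) above the epsilon heterodimer (1 intact, 1
repulsive, score 0).

## The synthetic-data generator

`sim_protein()` and `sim_spectrum()` exist so that every claim the package
makes is testable offline against known ground truth, which is always
emitted alongside the data. The spectrum generator emulates the conditions
of reflector-mode MALDI acquisition: monoisotopic peaks in a 750–4000 Da
window, Gaussian calibration jitter with SD 0.02 Da (well inside the 0.1 Da
matching tolerance; the two are independent knobs), log-normal intensities,
and uniformly placed decoy peaks. Decoys are excluded from ±0.2 Da (twice
the default tolerance) around the *full theoretical rung grid* of a planted
ladder, including planted-absent rungs — otherwise a decoy could land on an
absent rung and silently fill a gap the test is supposed to measure. A
`hostile` mode places decoys at half-rung offsets instead, stressing
tie-breaking. A single seed drives all draws; identical configurations give
byte-identical output.

What the generator does *not* emulate — isotope envelopes, detector noise,
intensity-dependent peak picking, chemical background with mass-defect
structure — bounds what passing tests show: recovery results here
demonstrate correctness of the calling logic under the stated noise model,
not instrument-level sensitivity on real spectra, where absence claims are
always conditioned on the peak-picking threshold.

## Validation scale and numerical choices

The shipped test suite checks, among other things: all eight reference
peptide masses at ±0.1 Da; ladder recovery (k_max = 24 with the anchor gap)
in 100/100 seeded runs at 50 decoys and 0.02 Da jitter; scanner/oracle
agreement on 1000 random plus 100 motif-bearing sequences of length ≤ 50 in
both strict and fuzzy modes; aligner/oracle score equality on 200 random
pairs of length ≤ 8; and the digestion tiling properties on 500 random
sequences. These sizes keep the full suite under a couple of minutes on one
core while making the stochastic checks meaningfully powered.

Ties and degenerate inputs are resolved deterministically throughout:
nearest-peak matching takes the first minimal-distance peak; ladder
extension stops only when the gap run exceeds `max_gap`; partner ranking
breaks score ties by intact count then lexicographic id; duplicate m/z
values within 1e-6 Da are merged with summed intensity. Empty inputs error
early with informative messages rather than propagating empty tibbles.

## Known limitations

* MS1-level evidence only: isobaric site assignments (e.g. which of several
  S/T residues is phosphorylated) are reported ambiguous, never localized.
* The signature motif is a discrete pattern, not a trained model; its
  biological sensitivity/specificity is untested beyond the sequences
  discussed above.
* Identity/similarity percentages are preset-dependent; reproducing values
  computed with other alignment tools may require their exact matrix and
  gap parameters, which are often unpublished.
* Salt-bridge scoring ignores structure; it ranks hypotheses, it does not
  predict binding energies.
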