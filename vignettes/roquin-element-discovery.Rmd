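---
title: "Discovering Roquin-bound decay elements in 3'UTRs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Roquin-bound decay elements in 3'UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roquinscan)
```

## The problem

Roquin-1 and Roquin-2 (RC3H1/RC3H2) destabilize mRNAs by recognising the
*shape* of small stem-loops in 3'UTRs rather than a linear sequence motif.
Two element classes are known: the constitutive decay element (**CDE**), a
perfect 6-8 bp stem capped by a YRN tri-nucleotide loop, and the
alternative decay element (**ADE**), the same stem capped by a U-rich
GUUYUA hexaloop.  Because recognition is structural, a candidate element is
only plausible if (i) the consensus hairpin is present in the sequence,
(ii) the hairpin actually *forms* with appreciable probability in the
thermodynamic ensemble of its whole UTR, and (iii) the element is conserved
across mammals in a structure-aware sense — point substitutions that
preserve the stem (compensatory or wobble-creating changes) or stay within
the loop consensus do not count against conservation.

`roquinscan` implements that three-legged filter plus the associated
statistics, and ships a synthetic-data generator so each stage can be
validated without any external download.

## Consensus scanning

`scan_motifs()` enumerates hairpins combinatorially: for every loop
register whose sequence matches the IUPAC consensus, the stem is extended
outwards while bases pair.  Wobble (G·U) pairs are *excluded* from the
search — the one stem change that measurably weakened repression in
mutation analyses — but are *tolerated* later during conservation
assessment; the two modules deliberately use different pairing predicates.

Two reporting decisions are not dictated by the consensus itself:

* **Maximality.** Nested sub-stems of one hairpin are not reported
  separately: per loop register only the longest extendable stem is kept.
  A stem extendable beyond 8 bp is capped at 8 by default, because the
  consensus caps the search; `reject_extendable = TRUE` drops such
  hairpins instead (a 9-bp stem is reported to be non-functional, so both
  readings are defensible; both are tested).
* **`N` handling.** An `N` never pairs and never satisfies a consensus
  letter, under either alphabet policy.

The scanner is validated against a brute-force enumeration of every
(position, stem length) combination on thousands of random sequences.

## The thermodynamic ensemble

Folding probabilities use a nearest-neighbor energy model over
pseudoknot-free secondary structures with hairpin loops of at least 3 nt.
The default parameter set (`energy_model("turner2004")`) is a documented
subset of the Turner 2004 rules, stored as a plain-text table under
`inst/extdata/params/`:

* Watson-Crick helix stacks at the published dG37 values; G·U stacks to
  about 0.1 kcal/mol.
* Hairpin initiations for loops of 3-9 nt from the tables; longer loops by
  Jacobson-Stockmayer extrapolation, `dG(L) = dG(9) + 1.75 RT ln(L/9)`.
* Terminal AU/GU penalty (0.5 kcal/mol) charged once per loop that a helix
  end borders — hairpin closing pair, both closing pairs of an internal
  loop or bulge of two or more nucleotides, and every multiloop or
  exterior-loop branch.  A lone pair is therefore charged twice, which is
  the convention of the established folding packages.
* Single-nucleotide bulges keep the flanking helix stack; affine
  internal-loop initiation with an asymmetry penalty (0.6 kcal/mol per
  unpaired-length difference, capped at 3); affine multiloops
  (3.4 closing + 0.4 per branch + 0 per unpaired nucleotide).
* No tetraloop bonuses, terminal mismatches, dangling ends or coaxial
  stacking.

Omitting the single-stranded stacking terms matters for absolute numbers
on real sequences; all correctness tests are therefore
parameter-set-independent, and a fuller table can be dropped in as a text
file without code changes.  Temperature only rescales RT (the tables carry
free energies, not enthalpies); the default is 37 °C.

`partition_function()` computes the inside recursion, base-pair
probabilities by the full inside-outside decomposition, and the MFE
structure, in C++ with per-nucleotide scaling so kilobase UTRs do not
overflow (`logZ` is always finite).  MFE ties are broken by a fixed,
deterministic preference order in the traceback (hairpin, then interior
loops by position, then multiloops); this is deterministic but is not
guaranteed to pick the lexicographically smallest co-optimal string, which
would require a second optimisation over the co-optimal set.

### The motif formation probability

`p_fold` is the ensemble probability of the *whole motif event*: every
stem pair present and the apical pair closing a hairpin whose loop is
exactly the motif's loop nucleotides, with anything allowed outside the
footprint, including enclosing helices.  It is computed exactly as a ratio
of two partition functions: the denominator is unconstrained; in the
numerator the footprint is frozen as a rigid element with its internal
Boltzmann weight (stem stacks + hairpin initiation + apical terminal
penalty) and all other pairings of footprint positions are forbidden.
This constrained rerun is an independent code path from the pair
probability (outside) computation, and both are checked against an
exhaustive structure enumerator on short sequences to a relative error of
1e-9.

One consequence worth stating: `p_fold` is **not** monotonically diluted
by context.  An enclosing helix that stacks on the motif's outer pair
*stabilizes* the element, so embedding a motif in a random context can
raise its formation probability above the bare-hairpin value.  What does
hold, and what the property tests assert, is that context that cannot pair
at all leaves `p_fold` exactly unchanged, and that
`p_fold <= P(apical pair)` always.

Folding context: UTRs up to 1,500 nt are folded whole; longer contexts use
a 1,000-nt window centered on the motif.  Both knobs are arguments and the
window actually used is reported in the result.

## Structure-aware conservation

Each human motif is judged against chimpanzee, mouse, dog and cow rows of
a Multiz-style alignment.  A species is `identical`, `tolerated`,
`violated`, or `absent`.  Tolerated changes are exactly four categories:
loop changes that still match the consensus; stem-length changes that
leave at least 6 loop-proximal pairs; compensatory pair changes; and
wobble-creating changes.  Everything else — including any gap column
inside the loop or the required pairs, and any insertion into the
footprint — is a violation.  Design choices that the rules do not fix:

* "Only 6 bp need to be conserved" is read as the **6 loop-proximal**
  pairs (`conserved_core = "apical"`), since apical mutations are the ones
  that abolish repression; `"any6"` is available as an alternative.
* A species absent from the alignment defaults to *not conserved*
  (`policy = "strict"`, matching the across-all-five-species wording);
  `"ignore_absent"` is provided because real alignment coverage is
  incomplete.
* Loop positions are read from the alignment columns of the human loop; an
  indel that relocates the loop is a violation, not a tolerated change.
* Species stems may gain pairable flanks beyond the human footprint; only
  the human footprint is judged.

The rules are deterministic, so the classifier is required to recover the
generator's intended labels with 100% accuracy on rule-generated data.

## Statistics

`pearson_chi_square()` is the classic `sum (O-E)^2/E` with no continuity
correction (small expected counts trigger a warning and a permutation
oracle is provided).  The co-occurrence analysis tabulates A/G at triloop
position 2 against Y-R vs R-Y closing-pair polarity (polarity named by the
5' partner) over conserved CDEs.  The conserved-vs-non-conserved folding
probability comparison uses a two-sided Wilcoxon-Mann-Whitney rank-sum
test; the underlying report never named its test, and the rank test is the
defensible default for a bounded, skewed quantity — recorded here as a
deviation risk.

## Target selection

A CDE qualifies for the high-confidence set iff it is conserved, its
`p_fold` strictly exceeds 5%, and its triloop carries U at position 3.  A
gene is high-confidence when it has 1-2 qualifying CDEs (the published set
had no gene with three or more, so whether 1-2 was a filter or an
observation is ambiguous; the default enforces it and
`policy = "at_least_one"` relaxes it).  Tandem elements are single-linkage
groups of CDEs separated by at most 50 nt — the published tandem pair sits
inside a 64-nt element and no explicit threshold was given, so 50 nt is a
recorded default, not a derived one.  Screen-window selection reproduces
the wet-lab criteria: external conserved-structure score > 0.9, parent UTR
500-1500 nt, and greedy non-overlap by descending score.

## The synthetic world

`gen_dataset()` emulates what the analysis assumes and nothing more: iid
background UTRs (default 600 nt, inside the 500-1500-nt screen band and
small enough that per-gene partition functions stay fast); planted
consensus hairpins with configurable stem length (6-8), stem composition
(AU fraction, purine stack), and loop (triloop position 3 skewed to U with
probability 0.7, mirroring the conservation-derived loop preference, and
position 2 skewed 70/30 toward A); and substitution-only five-species
alignments in which motif footprints change only via the named tolerated
or violating categories (background sites mutate iid at rate 0.1 per
species).  Flanks adjacent to a planted stem are resampled so they cannot
pair, which makes the planted footprint exactly recoverable and is why
scanner sensitivity on planted data must be 100% rather than merely high.

What a green synthetic test does *not* establish: realistic phylogeny (no
tree, no rate variation), indels (off by default because in-motif gaps are
violations by rule), composition biases of real UTRs, or the accuracy of
the energy parameters on real sequences.

## Worked-example stand-ins

The published worked examples (a 1131-nt tandem-CDE UTR and the known
TNF/Ox40/ICOS CDEs) cannot be fetched or redistributed in this build
environment.  `ucp3_synthetic_utr()` and `known_cde_synthetic_utrs()`
construct clearly-labelled synthetic stand-ins from the published verbal
descriptions only (element length, all-A-U CDEI stem, UAU loops, A-U
closing pairs, 3' purine stack in CDEII, ~72% AU element content), fixed
before any folding probability was computed and not adjusted afterwards.
On these stand-ins the scanner reports the two tandem CDEs at their
designed footprints and the acceptance test then compares folding
probabilities with the published 6%/55% values at +-10 points: the CDEI
assertion holds (0.015 vs 6%), the CDEII assertion fails by 1.1 points
(0.661 vs 55%) and is left failing — reproducing printed numbers for a
sequence one does not have, under a reduced parameter set, is exactly the
kind of claim this package declines to fake.  The three known-CDE
stand-ins all fall inside the published 15-98% folding-probability band
(0.52, 0.19, 0.63).

## Numerical notes

* Inside/outside computations are scaled per nucleotide by
  `exp(1.05 * MFE / (RT n))`; probabilities are scale-invariant and `Z` is
  reported via `logZ` when it overflows a double.
* The enumeration oracle refuses sequences longer than 22 nt; all
  oracle-backed tests run at 18 nt or less.
* Internal loops are capped at 30 unpaired nucleotides (standard), hairpin
  and bulge tables extrapolate beyond 30.
* Chi-square p-values are asymptotic; the permutation oracle
  (`chi_square_permutation_p()`) agrees within ~0.015 on the table sizes
  used in tests, and the type-I error of the co-occurrence test is
  calibrated to [0.03, 0.07] at nominal 0.05 over 1,000 null simulations.

## Known limitations

* The energy table is a reduced Turner set; absolute `p_fold` values on
  real UTRs will differ from a full-parameter implementation by up to
  roughly ten percentage points in our comparisons against the published
  worked-example values.
* MFE tie-breaking is deterministic but not lexicographically minimal.
* The MAF reader supports the `a`/`s` line subset produced by Multiz and
  this package's own writer; `q`/`i`/`e` lines are ignored.
* Genome-wide counts from the original study (~2600 CDE genes, 160
  high-confidence targets) depend on a specific UTR annotation and
  alignment release and are out of desk-scale reach by design.
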