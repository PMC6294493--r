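# roquinscan

Discovery of Roquin-bound mRNA decay elements (CDEs and ADEs) in 3'UTRs.

Roquin-1/-2 are RNA-binding proteins that trigger deadenylation and decay
of target mRNAs by recognising the *shape* of small 3'UTR hairpins:

* **CDE** (constitutive decay element): a perfect 6–8 bp stem capped by a
  **YRN** tri-nucleotide loop (no G·U pairs in the search consensus);
* **ADE** (alternative decay element): the same stem capped by a
  **GUUYUA** hexaloop.

A consensus match alone says little — the hairpin must also *form* in the
thermodynamic ensemble of its UTR and be conserved across mammals in a
structure-aware sense. `roquinscan` implements the full discovery
pipeline:

1. **Scan** — combinatorial enumeration of all maximal consensus hairpins
   (`scan_motifs()`), with BED6/TSV output.
2. **Fold** — nearest-neighbor partition function, base-pair
   probabilities and MFE (`partition_function()`, C++ core), and the exact
   motif formation probability
   `p_fold = Z(structures containing the full hairpin) / Z`
   (`motif_fold_probability()`), validated against exhaustive structure
   enumeration to 1e-9.
3. **Conserve** — structure-aware classification against
   chimpanzee/mouse/dog/cow alignment rows (`classify_motif()`): tolerated
   changes are consensus-preserving loop changes, compensatory pairs,
   wobble-creating changes, and stem-length changes leaving ≥ 6
   loop-proximal pairs.
4. **Statistics** — loop composition, Pearson chi-square tests (with a
   permutation oracle), the position-2 × closing-pair-polarity
   co-occurrence, AU-rich stems, 3' purine stacks, and a rank-sum
   comparison of folding probabilities.
5. **Select** — the high-confidence filter (conserved ∧ p_fold > 5% ∧ U at
   triloop position 3; 1–2 qualifying CDEs per gene), tandem-CDE
   detection, and screen-window selection (score > 0.9, UTR 500–1500 nt,
   greedy non-overlap).
6. **Simulate** — a first-class synthetic-data generator (`gen_dataset()`)
   producing FASTA/MAF/truth tables with planted elements and labelled
   per-species change plans, so every stage is testable offline.

## Worked example

The published worked example is a 1131-nt 3'UTR carrying a 64-nt element
with two tandem CDEs. That sequence cannot be redistributed, so the
package ships a clearly-labelled synthetic stand-in built from its verbal
description (`ucp3_synthetic_utr()`; all-A-U CDEI stem, mixed CDEII stem
with a 3' purine stack, UAU loops, A-U closing pairs):

```r
library(roquinscan)
model <- energy_model("turner2004")
ucp3  <- ucp3_synthetic_utr()
motifs <- scan_motifs(ucp3$record$sequence, motif_descriptor("CDE"),
                      ucp3$record$transcript_id)
tab <- motif_table(motifs)
tab$p_fold <- round(motif_fold_probabilities(ucp3$record$sequence, motifs, model), 3)
tab$au_frac <- round(sapply(motifs, function(m) stem_au_fraction(m)$fraction), 2)
tab$purine_stack <- sapply(motifs, purine_stack_3p)
tab[, c("five_start", "three_end", "stem_len", "loop_seq",
        "p_fold", "au_frac", "purine_stack")]
detect_tandem(tab)
```

Output:

```
 five_start three_end stem_len loop_seq p_fold au_frac purine_stack
        508       523        6      UAU  0.015     1.0        FALSE
        533       548        6      UAU  0.661     0.5         TRUE
[[1]]
[1] "UCP3-SYNTHETIC-STANDIN|CDE|508-523" "UCP3-SYNTHETIC-STANDIN|CDE|533-548"
```

The scanner finds exactly the two planted tandem CDEs in the full UTR.
The all-A-U CDEI folds poorly (p_fold 1.5%; the published value for the
real all-A-U CDEI is 6%), the stable mixed-stem CDEII folds most of the
time (66.1% vs the published 55% — 11 points off, on a synthetic
stand-in under a reduced Turner parameter set; see the methods vignette
and the acceptance test, where this assertion is deliberately left
failing rather than tuned).

Only CDEII would qualify for the high-confidence set:

```r
qualify_cde(conserved = c(TRUE, TRUE), p_fold = tab$p_fold,
            loop_seq = tab$loop_seq)
#> [1] FALSE  TRUE
```

## Command line

```sh
inst/cli/roquinscan simulate --out simdir --n-genes 50 --seed 1
inst/cli/roquinscan scan     --fasta simdir/utrs.fa --out motifs.tsv
inst/cli/roquinscan fold     --fasta simdir/utrs.fa --out folded.tsv
inst/cli/roquinscan conserve --fasta simdir/utrs.fa --maf simdir/alignments.maf --out conserved.tsv
inst/cli/roquinscan targets  --annotated annotated.tsv --out targets.tsv
```

## Layout

* `R/`, `src/thermo.cpp` — modules: sequence IO (FASTA/MAF/BED), scanner,
  thermodynamic ensemble, conservation, statistics, target selection,
  synthetic data, CLI.
* `inst/extdata/params/` — plain-text energy parameter tables.
* `vignettes/roquin-element-discovery.Rmd` — models, assumptions, design
  decisions, limitations.
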