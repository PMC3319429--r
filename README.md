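# loopfold

Loop-based thermodynamic prediction of RNA secondary structure in R.

Single-stranded RNA folds back on itself into helices and loops, and this
secondary structure — a pseudoknot-free set of Watson–Crick and GU pairs —
carries most of the folding free energy and much of the molecule's
function.  `loopfold` implements the standard nearest-neighbor model on
top of exact dynamic programming: every structure decomposes uniquely into
loops (hairpins, stacks, interior loops/bulges, multibranch and exterior
loops), each loop has a tabulated free energy, and the structure's energy
is the sum

&nbsp;&nbsp;&nbsp;&nbsp;ΔG(S) = Σ<sub>loops L of S</sub> ΔG(L).

On this model the package computes, in O(n³) time and O(n²) memory:

* **`eval_energy()`** — the loop-sum free energy of a given
  sequence/structure pair (linear or circular, dangle models 0 and 2);
* **`fold()` / `fold_circular()`** — the minimum free energy (MFE)
  structure by Zuker-style minimization, with hard constraints
  (unpaired / paired / specific pairs), canonical-only mode (`noLP`,
  no isolated pairs) and circular sequences;
* **`partition_function()`** — McCaskill's algorithm: the partition
  function Z = Σ<sub>S</sub> e<sup>−ΔG(S)/RT</sup>, the ensemble free
  energy −RT·ln Z, and the matrix of equilibrium base-pair
  probabilities p(i,j), with **`centroid_structure()`**,
  **`mea_structure()`** (maximum expected accuracy),
  **`positional_entropy()`** and seedable Boltzmann sampling via
  **`sample_structures()`**;
* **`subopt_band()`** — the *complete* set of structures within an
  energy band of the MFE; **`subopt_zuker()`** — the best structure
  containing each admissible pair;
* **`lfold()` / `plfold()`** — scanning predictions for long
  sequences: locally stable structures under a pair-span bound, and
  window-averaged pair probabilities plus accessibilities (probability
  that an interval is single-stranded);
* **`duplex_fold()`** — intermolecular hybridization of two strands
  (no intramolecular pairs, no multibranch loops);
* **`count_basepairs()` / `bp_scores()`** — benchmark statistics
  (sensitivity, PPV, MCC, F1) against reference structures, with the
  true-negative estimator TN = n(n−1)/2 − TP.

Energies are integer tenths of kcal/mol at 37 °C internally and kcal/mol
in all reports.  Parameters load from human-readable text files
structured like the Turner 2004 compilation (`read_energy_params()`,
`write_energy_params()`); a complete default set is bundled, and
`toy_energy_params()` builds hand-auditable sets for teaching and tests.

## A worked example

```r
library(loopfold)
s <- "GGGCGCAAGGCUAGCAAAGCUAGCCAAGCGCAAACCC"

fold(s)
#> ..((((..(((((((...)))))))..))))...... (-19.60)

pf <- partition_function(s)
pf
#> free energy of ensemble = -19.90 kcal/mol

centroid_structure(pf)$structure     # pairs with p > 1/2
#> ..((((..(((((((...)))))))..))))......
mea_structure(pf)$score
#> 35.40

subopt_band(s, band = 1)             # every structure within 1 kcal/mol
#>                               structure energy
#> 1 ..((((..(((((((...)))))))..))))......  -19.6
#> 2 ((((((..(((((((...)))))))..))))...)).  -19.1

duplex_fold("GCGCUUCG", "CGGGAAGC")
#>     structure i1 i2 j1 j2 energy
#> 1 (((((&)))))  3  7  4  8   -6.6
```

The MFE structure here is a two-helix stem with a 7-bp inner helix; its
free energy, −19.60 kcal/mol, is the loop sum that `eval_energy(s, ...)`
reproduces exactly.  The ensemble free energy is necessarily lower
(−19.90), and e<sup>−(ΔG<sub>MFE</sub>−G)/RT</sup> ≈ 0.62 is the
equilibrium probability of the MFE structure itself.  The centroid and
MEA structures coincide with it — this sequence has a well-defined
minimum.  The duplex call reports the best hybridization site between two
strands with its 1-based ranges on either side of the `&`.

Stream-oriented command-line tools (`rnafold`, `rnaeval`, `rnasubopt`,
`rnalfold`, `rnaplfold`, `rnaduplex`, `rnabench`) mirror the R functions
for shell pipelines:

```sh
printf '>demo\nGGGCGCAAGGCUAGCAAAGCUAGCCAAGCGCAAACCC\n' | \
  Rscript "$(Rscript -e 'cat(system.file("cli","rnafold.R",package="loopfold"))')" -p
```

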