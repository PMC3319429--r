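---
title: "The loop-based thermodynamic model behind loopfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The loop-based thermodynamic model behind loopfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopfold)
```

## The model

A secondary structure of an RNA sequence is a set of base pairs such that
(1) only Watson-Crick (AU, UA, CG, GC) and wobble (GU, UG) pairs form,
(2) every base pairs with at most one partner, (3) every pair encloses at
least three unpaired bases, and (4) no two pairs cross — the structure is a
non-crossing matching, which excludes pseudoknots.  Every such structure
decomposes uniquely into *loops*: hairpin loops, stacked pairs, interior
loops and bulges, multibranch loops, and the exterior loop containing the
free ends.  The nearest-neighbor model assigns each loop a free energy from
tabulated parameters, and the energy of the structure is, to a very good
approximation, the sum of its loop energies.  Everything the package
computes — minimum free energy (MFE) structures, partition functions,
pair probabilities, suboptimal sets, local structures, duplexes — is built
on that single additive model, so `eval_energy()` is the arithmetic
authority: every other module promises that the numbers it reports equal
the loop sum of the structures it returns, and the test suite enforces
this.

Energies are handled internally as integers in units of 10 cal/mol
("dekacal") at 37 °C and reported in kcal/mol with two decimals.  Integer
arithmetic makes the dynamic programs exact: two decompositions of the
same structure can never drift apart by floating-point noise.  Boltzmann
weights use RT = 1.98717×10⁻³ kcal mol⁻¹ K⁻¹ × 310.15 K ≈ 0.6163 kcal/mol.

## Energy parameters

Parameter sets follow the table structure of the Turner 2004 compilation:
stacking energies for the 21 pair combinations; terminal mismatch tables
for hairpin, interior, multibranch and exterior contexts; 5′ and 3′
dangles; dedicated tables for 1×1, 2×1 and 2×2 interior loops plus special
mismatch tables for 1×n and 2×3 loops; loop-length penalties for hairpin,
bulge and interior loops up to 30 nt with logarithmic extrapolation
`ΔG(s) = ΔG(30) + lxc·ln(s/30)` beyond (lxc defaults to 107.856 dekacal
and may be overridden in the parameter file); an affine multibranch model
`a + b·(branches) + c·(unpaired)`; the Ninio asymmetry term
`min(cap, |n1−n2|·m)` for interior loops; a terminal-AU penalty per
AU/GU-closed helix end; bonus energies for tabulated tri-, tetra- and
hexaloops (which *replace* the generic hairpin energy when the loop
sequence matches); and a duplex initiation penalty.  Loops containing
nonstandard pairs or nucleotides receive the least stabilizing (maximum)
energy over canonical completions; the bundled tables carry these entries
explicitly, and the loader completes the 2×2 table the same way.

The file dialect is the human-readable one used by current
thermodynamic-folding tools: `# section` headers, whitespace-separated
integers, `INF` for forbidden entries, `/* ... */` comments.  Two
deliberate simplifications of the full 2004 model are inherited: enthalpy
sections are skipped (folding is fixed at 37 °C), and the handful of
special-case corrections (all-C loops, the GU-closure hairpin term, one
tabulated helix, bulge-state entropy, multiloop asymmetry and three-way
penalties) are not evaluated.  A complete default set is shipped in
`inst/extdata/` (split into three files only to keep each file small);
`toy_energy_params()` builds deliberately simple sets — one stack value,
flat length tables, zero mismatches — so that worked examples and exact
tests can be summed by hand.

## Dangling ends

Two dangle models are implemented, selected by `dangles`:

* `dangles = 2` (default): every helix end in a multibranch or exterior
  loop always receives the stacking contribution of both neighboring
  nucleotides (a terminal-mismatch-style term).  Because the contribution
  depends only on fixed sequence positions, the model decomposes exactly
  in all dynamic programs — MFE, partition function, suboptimals and
  sampling all agree to the last integer.
* `dangles = 0`: no dangle contributions at all.

The intermediate models in which a free nucleotide may stack on at most
one helix do not decompose pair-locally and are not implemented; this is a
documented limitation, not an oversight.  Hairpin and interior-loop
mismatches are loop terms, not dangles, and apply under both models.

## Folding and its variants

`fold()` is a Zuker-style energy minimization over closed structures
(`C`), multiloop segments (`M`, `M1`) and the exterior prefix (`F`),
O(n³) time and O(n²) memory, with interior loops capped at 30 unpaired
bases (the standard restriction).  Traceback examines cases in a fixed
order — stacked continuation, hairpin, interior loops with the 5′-most
inner pair first, then multiloop splits — so ties always resolve
identically and results are reproducible run to run.

*Hard constraints* (`.`/`x`/`|` and matched brackets for specific pairs)
are enforced inside the recursion: forbidden pairs are masked from the
pair-type matrix, forced-paired positions may not appear in any unpaired
stretch (checked in O(1) with prefix counts), and pairs crossing a forced
pair are masked.  Unsatisfiable constraints produce the open chain with
`+Inf` energy and a warning rather than an error, so batch runs continue.

*Canonical-only folding* (`noLP`) forbids isolated pairs exactly, not
heuristically, by splitting the closed matrix: `C2` holds structures whose
closing pair stacks on the pair directly inside, `C1` the rest.  A helix
used as a free-standing branch must come from `C2`; below an enclosing
stacked pair either matrix is allowed.  This reproduces the complete set
of lonely-pair-free structures (the suboptimal enumeration on the same
matrices agrees exactly with the brute-force filtered set).

*Circular folding* keeps the linear recursions and evaluates the region
outside all pairs as a real loop on the circle: hairpin-like for one
outermost helix (which must enclose at least three unpaired bases on the
outer face as well), interior-loop-like for two, multiloop-like for three
or more, with dangle neighbors read modulo n.  The open chain (energy 0)
is a member of the circular ensemble here; tools that report a folded
structure even when every structure is destabilizing differ in exactly
that convention.

## Partition function, probabilities and derived structures

`partition_function()` mirrors the MFE decomposition with sums of
Boltzmann factors (McCaskill's algorithm) and obtains pair probabilities
from the outside pass (exterior, interior-loop and multibranch contexts).
To keep numbers in floating range each stored quantity covering k
nucleotides carries a per-nucleotide scale factor s^k, with
`ln s = 1.07·MFE/(n·RT)` from a preliminary folding pass; scale factors
cancel in every probability and are removed analytically from ln Z.

From the probability matrix the package derives the centroid (all pairs
with p > 1/2, which are automatically compatible; reported with its
expected base-pair distance to the ensemble), the maximum expected
accuracy structure (maximizing `Σ 2γ·p(i,j) + Σ q_unpaired`, γ = 1 by
default — the variant that weights the unpaired term unscaled — via a
Nussinov-style recursion), the positional entropy
`S(i) = −Σ p·ln p − q·ln q`, and Boltzmann-weighted samples by stochastic
backtracking.  The sampler caches the choice distribution of every matrix
cell it visits, so large samples cost little more than the random draws
themselves; given a seed it is exactly reproducible.

## Suboptimal structures

`subopt_band()` enumerates *every* structure within an energy band of the
MFE by backtracking with a stack of partial structures; the fixed energy
plus the matrix entries of the unresolved intervals is an exact lower
bound, so pruning is exact, and the decomposition's unambiguity guarantees
each structure appears exactly once.  Output is energy-sorted (generation
order available) with a configurable count cap that raises a truncation
error rather than exhausting memory.  `subopt_zuker()` computes, for every
admissible pair, the best structure containing that pair, by combining the
inside matrix with an outside minimization over exterior, interior-loop
and multibranch embeddings, and reports the distinct per-pair optima.

## Local folding

`lfold()` folds the whole sequence with pair span bounded by L (O(n·L²)
cells) and reports *locally optimal* hits: closing pairs whose structure,
including its exterior stem term, is stabilizing and cannot be improved by
growing the helix outward by one pair.  The paper-level notion of local
optimality is not formalized anywhere, so this rule is the package's
definition; it guarantees the documented equivalence that with L ≥ n and a
single-component MFE structure the best hit is exactly the global fold.

`plfold()` computes pair probabilities averaged over every window of
length W containing the pair, dividing by the actual number of qualifying
windows so sequence ends are not biased.  Each window is an independent
partition-function computation; results are exact per window, and the
single-window case W = n reproduces the global matrix bit for bit.
Accessibilities — probabilities that an interval of length ≤ u is
completely unpaired — are computed per window as a ratio of two partition
functions, the numerator with all pairs touching the interval masked.
This is exact and simple at the price of one restricted ensemble per
interval; the windows the package targets (tens of nucleotides) keep that
comfortably cheap, but genome-scale scanning would want the incremental
algorithm instead.  Window weighting is uniform.

## Duplexes

`duplex_fold()` hybridizes two strands with intermolecular pairs only and
no multibranch loops: the interaction is a single helical region with
bulges and interior loops (capped at 30 unpaired bases), charged one
duplex-initiation penalty plus terminal-AU and, under `dangles = 2`,
dangle/mismatch terms from whatever flanking nucleotides exist at the two
ends.  Both ends' terms use the exterior-loop convention; at a blunt end
(no flanking nucleotide on either strand) no dangle applies.  Hits with
stabilizing energy are reported best-first with 1-based interaction
ranges in both strands.

## Benchmark statistics

`count_basepairs()` compares predicted against reference pairs at exact
positions: TP, FP, FN, and the true negatives estimated by their upper
bound n(n−1)/2 − TP, since only a vanishing fraction of conceivable pairs
can occur.  `bp_scores()` reports sensitivity TP/(TP+FN), precision
TP/(TP+FP), their harmonic mean F1, and the Matthews correlation
coefficient.  Scores with zero denominators are 0 with a `degenerate`
flag; MCC is reported on the [0, 1] accuracy scale used for the other
scores, so an anti-correlated prediction (possible only with TP = 0)
truncates to 0 rather than going negative.

## Verification strategy, problem sizes, and what the tests do not show

The test suite's ground truth is `enumerate_structures()` — a complete
enumeration of all valid structures of a short sequence, validated against
an independent interval-counting recursion — combined with the loop-sum
evaluator.  Folding, partition function, suboptimal completeness, centroid
and MEA optimality, constraint soundness, circular folding and duplex
prediction are each checked for exact agreement with this oracle on
panels of a few hundred random sequences of 8–14 nt (8–12 where the
quantity is quadratic in the structure count), under toy and full
parameter sets, both dangle models, and with and without the
canonical-only restriction.  Stochastic backtracking is checked on
50,000-structure samples against exact Boltzmann probabilities with
per-category binomial tail tests at the 4σ level.  A second, independent
check compares evaluation, folding and band suboptimals against the
widely used reference implementation of the same model on longer random
sequences (20–70 nt), where agreement is exact to the printed precision.

Random panels of short sequences exercise every loop type and every code
path, but they are synthetic: they say nothing about prediction *accuracy*
on evolved RNAs with modified bases, pseudoknots, tertiary contacts or
kinetic traps, and agreement with the energy model is not agreement with
nature.  Known limitations worth restating: no pseudoknots, no
temperature dependence, dangle models 0 and 2 only, interior loops capped
at 30 unpaired bases inside the dynamic programs (evaluation of given
structures has no cap), and local-fold hit definition as described above.
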