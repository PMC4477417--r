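---
title: "Minimal-distance protein alignment from weighted property profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal-distance protein alignment from weighted property profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propalign)
```

## The model

Two protein sequences `X = x_1..x_n` and `Y = y_1..y_m` are aligned
globally by *minimizing* a distance objective rather than maximizing a
substitution-matrix similarity. Each of the 20 standard residues is
represented by a vector of `k >= 1` biochemical property values; the
distance between two aligned residues is the weighted L1 distance between
their property vectors,

    d(x, y) = sum_b w(b) * |p_b(x) - p_b(y)|,

with nonnegative weights constrained to sum to 1, so that the weights form
a convex combination and directly express the relative influence of each
property on the alignment. Gaps are charged the affine penalty
`g(r) = alpha + (r - 1) * beta` per maximal gap run of length `r`, with
`alpha, beta >= 0` in the same distance units, and terminal gaps are
penalized exactly like internal ones (a true global alignment; no
semi-global mode is offered). The total score is the summed pair distance
plus the summed gap penalties, and the reported alignment attains the
global minimum.

### Normalization

By default every property scale is min-max normalized to `[0, 1]`:
`np(x) = (p(x) - min) / (max - min)`. Without this step the scale with the
largest numeric range (residue volume spans ~170 cubic angstroms, a
hydropathy index ~9 units) would dominate `d` regardless of its weight.
Normalization makes the weights, and only the weights, the units of
influence. It can be disabled (`normalize = FALSE`), which is supported
for completeness but not recommended. A constant scale cannot be
normalized and is rejected rather than silently mapped to zero.

### The dynamic program

The recursion is realized as the standard three-state affine-gap dynamic
program (Gotoh): states for "x_i aligned to y_j", "x_i over a gap", and
"gap under y_j", with boundary conditions `D(i, 0) = g(i)`,
`D(0, j) = g(j)`. Because the gap cost is affine, this quadratic-time
formulation is exactly equivalent to the naive recursion that scans all
gap lengths (cubic time); the test suite proves the equivalence against an
independent brute-force enumeration of *all* global alignments on
hundreds of small instances (lengths up to 6). The matrix baseline
`align_matrix` is the same engine run on the negated similarity matrix, so
the two aligners share one tested code path and one tie-break convention.

Numerical choices worth stating explicitly:

* All scores are doubles, and DP comparisons use exact floating-point
  comparison — no epsilon. Candidate values being compared are produced by
  the same arithmetic expressions, so exact ties are meaningful; test
  tolerances are `1e-9`.
* Traceback ties prefer the diagonal (match) move, then the gap in `y`
  (consuming `x`), then the gap in `x`. The choice is arbitrary but fixed
  and documented: the optimal *score* is the contract, the path is merely
  deterministic.
* An empty-vs-empty problem returns the empty alignment with score 0;
  empty-vs-`m` returns one gap run costing `g(m)`.

### Residues outside the 20-letter alphabet

Ambiguity codes and rare residues (B, Z, X, U, O, J) have no property
values. The default policy is a hard error naming the residue and its
position, because silently imputing values would change scores invisibly.
An explicit `on_unknown = "mean"` policy maps any unknown letter to the
per-property mean of the 20 standard values.

## Default properties, weights and presets

Four default properties are bundled: hydrophobicity, size, coil
propensity, and presence of a thiol group. Four is a deliberate ceiling —
the weight/gap grid search costs `n * N^(k+2)` alignments
(`complexity_estimate()`), which at benchmark scale (6,000 pairs, 20-point
grid, k = 4) is already ~3.8e11 — and these four capture the major axes of
amino acid variability: hydrophobicity, size, and structural propensity,
plus the uniquely conserved cysteine thiol (a binary indicator: 1 for C,
0 otherwise).

The preset table (`default_presets()`) ships optimized weights and gap
penalties for five percent-identity ranges; the 30--40% row
(weights 0.25/0.2/0.15/0.4, alpha 0.7, beta 0.1) is the default. Identity
ranges are half-open `[low, high)` — an identity of exactly 40 falls in
the "Above 40%" row — a convention chosen here to make preset selection
deterministic at the boundaries. `estimate_identity()` supports automatic
preset choice by running a quick matrix alignment first; the estimate is
rough and can differ from the final property alignment's identity.

The numeric values of the four default scales are sourced from standard
published scales (Kyte--Doolittle hydropathy; Zamyatnin residue volume;
Deleage--Roux coil conformational parameter; the thiol indicator), named
in the bundled file's header. They are ordinary literature scales, not
package-specific constants: every function accepts a user property file in
the documented format, and all tests that need concrete numbers use the
two-property example file whose values are printed in the format
documentation, keeping the test suite independent of the sourcing choice.

The property-file grammar is deliberately liberal in what it accepts:
surrounding whitespace, blank lines between blocks, CRLF endings, and
property names containing spaces are all tolerated; the alphabet line and
the 20-value count are strict. Weights that do not sum to 1 are rejected
by default, with an opt-in `renormalize` mode that warns.

## Accuracy metrics

Against a gold reference alignment, a test alignment is scored by the
developer/modeler pair: `f_D = n_I / l_R * 100` and `f_M = n_I / l_T * 100`,
where `n_I` counts residue-index pairs aligned identically in both, and
`Q = (f_D + f_M) / 2`; `Q_AVER` is the mean `Q` over a benchmark.

"Length" of an alignment is read here as its number of residue-residue
(aligned-pair) columns, not its total column count. The alternative
reading would give `Q(reference, reference) < 100` for any gapped
reference, contradicting the metric's role as an accuracy score; the
columns reading remains available via `length_mode = "columns"` for
comparison. A reference with zero aligned pairs leaves `f_D` undefined and
is an error; a test with zero aligned pairs has `f_M = 0` (and `n_I = 0`),
hence `Q = 0`.

The same aligned-pairs convention is used for the displayed percent
identity (`percent_identity()` exposes both denominators).

Method comparison (`compare_methods`) aligns each benchmark pair with the
property aligner and the matrix baseline, computes `D = Q1 - Q2`, and
categorizes pairs as better/equal/worse. Equality is exact floating
equality: both Q values are ratios of small integers times 100, so exact
ties are well defined.

## Grid search

`grid_search_property` exhaustively evaluates `Q_AVER` for every weight
vector on a simplex grid (all `k`-tuples of multiples of `weight_step`
summing to 1; 1,771 vectors for k = 4 at step 0.05) crossed with every
`(alpha, beta)` on the gap grid. Exhaustive enumeration is a feature:
fidelity of the protocol over speed, and the landscape (`keep_trace`) is
often as informative as the argmax. Ties are broken by enumeration order
(weights lexicographic, then alpha, then beta ascending), making results
platform-independent; the result is invariant to the order of the input
pairs.

The gap grid defaults to `0.1, 0.2, ..., 1.0` for both alpha and beta — a
10-point grid with 0.1 increments, anchored so that it covers every preset
value (all lie in `(0, 1]`); the range is configurable. The matrix
counterpart `grid_search_matrix` searches integer (opening, extension)
penalties, conventionally negative.

Over-represented families are capped before the search: families with more
than `max_pairs_per_family` (default 10) pairs are down-sampled uniformly
without replacement under a caller-supplied seed, implemented on a private
RNG stream so the caller's RNG state is untouched.

## The synthetic benchmark

Structure-based reference alignment databases are external and large, so
the package generates desk-scale benchmarks with *exact* known truth:
each family draws an ancestor (default length 120, uniform residue
frequencies); each pair evolves two descendants independently by per-site
substitution (default rate 0.35 per branch, substituting uniformly over
the other 19 letters) and per-site insertion/deletion events (default rate
0.03, split evenly, geometric lengths with mean 2, the simplest model
producing affine-like gap structure). The defaults were chosen to emulate
the mid-range of homologous-pair identity (the realized identities
concentrate around 30--50%, the range where alignment is informative but
not trivial); they are ordinary arguments, not constants.

The true alignment is maintained through the edit history in ancestor
coordinates — ancestral sites surviving in both descendants become aligned
pairs; sites deleted on one branch become gap columns; insertions are
unalignable and paired with gaps — so the reference is exact by
construction, never inferred by re-alignment. Realized percent identity is
computed from the reference and stored as an identity bin.

What the generator does *not* emulate: structural-superposition
references, real family phylogenies (pairs within a family share an
ancestor but evolve independently), position-dependent substitution
preferences, and length-dependent indel placement. Passing tests on
synthetic data therefore demonstrate correctness of the machinery —
recovery of planted parameters, exact metric arithmetic, determinism —
not performance on real structural benchmarks.

## Problem sizes used by the shipped tests

The test suite checks the aligners against exhaustive enumeration on 500+
random pairs of lengths up to 6 over a 4-letter sub-alphabet (enumeration
grows super-exponentially; 6 is where it stays pleasant), metric
invariants on 1,000 randomized toy alignments, and parameter recovery on a
50-pair benchmark with a k = 2, 5-point weight grid and a 5x5 gap grid —
sizes chosen so the whole suite runs in about a minute while every
property of interest is still exercised at scale.

## Known limitations

* No local or semi-global alignment, no multiple sequence alignment.
* The matrix used by the original web service for identity estimation
  (VTML200) is not redistributed here; any matrix file in BLAST layout can
  be supplied, and BLOSUM62 (via Biostrings) is the packaged default.
* Alphabets other than the 20 standard amino acids are out of scope.
* Q differences carry no significance test; `compare_methods` reports
  counts and percentages only.
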