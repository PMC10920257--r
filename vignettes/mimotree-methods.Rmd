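---
title: "Mapping mimotopes to conformational epitopes: methods and design"
author: "mimotree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mimotopes to conformational epitopes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimotree)
```

## The problem and the model

Phage-display panning against a monoclonal antibody yields linear peptides
(mimotopes) that bind the antibody because their physicochemical surface
mimics the antibody's epitope on the antigen. When only the antigen
structure is available — not the antigen–antibody complex — the epitope can
be estimated by mapping the mimotope sequences onto the antigen surface.
Two features of real mimotope data drive the design here:

* a mimotope is *similar, not identical*, to the epitope, so residue
  comparison must be a graded physicochemical similarity rather than
  identity; and
* parts of a mimotope often do not touch the antibody at all — they are
  spacers that let the peptide adopt its bound conformation — so an
  alignment that skips such a stretch should not be penalised, provided the
  skip is geometrically realisable on the antigen.

### Property distance

Each standard amino acid carries a five-component eigen-descriptor vector
$E_1..E_5$ from a multidimensional-scaling analysis of a large panel of
physical-chemical properties, with eigenvalue weights $\lambda_1..\lambda_5$.
The property distance between amino acids $A$ and $B$ is

$$PD(A,B) \;=\; \sqrt{\sum_{i=1}^{5} \lambda_i \,\bigl(E_i^A - E_i^B\bigr)^2}$$

and residues with $PD \le$ `pd_cutoff` (default 8, inclusive) are treated
as identical during mapping.

**Numeric provenance of the table.** The $E$ components are embedded from
the widely reproduced published descriptor table. The source analysis does
not travel with its eigenvalues in most reprints, so the packaged weights
$\lambda = (2050, 630, 360, 270, 220)$ were calibrated once, before any
benchmarking, so that the distance scale exhibits the documented behaviour
of this descriptor space: conservative substitutions (I/L 7.2, I/V 5.2,
S/T 6.5, K/R 6.7) fall below the matching cutoff of 8, the finest grouping
of the twenty amino acids appears near 9.5 (19 of 190 pairs), and
chemically dissimilar pairs land at 15–35 (D/I 30.9, G/W 31.1). Users with
the original eigenvalue table can supply it verbatim through
`read_descriptors()` (a TSV with a `# lambda ...` header line); every
downstream function accepts the override.

```{r}
m <- pd_matrix()
round(m[c("I", "L", "S", "T", "D"), c("I", "L", "S", "T", "D")], 2)
```

### Surface model

Per-residue SASA is computed with an in-package Shrake–Rupley
implementation: heavy atoms only, element-based van der Waals radii
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å), water probe 1.4 Å, and a fixed
deterministic golden-spiral sample of 960 points per atom. The point count
fixes determinism and gives per-residue areas within ~1% of an independent
Shrake–Rupley implementation on the same radii (this is asserted in the
test suite against python `biotite`). A residue is a *surface residue*
when its SASA strictly exceeds 5% of its maximal SASA, the reference
accessibility of its type in an extended Gly-X-Gly tripeptide (embedded
Miller-style table, overridable).

The *surface map* links two surface residues when their alpha-carbons are
within 4 Å (inclusive). Read literally, a CA–CA 4 Å criterion connects
almost exclusively sequence-adjacent residues (typical CA spacing 3.8 Å),
which biases seeds toward sequence-continuous stretches; an
`adjacency_metric = "any-atom"` option links residues whose closest heavy
atoms are within the cutoff and yields a denser, genuinely conformational
graph. The default follows the literal criterion; both are first-class and
the choice is recorded in every output.

### Seeds, connections, selection

For each mimotope and each start position in it, a depth-first search over
the surface map enumerates **all** simple paths whose residues match the
corresponding contiguous mimotope substring under the PD cutoff; every
matched path of length $\ge$ `min_seed_len` is kept as a seed (not only
the maximal ones — keeping prefixes preserves monotonicity in the cutoff
and gives later stages the full choice of join points). `min_seed_len`
defaults to 2: single-residue seeds would make gap bridging degenerate and
the enumeration explosive. Mimotopes are mapped N-to-C only; reversed-path
matching is not attempted.

Seeds of one mimotope are chained into **seed connections** in strictly
increasing, non-overlapping span order with pairwise-distinct antigen
residues. A gap of $g$ unmatched mimotope residues between consecutive
seeds is bridgeable when the backbone N-to-N distance between the last
residue of the earlier seed and the first residue of the later seed is at
most $(g+1) \times$ `nn_step` (default 3.5 Å per residue, the extended-chain
step; inclusive at the bound). Every chain of $\ge 1$ seeds is a
connection, so the matched positions of a gapped alignment carry exactly
the PDs they would carry without the gap — the no-gap-penalty principle.

The final prediction is the union of antigen residues over (i) all
connections with average PD exactly 0 — "exactly" meaning every
per-position PD is zero, avoiding floating-point tolerance games — and
(ii) connections whose matched length equals the global maximum across the
whole mimotope set with average PD in $(0,$ `avg_pd_max`$]$ (default 2).
Clause (i) admits perfect matches of any length $\ge$ `min_seed_len`;
"longest overall" in clause (ii) is the global maximum with all ties
included. Duplicate input sequences are removed (the algorithm is
frequency-blind), and enumeration ceilings (`max_seeds`,
`max_connections`) turn combinatorial blow-ups into advisory errors
suggesting a lower cutoff rather than unbounded run time.

### Parameter ledger

| parameter          | default | units | role                                   |
|--------------------|---------|-------|----------------------------------------|
| `pd_cutoff`        | 8       | PD    | residue match threshold (inclusive)    |
| `adjacency`        | 4.0     | Å     | surface-map edge cutoff                |
| `adjacency_metric` | `"ca"`  | —     | CA–CA or any-heavy-atom adjacency      |
| `nn_step`          | 3.5     | Å     | extended-chain step per gap residue    |
| `avg_pd_max`       | 2.0     | PD    | average-PD bound for longest matches   |
| `surface_fraction` | 0.05    | —     | surface threshold (strict >)           |
| `min_seed_len`     | 2       | res   | minimum seed length                    |
| `probe_radius`     | 1.4     | Å     | SASA probe                             |
| `epitope_delta`    | 10      | Å²    | true-epitope burial threshold (strict >) |

Sensible sweep ranges: `nn_step` 3.4–3.8 Å, `avg_pd_max` 2–3.

## True epitope and evaluation

Given an antigen–antibody complex and a user-declared chain split,
`true_epitope()` computes each antigen residue's SASA in the antigen
chains *alone, at complex coordinates* (no relaxation) and in the full
complex; residues losing strictly more than 10 Å² form the true epitope.
Waters and non-polymer ligands are stripped before both passes so they
cannot occlude the interface. Burial is non-negative up to discretisation
noise; the tests assert $\Delta SASA \ge -0.1$ Å².

`evaluate_prediction()` reports TP/FP/FN/TN, sensitivity
$TP/(TP+FN)$, precision $TP/(TP+FP)$, the Matthews correlation
coefficient, the upper-tail hypergeometric p-value
$P(X \ge k)$ for overlap $k$ between a size-$M$ prediction and a size-$n$
epitope in a universe of $N$ residues, prediction size and density
($M/N$). The evaluation universe defaults to **all** residues of the
selected antigen chains, not just surface residues: published per-case
densities are consistent with a whole-chain denominator, and a
surface-only universe would silently inflate significance (pass a custom
`universe` for that analysis). Zero denominators yield 0 for
sensitivity/precision/MCC and an empty prediction yields $p = 1$, so empty
predictions score worst without crashing.

Method comparisons use a one-sided Wilcoxon signed-rank test implemented
in the package because its conventions matter for reproducibility: zero
differences dropped, midranks for ties, the exact convolution distribution
up to 25 informative pairs (valid with midranks) and a tie-corrected
normal approximation with continuity correction beyond. The test suite
pins it against full sign-enumeration and against `stats::wilcox.test` on
tie-free data.

## Ensembles

`combine_union()`, `combine_intersection()`, `combine_majority()` (exactly
three inputs, keep residues present in at least two) and `combine_core()`
(base $\cup$ (a $\cap$ b)) fuse residue-level predictions from different
methods. Inputs use a common residue TSV dialect; the package does not try
to reconcile numbering across structures, but warns when two inputs share
zero residues. Provable properties — union sensitivity dominates every
member, majority $\subseteq$ union, core $\supseteq$ base — are asserted
over random cases in the tests.

## Synthetic fixtures: what they do and do not show

`make_toy_antigen()` writes backbone-only (N, CA, C, O) chains at ~3.8 Å
CA spacing on three geometries: `extended` (everything exposed), `helical`
(idealised α-helix) and `lattice` (a serpentine walk through a near-cubic
grid whose interior residues are genuinely buried below the 5% threshold).
A planted epitope is a set of sequence positions guaranteed exposed —
requesting a lattice-core position is an error. `make_mimotopes()` derives
peptides from the epitope sequence by per-position substitutions drawn
only from residues within `pd_budget` (default 8) of the original, plus
inserted internal spacer stretches, and reports the ground-truth alignment
of each peptide. All randomness sits behind one explicit seed; the same
seed reproduces byte-identical PDB text, and the fixture shipped for the
worked example is additionally pinned by a test against its generator.

Default study conditions for the end-to-end recovery experiment, chosen
once as a realistic small panning campaign: a 27-residue lattice antigen
with a 7-residue planted surface epitope, 6 mimotopes per set, substitution
rate 0.2, one 2-residue spacer, 20 replicate seeds. Under these conditions
exact mimotopes give complete epitope recovery, and the noisy condition
stays above 80% mean recovery with recovery non-increasing in the
substitution rate.

These fixtures exercise the *algorithmic* contracts — graph search,
gap geometry, selection algebra, burial — on structures whose ground truth
is known by construction. They are not physically realistic proteins: no
side chains (so SASA magnitudes are backbone-scale even though the 5%
thresholding logic is identical), idealised geometry, uniformly random
background sequence. Passing them shows the machinery is correct, not that
prediction accuracy on real antigens matches any benchmark; real-data
accuracy additionally depends on mimotope quality and the descriptor
weights discussed above.

## Numerical choices and degenerate inputs

* All threshold comparisons are inclusive (`<=`) except the two the
  contracts state as strict: the 5% surface-exposure rule and the 10 Å²
  burial rule (`>`).
* Ties for "longest matched length" are all included; `avg_pd == 0` means
  all-zero PDs, not a tolerance.
* First model only for multi-model PDB files; highest-occupancy altloc
  (ties by file order); hydrogens dropped; MSE treated as MET; other
  non-standard polymer residues remain SASA obstacles but are excluded
  from the surface map and never match.
* Empty mimotope files, unknown chains, overlapping chain sets, negative
  counts and infeasible hypergeometric tuples raise immediate errors;
  empty connection pools yield an empty prediction, not an error.
* Deterministic throughout: no randomness anywhere in the mapping path.

## Problem sizes in the shipped tests

The suite validates the search stages by exhaustive enumeration on random
toy graphs of up to 12 surface residues (100+ cases per stage), the
statistics on 100+ random tables and tuples, and the end-to-end pipeline
on 27-residue fixtures with 20 replicate seeds — sizes at which the
brute-force oracles are exact and the whole suite runs in about a minute.
The algorithm itself scales to real antigen chains; the enumeration
ceilings above are the guard rails for permissive cutoffs.

## Known limitations

* The eigenvalue weights are a documented calibration of the published
  descriptor space, not a verbatim reprint; exact reproduction of
  published PD values requires supplying the original table via
  `read_descriptors()`.
* The CA–CA 4 Å default adjacency favours sequence-local seeds; use
  `"any-atom"` for a true conformational search graph.
* No mimotope conformer modelling, docking, antibody-side modelling,
  paratope extraction, or structure repair; mmCIF input is out of scope.
* Predictions are residue sets with provenance, not per-residue
  confidence scores; precision is known to trail sensitivity, which is
  why the ensemble rules exist.
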