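# mimotree

Epitope prediction on antigen structures from phage-display mimotope sets.

Most B-cell epitopes are conformational: the residues an antibody contacts
sit close together on the folded antigen surface but far apart in sequence,
which makes them hard to find from sequence alone. Phage-display panning
against a monoclonal antibody yields short linear peptides ("mimotopes")
whose physicochemical surface mimics the antibody's true epitope without
necessarily sharing its sequence. `mimotree` maps such mimotope sets onto a
3D antigen structure to predict the epitope, for immunologists and
structural bioinformaticians designing vaccines or immunodiagnostics who
have an antigen structure (or homology model) and panning data, but no
antigen-antibody complex.

## The algorithm

Residue similarity is measured as a weighted Euclidean **property distance**
in a five-dimensional physicochemical eigen-descriptor space:

    PD(A, B) = sqrt( sum_i lambda_i * (E_i^A - E_i^B)^2 ),   i = 1..5

and two amino acids with PD <= 8 are treated as identical during mapping.
The pipeline is:

1. **Surface map.** Per-residue solvent-accessible surface area
   (Shrake-Rupley, probe 1.4 A); residues with SASA > 5% of their extended
   Gly-X-Gly maximum are surface residues, and two surface residues are
   adjacent when their alpha-carbons lie within 4 A (an any-heavy-atom
   variant is available).
2. **Seed search.** A depth-first search started from every mimotope
   position enumerates every simple path of adjacent surface residues that
   matches a contiguous mimotope substring position-by-position under the
   PD cutoff ("seeds", minimum length 2).
3. **Seed connection.** Seeds of one mimotope are chained in sequence
   order when each intervening mimotope gap of g residues, assumed fully
   extended at 3.5 A per residue, can span the backbone N-to-N distance
   between the flanking matched residues: distance <= (g + 1) * 3.5 A.
   Gaps carry no penalty — a spacer stretch that merely lets the peptide
   adopt its bound conformation does not down-weight the match.
4. **Selection.** The prediction is the union of residues from (i) all
   connections with average PD 0 (perfect physicochemical matches) and
   (ii) connections of the overall longest matched length with average
   PD in (0, 2].

For benchmarking, the **true epitope** of an antigen-antibody complex is
the set of antigen residues losing more than 10 A^2 of SASA upon binding,
and predictions are scored by sensitivity, precision, Matthews correlation,
a hypergeometric enrichment p-value, size and density. Residue-level
predictions from several methods can be fused by union, intersection,
majority vote, or a base method plus the intersection of two others.

## Worked example

A shipped toy fixture plants a seven-residue epitope (positions 2-8,
sequence `CAIDWTP`) on the surface of a 27-residue lattice-folded chain and
derives five mimotopes from it with 20% PD-bounded substitutions and one
two-residue spacer insertion (e.g. `CAIDPPWTP`, `CAIDFGPTP`):

```r
library(mimotree)
pdb  <- system.file("extdata/example/antigen.pdb",  package = "mimotree")
mims <- system.file("extdata/example/mimotopes.txt", package = "mimotree")

fit <- mimotree(pdb, mims)
fit
#> MimoTree epitope prediction
#>   mimotopes: 5   surface residues: 26 / 27
#>   seeds: 132   connections: 570 (longest matched length 8)
#>   predicted residues: 14

truth <- read.delim(system.file("extdata/example/truth.tsv",
                                package = "mimotree"))
evaluate_prediction(fit, truth$key[truth$is_epitope],
                    universe = fit$antigen$residues$key)
#> Prediction evaluation (universe: 27 residues)
#>   TP 7  FP 7  FN 0  TN 13
#>   Sensitivity 1.00  Precision 0.50  MCC 0.57
#>   p-value 0.00386  Size 14  Density 51.9%
```

All seven planted epitope residues are recovered (sensitivity 1.00); half
of the 14 predicted residues are spurious matches elsewhere on the surface
(precision 0.50), and the hypergeometric p-value (0.0039) says an overlap
this good is unlikely for a random 14-residue pick — the typical profile of
the method, which favours coverage over parsimony.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/mimotree.R` (`run`, `truth`, `eval`, `ensemble`, `fixtures`
subcommands; see `--help` output for flags).

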