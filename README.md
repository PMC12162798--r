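# motifavoid

Tools for studying **motif-avoidant attractors (MAAs)** in asynchronous
Boolean networks, together with an analysis workflow that quantifies how
rare they are in critical random ensembles, how node-deletion reduction
creates (and destroys) them, and how fragile they are to delays.

## Background

A Boolean network updates binary variables `x_1, ..., x_N` by logical rules
`f_i` of their regulators. Under the general asynchronous scheme one
randomly chosen variable is updated per step, so the dynamics form a state
transition graph (STG) on the `2^N` states whose **attractors** are the
terminal strongly connected components. A **trap space** is a subspace
(notation like `0*1*`) that the dynamics cannot leave; trap spaces are
update-scheme independent, and the inclusion-minimal ones each contain at
least one attractor. An attractor contained in *no* minimal trap space is
**motif-avoidant**: it evades every self-reinforcing stable motif that would
otherwise lock the system into a trap space. MAAs are the awkward case for
attractor-detection algorithms built on trap spaces, which is why their
prevalence matters.

The package implements, as plain R over explicit STGs:

- `.bnet` parsing/serialization and signed interaction-graph inference
  (`parse_bnet()`, `write_bnet()`, `interaction_graph()`);
- attractors, trap spaces, and MAA detection with the per-attractor metrics
  `(M, d, m)` — free variables of the joint enclosing trap space, number of
  oscillating variables, and minimal disagreement with the avoided trap
  space on the oscillating variables (`attractors()`,
  `minimal_trap_spaces()`, `find_maas()`);
- structural exclusion criteria: cycle-sign analysis and linear-cut
  (L-cuttability) testing (`maa_excluded_by_structure()`);
- node-deletion reduction and constant percolation (`delete_node()`,
  `reduce_max()`, `percolate()`);
- linear (delay) extensions, projected STGs, exhaustive minimal delay-set
  search, and the delay-count bound
  `(M - d)(M - 1) + m(m + 1)/2` (`linear_extend()`, `projected_stg()`,
  `minimal_delay_set_size()`, `delay_upper_bound()`);
- canalization measures: average sensitivity and prime-implicant effective
  connectivity (`sensitivity()`, `effective_connectivity()`);
- critical N-K random Boolean network ensembles (`2Kp(1-p) = 1`) and the
  three desk-scale experiments: MAA frequency, maximal-reduction statistics,
  and single-delay fragility, with Wilson 95% intervals
  (`maa_frequency_experiment()`, `reduction_experiment()`,
  `fragility_experiment()`).

## Worked example

The unique two-variable MAA network (both rules XNOR):

```r
library(motifavoid)
net <- parse_bnet("A, !A & !B | A & B\nB, !A & !B | A & B")
find_maas(net)[[1]]
#> Motif-avoidant complex attractor: 00 10 01
#>   enclosing trap space: **
#>   metrics per avoided minimal trap space:
#>   trap_space M d m bound
#> 1         11 2 2 1     1
```

The attractor `{00, 01, 10}` fills three corners of the state space but can
never reach the fixed point `11` (each variable would have to be updated
before the other). Its smallest enclosing trap space is the whole space,
which is not minimal — the minimal trap space `11` is avoided. With
`M = d = 2` and `m = 1` the bound says one delay suffices, and indeed every
single-edge delay eliminates it:

```r
single_delay_survey(net, find_maas(net)[[1]])
#>   from to eliminates
#> 1    A  A       TRUE
#> 2    B  A       TRUE
#> 3    A  B       TRUE
#> 4    B  B       TRUE
```

The star-shaped family generalizes this network; exhaustive search certifies
that its MAA needs `floor(N^2/4)` delays:

```r
minimal_delay_set_size(star_network(3))$size
#> [1] 2
minimal_delay_set_size(star_network(4))$size
#> [1] 4
```

## Analysis workflow

The numbered scripts under `analysis/` re-run the computational study at
desk scale and write tab-separated tables under `results/`:

1. `01_small_networks.R` — fixture networks, the exhaustive two-variable
   enumeration, and the prototypical 3-variable template survey;
2. `02_canalization.R` — sensitivity / effective connectivity of the eight
   MAA-generating rules vs the critical ensemble;
3. `03_rbn_frequency.R` — MAA frequency across critical N-K ensembles;
4. `04_reduction.R` — maximal-reduction statistics and reduced-network MAA
   frequency;
5. `05_delays.R` — star-family delay counts, a projected-STG example, and
   single-delay fragility.

Run each with `Rscript analysis/01_small_networks.R` (and so on) from the
repository root.

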