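---
title: "Detecting and dismantling motif-avoidant attractors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dismantling motif-avoidant attractors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifavoid)
```

## The model

A Boolean network consists of binary variables updated by logical rules of
their regulators. `motifavoid` represents every rule as a truth table over
its *essential* inputs: inputs whose value never affects the output are
pruned at construction time, so degrees, self-regulation and the signed
interaction graph are semantic properties of the rules rather than artifacts
of how an expression was written. Expressions use the `.bnet` dialect
(`!`, `&`, `|`, parentheses, constants `0`/`1`), with `&` binding tighter
than `|`.

Under the general asynchronous update scheme a single randomly chosen
variable is updated per step. The state transition graph (STG) on the `2^N`
states then has one edge per state-changing single-variable update;
non-changing self-transitions are omitted, so fixed points are exactly the
states with no outgoing edge. Attractors are the terminal strongly connected
components of the STG. A subspace (some variables fixed, the rest free,
written like `0*1*`) is a *trap space* when the dynamics cannot leave it,
which holds exactly when every fixed variable's rule is constantly equal to
its fixed value on the subspace — a condition on the rules alone,
independent of the update scheme.

A **motif-avoidant attractor (MAA)** is a complex attractor contained in no
minimal trap space; equivalently, its smallest enclosing trap space is not
minimal. For every MAA and every avoided minimal trap space the package
reports three numbers: `M`, the number of free variables of the smallest
trap space containing both the attractor and the avoided trap space; `d`,
the number of variables oscillating in the attractor; and `m`, the minimal
Hamming disagreement of an attractor state with the trap space's fixed
values, counted only over the oscillating variables. These feed the delay
bound described below.

## Algorithms and numerical choices

**Attractors.** STGs are built explicitly (vectorized over integer-encoded
states) and strongly connected components are delegated to `igraph`. The
explicit construction is capped at 22 variables; all experiments here use
far smaller networks, and anything larger is reported as skipped rather than
silently truncated.

**Minimal trap spaces** have three interchangeable engines:

- `"branching"` (default): depth-first search over partial assignments in
  `{0, 1, free}`. A partial assignment is abandoned as soon as some fixed
  variable's rule is constantly the *opposite* value on the current
  subspace — a sound pruning, because restrictions only shrink as more
  variables are fixed. Capacity is capped at 28 variables.
- `"brute"`: enumeration of all `3^N` subspaces (N ≤ 12). This is the
  oracle the other engines are tested against.
- `"attractor"`: when the full STG is available, the minimal trap spaces
  are exactly the inclusion-minimal elements of the set of smallest
  enclosing trap spaces of the attractors. This is not an approximation:
  every trap space contains an attractor, and if an attractor lies in a
  minimal trap space, its enclosing trap space equals that trap space.
  `find_maas()` uses this route internally because it is by far the
  fastest for the dense ensembles; the test suite asserts agreement of all
  three engines on a random corpus.

The smallest enclosing trap space of a state set is computed by closure:
start from the componentwise span and repeatedly free any fixed variable
whose rule violates its value somewhere in the current subspace. Trap spaces
are intersection-closed, so the fixpoint is the unique smallest enclosing
trap space.

**Structural exclusion.** Cycle-sign analysis treats an ambiguous edge
(sign 0) as both positive and negative. Non-positive cycles are also
detectable on the parity-doubled graph (an odd closed walk always contains
an odd simple cycle), but the analogous construction is *unsound* for
non-negative cycles — an even closed walk need not contain an even simple
cycle (two negative cycles sharing a vertex already give a counterexample).
The summary therefore enumerates simple cycles exhaustively (exact, and
cheap at the graph sizes used here), and the parity engine is kept as a
cross-checked secondary for the non-positive flag. The path criterion is
implemented in its weaker form — a path from a vertex on a non-positive
cycle to a vertex on a non-negative cycle, paths of length zero included —
which is the more conservative exclusion test.

**Linear cuts.** A linear node has in- and out-degree one (self-loops count
for both). A graph admits a linear cut when a linear node lies on every
cycle and on every path *with at least one edge* from a node with two or
more targets to a node with two or more regulators. Zero-length paths are
deliberately not counted: under a zero-length convention a node with both
multiple regulators and multiple targets could never be cut, and a fully
delay-extended network — in which every original node keeps its degrees —
would never qualify, contradicting the theorem that extending every edge
always produces a linear cut. L-cuttable networks have attractors in
bijection with minimal trap spaces, hence no MAAs; this is asserted on
random L-cuttable instances in the tests.

**Reduction.** Deleting a variable without essential self-input substitutes
its rule into its targets and re-normalizes, so substitution identities
(`X | !X`) can percolate into new constants — the mechanism by which
reduction sometimes *destroys* an MAA by creating a fresh stable motif.
Maximal reduction deletes the eligible variable with the fewest essential
inputs, ties broken by declaration order. This approximates the
smallest-representation-first policy used with decision-diagram tooling
without taking on that dependency; reduction order can change which final
variant is reached, so the policy is part of the reported protocol.
Substitutions that would push a rule past 20 inputs are refused; a trace
that cannot proceed is marked `skipped` and excluded from ensemble
denominators. An empty final network (everything percolated away) counts as
MAA-free with size 0.

**Delays.** Linearly extending `u -> v` inserts a fresh variable `d_u_v`
that copies `u`, and rewires `v` to read `d_u_v`. Canonical states (every
delay node equal to its parent) retain all original connectivity; memory
states can gain transitions (the delay remembers the parent's old value)
and lose others, and the gained transitions are what allow an MAA-derived
state to finally reach the avoided trap space. The projected STG collapses
the extended dynamics back onto original states: an edge connects two
states when the corresponding canonical states are joined by a path through
memory states only; self-edges are excluded for the same reason
non-changing self-transitions are. The closed-form bound on the number of
delays needed to eliminate an MAA is `(M - d)(M - 1) + m(m + 1)/2`; with a
complete interaction graph and maximal disagreement `m = d - 1` this equals
`E_max - (sqrt(E_max) - d/2)(d + 1) < E_max = N^2`. When an MAA disagrees
with an avoided trap space only on non-oscillating variables (`m = 0`) the
bound's hypotheses fail and the report shows `NA` instead. "Eliminated"
always means the extended network has *no MAA at all*, not merely that the
original attractor's image is trapped — the stricter reading, chosen
because the ensemble experiments count networks, not attractors.
`minimal_delay_set_size()` enumerates edge subsets in increasing
cardinality and lexicographic order, so the reported minimum is certified
by exhaustion of all smaller subsets.

**Canalization.** Sensitivity is the mean number of single-input flips that
change the output. Effective connectivity is the in-degree minus the mean
redundancy `k_r(x)`, where `k_r(x)` is the *unweighted* average number of
wildcard positions over all prime implicants (of the matching output class)
covering input state `x`; prime implicants come from a Quine–McCluskey
expansion-and-subsumption pass. The unweighted average over covering
implicants, with plain single-symbol wildcards, is the definition under
which the published per-rule values (for example 1.5625 for `A | B & C`)
are reproduced exactly, so no two-symbol schema refinement is used.

## The synthetic ensembles

`generate_critical_rbn(N, K, p)` draws, for each node, `K` distinct
regulators uniformly from all `N` nodes (self allowed) and `2^K` truth-table
bits i.i.d. Bernoulli(`p`). The default bias is the smaller root of
`2Kp(1-p) = 1` — the critical line where the exact expected sensitivity is
1; the two roots are statistically equivalent by negation symmetry (`K = 1`
has no real root and conventionally uses `p = 0.5`). Everything downstream
is reproducible bit-for-bit from the experiment seed.

The experiments use these desk-scale problem sizes, chosen so that each run
completes in minutes while leaving the binomial error comfortably below the
effect sizes of interest: 8,000 networks for the dense `N = K = 10` MAA
frequency, 20,000 (`N = 10`) and 1,000 (`N = 40`) networks for the `K = 2`
reduction statistics, and 100 MAA-positive networks for the fragility
survey (a fixed-positive-count stop rule; sampling stops once the target
count of MAA networks is reached). Frequencies are reported with the Wilson
95% interval with center `(m + 2)/(n + 4)` and half-width
`2 sqrt(1 + n * sigma^2)/(n + 4)`.

What the generator emulates — and what it does not: critical N-K ensembles
match published biological Boolean models in average sensitivity, but not
in their in-degree distribution, their abundance of canalizing rules, or
their input (source) nodes. Passing ensemble tests therefore says the
implementation reproduces the random-ensemble statistics, not that the same
frequencies hold for curated biological models, which are out of scope
here.

Two family/fixture choices deserve mention. The star-shaped MAA family is
realized as `f_i(x) = 1` iff the Hamming weight of `x` is 0 or `N` (XNOR at
`N = 2`): every network has the all-ones fixed point, an `N + 1`-state
star-shaped MAA through the zero state, and a complete interaction graph.
Under this realization states of weight 2 fall back toward the attractor
rather than climbing to the trap space, and the exhaustively certified
minimal delay counts come out at `floor(N^2/4)` (1, 2, 4 for `N = 2, 3, 4`)
— the property that defines the family. A plausible alternative,
`f_i(x) = 1` iff `weight(x) != 1`, produces the same attractors but lets a
*single* delay dismantle the `N = 3` member, so it is not the family meant
here. Second, the fixture in which reduction destroys an MAA was found by
randomized search and frozen in the test helpers; it is synthetic, and its
mechanism (deletion creates a stable motif that traps the oscillation) is
the point, not its particular rules.

The prototypical-template survey enumerates, exhaustively over all
`2^(n(2^n - 1))` candidate networks, the `n`-variable networks whose only
minimal trap space is the point `11..1` and whose MAA has edge-minimal
internal structure (every internal transition is critical for the
attractor's strong connectivity — removing any one destroys it as an
attractor). Patterns are grouped up to variable permutation, the only
relabel/negate symmetry fixing the trap space `11..1`. The class count
depends on this convention, which is why the survey reports its convention
alongside the count instead of asserting a particular number; the
two-variable survey yields exactly one template, and the three-variable
survey contains, among others, the single 6-cycle template and
near-complete-subspace templates, with every `M = d, m = 1` class
eliminable by one delay on a self-regulation.

## Limitations

- All dynamics are explicit: networks beyond ~22 variables (and extensions
  that exceed it) are out of reach by design; there is no symbolic
  (decision-diagram) backend. Ensemble runs record such cases as skipped.
- Only the asynchronous and synchronous schemes are implemented; random-set
  and most-permissive semantics are not.
- The reduction policy is deterministic; other elimination orders can reach
  different maximally reduced variants, so reduced-network statistics are
  tied to the stated policy.
- The constructive delay-placement procedure behind the closed-form bound
  is represented by the exhaustive subset search (which certifies
  minimality) plus the bound itself, not as a standalone algorithm.
- Analyses of curated biological model repositories are out of scope; the
  same functions apply to any user-supplied `.bnet` file within the size
  guards.
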