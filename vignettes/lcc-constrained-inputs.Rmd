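---
title: "Minimum input placement under longest-control-chain constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum input placement under longest-control-chain constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Linear dynamics on a directed network, `x'(t) = A x(t) + B u(t)`, are
structurally controllable through a set of input nodes `S` (each external
signal wired to exactly one node) when two purely combinatorial conditions
hold: some matching of the network leaves exactly the nodes of `S`
unmatched, and every node is accessible from `S`. The *longest control
chain* (LCC) of a placement is the largest distance from the nearest input
to any node,

```
l_LCC = max_w min_{v in S} d(v, w).
```

Minimum input sets obtained from maximum matchings alone tend to produce
long control chains, and long chains are exactly what makes the
controllability Gramian ill-conditioned and the control energy explode.
`lccontrol` solves the *LCC-constrained minimum input problem*: find a
smallest `S` that ensures structural controllability with `l_LCC <= l`.

The constraint maps onto two classical problems at once. Controllability is
a maximum matching in the bipartite representation `B` (split every node
`v` into `v+` and `v-`; each link `(v -> w)` becomes the edge `(v+, w-)`).
The chain constraint says `S` dominates the `l`-step accessibility graph
`G_l`, which links `v -> w` whenever a path of at most `l` steps runs from
`v` to `w`: every node must be in `S` or have an in-neighbor in `S` there.
Domination uses *closed* in-neighborhoods — a node in `S` covers itself at
distance zero; without that convention the covering constraint would be
infeasible for every source node. `G_l` itself carries no self-loops even
when a node sits on a short cycle; self-coverage lives entirely in the
closed neighborhoods. The joint problem is NP-complete, which dictates the
package's architecture: certified exact solvers at small scale, a
linear-time greedy approximation with a built-in optimality certificate at
large scale, and bounds that bracket the answer everywhere.

## Exact solvers

`solve_ilp()` writes the problem as an integer program with one binary
variable per link (`1` = in the matching): each `v+` and each `v-` touches
at most one matched link, and every closed in-neighborhood in `G_l` must
contain at least one unmatched node. The objective counts unmatched minus
copies, i.e. inputs. Models are assembled in R and solved by the HiGHS
branch-and-bound (single-threaded, zero relative gap), so `certified_optimal`
means a proven optimum, and a time limit degrades gracefully to the
incumbent with the certificate withdrawn.

The plain formulation has a weak LP relaxation at intermediate densities:
the LP happily matches almost everything while covering neighborhoods with
fractional slack. We therefore first solve the (much easier) set-cover
program for the minimum dominating set `N_DS` of `G_l` and add the valid
inequality "matched links `<= n - N_DS`". This changes neither the feasible
set nor the optimum, but lifts the root bound enough that instances that
previously needed minutes certify in seconds.

`brute_force_min_inputs()` enumerates candidate sets by increasing size
(sources forced in, start at the matching deficiency) and is the
implementation-independent oracle for everything else: it shares no code
with the ILP path, deciding matchability with its own augmenting-path
routine. It is guarded to 12 nodes.

## The coupled leaf-removal approximation

The greedy solver couples two classical decimation schemes: Karp–Sipser
matching leaf removal (MLR) on `B` and generalized dominating-set leaf
removal (DSLR) on `G_l`, with node labels *unobserved / observed /
dominating*. Each rule fires only when it is locally optimal for **both**
problems:

* **M+** — a leaf `v+` is matched unconditionally (which plus copies are
  matched never changes the input set).
* **M−** — a leaf `v-` is matched only when `v` is observed and has no
  remaining out-links in `G_l`, i.e. only when `v` can no longer be forced
  into the dominating set.
* **DS1** — a node that loses all predecessors must dominate; its
  successors become observed.
* **DS2** — an unobserved node with a single predecessor and no unobserved
  successor promotes that predecessor — but only if its own minus copy is
  already matched, otherwise the step could clash with the matching.
* **DS3** — an observed node with a single unobserved successor drops that
  link, under the same matching precondition.

Cross-updates tie the two graphs together: a minus copy isolated in `B` is
unmatched and hence an input (dominating), and a dominating node has all
edges at its minus copy removed, along with all incoming accessibility
links to it and to its newly observed successors. One asymmetric corner is
handled explicitly: M+ can match a minus copy whose node is *later* forced
to dominate (possible after repeated DS3 deletions); the pair is then
dropped from the matching, which stays a valid matching and restores the
invariant that the inputs are exactly the unmatched minus copies.

If the rules exhaust both edge sets the result is provably optimal
(`certified_optimal = TRUE`). Otherwise the remaining edges form the M-core
and DS-core, and a heuristic step is taken: match the minus copy of the
node with the smallest total degree in `G_l` (the node least likely to be
needed as a dominator), or, once `B` is empty, commit the highest-degree
node as dominating. Ties and the matching partner are drawn uniformly at
random; a single integer seed governs a run, and the stalled core size
itself is seed-independent (a property the test suite checks rather than
assumes).

Two readings of "smallest degree in `G_l`" are defensible — the degree in
the original accessibility graph or in its decimated remainder. We
benchmarked both against certified ILP optima on static scale-free
ensembles (`N = 300`, `gamma = 3`): the original-graph reading keeps the
mean excess input fraction below about 0.04 everywhere we scanned, while
the live-graph reading degrades to about 0.07 at intermediate density. The
original reading is therefore the default (`heuristic_degree = "original"`),
with the alternative kept as an option. The uncoupled engines
(`mlr_matching()`, `dslr_dominating()`) are exposed for core-percolation
baselines, and `naive_input_set()` gives the union-of-both-solutions
comparator the coupled scheme is designed to beat.

### What the core is and is not

The decimation stalls on genuinely hard structure (the extensive cores that
appear at high density), but also on small rule-immune residues: a source
strongly connected component, or an observed node with several unobserved
successors each of which has several predecessors. Below the percolation
threshold these residues occupy well under a percent of edges and the
heuristic resolves them — in our sub-threshold experiments the greedy still
matches the exhaustive optimum — so "empty core" should be read as "core of
vanishing relative size", which is also all that a finite-size scan can
certify.

### The full-reachability sentinel

`ell = Inf` means controllability with no chain constraint and maps to
`ell = n`. Materializing the transitive closure is the only expensive step
at that setting, and it is avoidable: dominating the closure is equivalent
to hitting every source SCC, so the engine runs on the reachability edges
out of source-SCC members only. Feasible sets and optima are unchanged
(the tests cross-check this against brute force on the full closure);
closures with tens of millions of edges shrink to a few million.

## Bounds

`compute_bounds()` reports `N_M` (maximum-matching deficiency), `N_DS`
(minimum dominating set of `G_l`, exact via set cover by default up to 2000
nodes, otherwise DSLR-approximate and flagged), and the source count `N_s`.
The reported bounds are `min(N_M, N_DS) <= N_i(l) <= N_M + N_DS - N_s`; the
upper bound is constructive (unmatching the dominated-but-matched nodes of
a maximum matching), and sources — always unmatched *and* always
self-dominating — are the overlap correction. With an approximate `N_DS`
the lower bound is only indicative, and is labelled as such.

## Network models

Both generators fix the link count exactly rather than using per-pair coin
flips — lower variance, and the natural reading of the static model.
Throughout the package the density parameter `c` is the **average
in-degree**, equal to the average out-degree: a realization has
`L = round(N * c)` links and mean total degree `2c`. This convention is
forced by the physics rather than taste: the bipartite representation of a
directed graph with per-direction mean `c` is locally a Poisson(`c`) graph,
so Karp–Sipser leaf removal develops an extensive core at `c = e`, the
classical threshold, and that is exactly where our measured M-core onset
lands (`2.7 ± 0.1` on a 0.1-spaced grid at `N = 10^5`). Halving the link
count moves the onset to `2e` and breaks every downstream quantitative
anchor.

* `er_directed(n, c)` draws `round(n*c)` distinct ordered pairs uniformly;
  no self-loops or multi-links (self-loops in *user* data are legal and
  kept by the reader, they are simply never generated).
* `sf_static(n, c, gamma)` is the hidden-parameter static model: node `i`
  carries weight `i^(-1/(gamma-1))`, sources and targets are drawn
  independently in proportion to the weights, duplicates rejected. Both
  degree tails decay with exponent `gamma`; `gamma -> Inf` recovers the ER
  model. The same weight sequence serves both directions — the model gives
  no reason to break in/out symmetry.
* `rewire_degree_preserving(g, epsilon)` performs
  `ceiling(L/2 * log(1/epsilon))` double-edge swap trials (about `6.9 L`
  at the default `epsilon = 1e-6`), preserving both degree sequences
  exactly while destroying higher-order structure.

What the generators do *not* emulate about real networks: degree
correlations, communities, reciprocity and motif structure. Tests passing
on these ensembles validate the solvers and the ensemble-level physics;
they say nothing about how far a particular real network's input count
deviates from its degree-sequence expectation — measuring exactly that gap
is what `randomization_comparison()` is for.

## Control energy

`lti_system()` builds `A` (by default unit weight on every link — the
transparent choice when no weighting is prescribed; uniform-random and
diagonally stabilized schemes are options, and the scheme is recorded in
the object) and a one-nonzero-per-column `B`. The finite-time Gramian
`W = ∫_0^tf exp(At) B B' exp(A't) dt` comes from the block-exponential
identity (exponential of `[[-A, BB'],[0, A']]`), accurate to machine
precision on the closed-form fixtures. Gramians of poorly placed inputs are
*expected* to be numerically singular — that is the phenomenon under study
— so `tr(W^-1)` is reported from eigenvalues floored at `1e-12` of the
largest, together with a singularity flag, and an independent ODE oracle
(the differential Lyapunov equation) backs the implementation in the tests.

`lcc_vs_random_experiment()` compares, per input budget `M`, the LCC-aware
placement (solve at the smallest `l` with `N_i(l) <= M`, fill the remaining
budget randomly) against matching-based placement topped up randomly. The
published comparison states the caption's budget rule with an empty
interval (`N_i` is nonincreasing in `l`); we implement the evident intent —
the smallest feasible `l` — which reproduces the advertised breakpoints
where `l` changes. Results are reported as energy ratios between the two
strategies, which is also the only scale on which the unknown link weights
of the original experiment drop out.

## Numerical and reproducibility choices

* Randomness enters only through generator sampling, rewiring, heuristic
  tie-breaks and random input top-ups; every entry point takes a seed, and
  ensemble drivers derive per-replicate seeds from it.
* HiGHS runs single-threaded with zero MIP gap: certified optima are
  reproducible.
* Ties in the heuristic are broken uniformly (reservoir sampling), not by
  node id, so seed averaging is meaningful.
* Degenerate inputs: the edgeless graph (every node is an input), the
  single node, complete digraphs, self-loops (matchable; a self-looped
  node can cover itself), and `ell >= n` all reduce to the documented
  sentinels; duplicate links collapse with a warning on read.
* The test suite runs its ensemble checks at reduced size — 200 random
  digraphs for the oracle cross-validation; six replicates per grid point
  for the greedy-versus-ILP scan (`N = 300`); six replicates at `N = 10^4`
  for the LCC-cost anchors; two replicates at `N = 10^5` for the core
  onset — sizes chosen so the whole suite stays a routine run while the
  standard errors remain an order of magnitude below the tolerances being
  tested. `scripts/acceptance.R` re-runs the same quantities at the fuller
  ensemble sizes stated in its header.

## Known limitations

* Exact solutions are practical to a few thousand links; beyond that only
  the greedy and the bounds apply.
* The greedy's error is largest at intermediate density and `l = 2`, where
  the coupled core is largest; certified runs are exact, uncertified runs
  carry no per-instance error bound beyond the bracketing bounds.
* Energy computations are dense linear algebra — intended for the
  tens-of-nodes systems where Gramians are meaningful at double precision,
  not for large networks.
* The combinatorial layer treats weights as free (structural
  controllability); all weight-dependent statements live in the energy
  module and inherit its weight-scheme caveat.
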