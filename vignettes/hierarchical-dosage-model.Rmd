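---
title: "The multilayer dosage model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multilayer dosage model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierspread)
```

## The model

`hierspread` simulates the spread of an innovation (a new practice, tool or
procedure) through a large organization, modelled as a generalized-contagion
elaboration of the SIR compartment model.  Every node is susceptible (S,
unaware or unconvinced), infected (I, an active promoter of the innovation)
or removed (R, a permanent rejector).  Unlike plain SIR, transitions are not
driven by per-contact probabilities but by *doses* accumulated in a rolling
memory:

* each node $i$ has an individual adoption threshold
  $d_i^\* \sim \mathcal{N}(1,\,0.5)$ truncated to be strictly positive,
  giving the population a heterogeneous reluctance to change;
* one micro-step is one interaction: a *listener* is drawn uniformly from
  all nodes, then a *speaker* uniformly from the listener's neighbours,
  pooled over every layer of the network;
* an infected speaker confers a dose
  $\sim \mathcal{N}(0.5\langle d^\*\rangle,\,0.25\langle d^\*\rangle)$
  (with the nominal threshold mean $\langle d^\*\rangle = 1$), truncated at
  zero; any other speaker confers a zero dose, and a listener with no
  neighbours logs a zero dose too, so memory always advances;
* the listener keeps its last $T = 5$ doses; writing $D_{t,i}$ for their
  sum, a susceptible listener with $D_{t,i} \ge d_i^\*$ adopts
  ($S \to I$), while an adopted listener with $D_{t,i} < d_i^\*$ abandons
  with probability $r = 1/T = 0.2$ per activation ($I \to R$, absorbing).

The multilayer mechanism under study is the *hierarchical dose override*:
when an infected speaker sits on a higher layer than its listener (a
manager speaking downward along an existing reporting edge), the dose
equals the listener's threshold, which guarantees an immediate switch but
leaves the listener exposed — its memory holds one large dose that ages out
after $T$ interactions, so an organizational mandate dies unless peers
reinforce it.  Disabling the override (`manager_override = FALSE`) is the
*flat network* ablation: identical edges, monoplex dynamics.  `si_mode`
forces $r = 0$, turning the process into an SI system whose only absorbing
state on a connected graph is full consensus; there the natural observable
is time-to-consensus rather than peak adoption.

Since R is absorbing and removed nodes still confer zero doses, the only
long-run outcome with $r > 0$ is extinction of I.  The memory window
$T > 1$ nevertheless creates metastable adopted communities with long
survival tails, which is why persistence metrics (survival of the peak
population at a late checkpoint) matter alongside peak adoption.

### Switch condition at exactly the threshold

The override confers a dose *equal* to the listener's threshold and is
described as guaranteeing a switch; because remembered doses are
non-negative, that guarantee holds exactly when the adoption condition is
$D \ge d^\*$.  We therefore use $\ge$ for adoption and the strict $<$ for
removal eligibility, which makes the two conditions exhaustive and
mutually exclusive.  For the continuous dose distributions the boundary
case has measure zero, so this choice only matters for the override.

### Random-number architecture

Each run derives every random quantity from a single integer master seed
through five independent substreams: thresholds (consumed in node-id
order), listener choices, speaker choices (a single uniform variate
mapped onto the neighbour list), dose draws and removal draws.  Two runs
with the same master seed on two graphs over the same node set therefore
share thresholds and attempted transmission pathways — the
common-random-number (CRN) contract that makes paired comparisons
(hierarchical vs flat, removal-rate grids, seeding strategies) sharp.
`run_ensemble()` rejects duplicated master seeds for this reason.
Truncated normals are sampled by resampling rather than clipping, which
preserves the conditional distribution shape; with the default parameters
the truncation point sits two standard deviations below the mean, so the
realized threshold mean is 1.028 rather than 1 — the dose scale
deliberately uses the nominal mean 1, keeping the dose distribution
identical across realizations.

## Synthetic hierarchies

`build_synthetic_hierarchy()` composes three steps:

1. **Staff layer** — a random geometric graph: `n_staff` points uniform in
   the unit square, edge iff Euclidean distance $\le
   r = \sqrt{\langle k\rangle / (N_{\text{staff}}\,\pi)}$ (inclusive
   boundary, no wraparound).  The radius formula targets the requested
   mean degree at bulk density; hard boundaries thin the realized mean by
   roughly 7% at the default size, which is a property of the standard
   construction and is shared by the reference results.
2. **Fluid-communities partition** into exactly `c = round(0.06 n_staff)`
   communities (igraph's fluid-communities implementation), chosen because
   it returns a requested community count and covers the layer, so the
   mean community size is exactly `n_staff / c` (16.667 at the standard
   1000/60 configuration).  The algorithm requires a connected graph; at
   the default density a disconnected draw is rare, and the generator
   retries with a shifted seed a bounded number of times rather than
   patching the graph.
3. **Management layer** — one manager per community, wired down to every
   member of its community, with manager–manager wiring per topology:
   `isolated` (none), `full`, `er` (G(c, p)), `rgg` (same radius formula
   with $n = c$), or `ba` (preferential attachment with
   `round(k/2)` edges per node, since a BA graph's mean degree is about
   twice its attachment count).

Experiment drivers regenerate the network for every replicate, so reported
means average over both structural and dynamical randomness; fixed-graph
paired designs use `run_ensemble()` on one graph with shared master seeds.

## Empirical-style networks and fixtures

`read_org_network()` / `write_org_network()` exchange graphs as plain CSV
node lists (`node_id, level`) and edge lists (`source, target`), the format
of published organizational datasets; `threshold_weighted_edges()` turns
weighted co-working records into edges with a strict `weight > threshold`
rule, and `choose_weight_threshold()` scans the unique weights for the
cutoff matching a target mean degree.  `layer_stats()` reports per-layer
and total mean closeness, degree and clustering.  Closeness is computed on
the full multilayer graph — per-layer subgraphs of a tree-coupled
hierarchy are typically disconnected, which would leave closeness
ill-defined — and uses the component-size-normalized form, which reduces
to ordinary normalized closeness on connected graphs.

Because the original personnel data cannot be redistributed, the package
generates two synthetic stand-ins that reproduce the *topological
contrast* between an administrative and a collaboration network:

* `make_lineorg_fixture()` — disjoint department cliques under a manager
  tree with sibling-group cliques and a single apex; highly modular,
  clustering near 1 on the base layer, closeness low.
* `make_project_fixture()` — the same tree skeleton, but intra-layer edges
  from a Chung–Lu model with Pareto-distributed expected degrees whose
  mean rises through the first three layers, emulating a centralized
  co-working structure in which lower management is the hub.

At the standard shape (60 departments of mean size 16.7 under levels of
12 and 3 groups plus an apex) both fixtures land near mean degree 20,
matching the scale of the published networks.  The fixtures reproduce
the structural contrast — insular cliques versus a centralized hub — but
not the exact degree sequence, layer sizes (1787/115/33/6/1) or the
370-hour co-working weight distribution of the original data, so tests on
fixtures check orderings and invariants rather than the published
empirical-network numbers.

## Seeding strategies

`select_seeds()` places the initially adopted nodes: uniformly at random
within a layer (the default experimental condition; the standard
"established community" size is `round(0.015 N)` against the minimal
single seed), or by influence rankings — total degree, VoteRank (iterated
voting where an elected node's neighbourhood loses voting ability), or
onion layer (the peeling round of the onion decomposition, a refinement of
the k-core number in which the peeling threshold never decreases inside a
core).  Rankings are computed on the full multilayer graph and then
filtered to the requested layer, because inter-layer edges are precisely
what make managers influential; an induced-subgraph ranking would discard
them.  Ties break by higher degree then lower vertex index so that
deterministic strategies are reproducible and CRN-comparable.

## Numerical and scale choices

Replicate counts in the bundled tests and in `scripts/acceptance.R` are
300–500 per condition with early stopping on extinction, against a
micro-step cap of $10^6$ (about 1000 epochs at $N \approx 1000$, one epoch
being $N$ micro-steps).  At these sizes the Monte-Carlo standard error of
a mean peak-adoption fraction is 0.003–0.01 depending on the seeding
(single-seed conditions are strongly bimodal — most runs die at once — and
carry the largest variance), which is the precision the documented
tolerances reflect.  Long-horizon persistence runs extend the cap to
cover the checkpoint epoch (e.g. 515) instead of relying on trajectory
extrapolation; runs that end early are carried forward at their final
state, and survival curves average unconditionally over all replicates,
extinct ones contributing zero.  Within a run, per-epoch S/I/R counts are
recorded at epoch boundaries while the peak adopted count is tracked at
micro-step resolution; survival normalizes by the recorded trajectory
peak so that the curve equals 1 at the peak epoch exactly.

## Known limitations

* The dose memory is a strict sliding window; no forgetting curves or
  edge-weighted doses.
* There is no $S \to R$ transition and no re-susceptibility; removed
  nodes keep conferring zero doses.
* The synthetic generator produces two layers; deeper hierarchies come
  from the fixture generators or external data.
* Fixture-based results are qualitative stand-ins for the empirical
  networks, as described above.
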