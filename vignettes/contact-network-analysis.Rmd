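---
title: "Contact-network analysis of conformational ensembles with dcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-network analysis of conformational ensembles with dcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcna)
```

## The model

A conformational ensemble is reduced to a set of binary residue–residue
contact events. Two network nodes are in contact in a frame when **any**
pair of their heavy atoms lies within a cutoff (default 4.5 Å, boundary
inclusive: a pair at exactly 4.5 Å counts). Same-chain polymer pairs with
sequence separation below 3 are excluded — nearest neighbours and i, i+2
pairs are in near-permanent contact for trivial covalent reasons and would
dominate every network. Ligands (ATP, an allosteric modulator) are single
nodes aggregating all of their heavy atoms and are exempt from the
separation rule. The contact probability of a pair,

$$p_c = \frac{\#\{\text{frames containing the contact}\}}{\#\text{frames}},$$

is estimated per replica and averaged (unweighted) over replicas; a pair
missing from a replica contributes 0. The underlying assumption is that
frames are exchangeable samples of a stationary ensemble, so $p_c$
estimates a per-state Bernoulli parameter — which is exactly what the
synthetic generator plants (below).

Three analyses build on the tables:

* **Consensus network and communities.** An edge requires
  $\min_e p_c^{(e)} \ge 0.9$ over all ensembles; its weight is the mean.
  The network is divided by Girvan–Newman removal of the highest-betweenness
  edge (recomputed after every removal), and each partition arising when
  the component count grows is scored with Newman–Girvan modularity
  $Q = \sum_i (e_{ii} - a_i^2)$ evaluated on the *original* network. The
  maximum-$Q$ partition is selected.
* **dCNA.** $\Delta f(A,B) = \sum_{i \in A, j \in B, i<j}
  \left[p_c^{\mathrm{bound}} - p_c^{\mathrm{free}}\right]$, including the
  within-community case $A=B$; $|\Delta f| \ge 0.1$ is flagged significant
  (inclusive). The total over all community pairs equals the total over all
  node pairs exactly, a conservation property the tests verify.
* **Multiensemble correlation.** With $x_e = \log_{10} K_e$ of each
  modulator's activity constant, Pearson's $\rho$ is computed between $x$
  and each pair's $p_c$ vector, and between $x$ and each community pair's
  summed inter-community $p_c$. Function-linked contacts are those with
  $|\rho| > 0.5$ plus the top-3 per sign within each community pair.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `cutoff` | 4.5 | Å | heavy-atom contact distance, inclusive |
| `min_separation` | 3 | positions | same-chain exclusion (i to i+n, n ≥ 3) |
| `rare_floor` | 0.10 | probability | drop pairs below this in **every** ensemble |
| `consensus_threshold` | 0.9 | probability | stable-contact requirement in **every** ensemble |
| `delta_threshold` | 0.1 | probability sum | dCNA significance on \|Δf\| |
| `correlation_cut` | 0.5 | — | \|ρ\| threshold for function-linked pairs |
| `top_k` | 3 | pairs | per-sign ranking depth |
| `log_base` | 10 | — | activity transform; ρ is base-invariant |

The rare-contact floor is applied to ensemble-averaged tables, and a pair
survives if it reaches the floor *anywhere*: a contact rare in all states
carries no comparative signal, while a contact rare in one state and common
in another is precisely the object of interest. Both choices (averaged vs
per-replica, and any-vs-all) are the defaults but the functions accept any
list of tables, so per-replica strictness is a matter of what you pass in.
Likewise the consensus rule is per-ensemble; feeding replica tables to
`build_consensus()` gives the stricter per-replica reading.

Activity constants of different experimental types (AC50, EC50, IC50, K_d)
are pooled on one μM scale, with the type recorded per modulator so users
can stratify; `filter_activity()` implements the K_d-only exclusion (a
modulator with an AC50 *and* a K_d is kept, via its AC50). Note that ρ is
computed against log K literally; because lower AC50 means higher potency,
mapping the sign of ρ onto "activity increases/decreases" is an
interpretation step the package deliberately leaves to the user.

## Numerical and algorithmic choices

* **Tie-breaking.** Equal edge betweenness (within a 1e-9 relative
  tolerance, since betweenness values are ratios computed in floating
  point) is resolved toward the lexicographically smallest (node_i,
  node_j); equal Q is resolved toward fewer communities. Partitions are
  therefore reproducible run to run.
* **Partition series.** For a connected network the series starts at the
  first split: community *detection* always divides the input, so the
  undivided network is not a candidate (its Q = 0 would otherwise beat any
  split of, e.g., a single edge). A disconnected input contributes its
  component partition as the first entry — that is what makes two
  disconnected triangles score their natural Q = 0.5 without removing an
  edge.
* **Betweenness is unweighted** for edge removal: consensus edges all have
  weights near 1 by construction (p_c ≥ 0.9), so weighting adds noise, not
  information. A weighted Q is available (`weighted_q = TRUE`).
* **Superposition** is rigid-body least squares (via `bio3d::fit.xyz`)
  onto the first frame by default, over the backbone (N, CA, C, O)
  selection; the test suite checks it against an independent closed-form
  quaternion solution to 1e-8. Fitting is per-replica; pass an explicit
  `reference` to share one across replicas.
* **Undefined correlations** (zero variance in p_c, or a community pair
  with no retained pairs) are reported as `NA`, never coerced to 0, so
  they cannot silently enter rankings.
* **Degenerate inputs**: an empty consensus edge set is a warning, not an
  error; a single-frame RMSF is zero with a warning; slicing longer than
  the trajectory, collinear superposition selections, non-positive
  activities, and partitions missing a node are errors naming the problem.

## What the synthetic generator emulates

`gen_contact_ensembles()` plants the statistical structure the analysis
assumes, with known ground truth:

* contiguous residue blocks with within-block contact probability
  `p_within` (default 0.95) and cross-block `p_between` (0.02) — the
  block structure the consensus network should recover;
* `n_responders` cross-block contacts following
  $p = \mathrm{clip}(b_0 + b_1 x_e + \varepsilon)$, $\varepsilon \sim
  N(0, \texttt{noise\_sd})$ drawn once per ensemble and pair, with
  $x_e = \log_{10} K_e$ — the function-linked contacts the correlation
  stage should rank;
* independent Bernoulli contact formation per frame and replica. Counts
  are drawn as the equivalent binomial; `snapshots = "frames"`
  materializes the frame-level matrix when the frame-major CSV export is
  wanted.

Defaults mirror the study design the package targets: 8 modulator-bound
ensembles × 3 replicas, activity constants log-uniform over 2–34 μM (the
span of the bundled 8-modulator table), slopes ±0.1 with noise 0.02, and
1500 frames per replica — the analyzed 1.5 μs tail of a production run at
an effective 1 ns spacing. Responder probabilities are clipped to
[0.02, 0.98] so no column degenerates to all/none (which would make ρ
undefined); the modulator-free reference uses the planted line's x = 0
value, so each responder's bound-vs-free difference is $b_1 x_e$ by
construction. One global seed expands deterministically into per-ensemble
and per-replica child seeds, so any replica can be regenerated alone.

`gen_toy_structure()` makes the geometric counterpart: blocks are spatial
clusters 30 Å apart (an octahedron-plus-centre layout guarantees full
mutual contact for blocks of up to 7 residues; larger blocks gain an outer
shell that remains adjacent but not a complete clique), and
`gen_coordinate_ensemble()` adds Gaussian jitter and a two-state rigid
translation with an exact open-state count, so contact detection from
coordinates can be tested against deterministic expectations.

What the generator does **not** emulate: energetics, correlated contact
formation (every pair is independent given its probability), slow
conformational drift within a replica, and solvent or entropy effects.
Passing tests therefore demonstrate that the statistical machinery is
correct and well-calibrated under the model's assumptions — not that any
particular force field or sampling protocol yields converged contact
probabilities.

## Problem sizes and what the validation shows

The validation suite runs on deliberately small instances chosen to make
the statistics sharp: oracle-equivalence checks (contact detection vs an
all-pairs scan, modularity vs direct summation, Δf vs an exhaustive pair
loop, Pearson vs the covariance formula) on graphs and toys of up to ~50
residues over ~100 random instances; planted-partition recovery on 20
graphs of 4 blocks × 15 nodes (within 0.95 / between 0.02), where the
Girvan–Newman partition attains a mean adjusted Rand index of 1; and
responder-sign recovery over 20 synthetic studies of 8 ensembles at slope
±0.1 and noise 0.02, where 2000-frame sampling gives per-ensemble binomial
noise (~0.011) well under the planted signal. A full end-to-end demo (60
residues, 4 blocks, 8 + 1 ensembles, 3 × 1500 frames) recovers the planted
partition exactly and is byte-identical on rerun under a fixed seed.

## Known limitations

* Girvan–Newman recomputes betweenness after every removal; cost grows
  quickly beyond a few thousand consensus edges. For kinase-sized systems
  (a few hundred residues, ~10³ consensus edges) this is minutes, not
  hours, but no faster alternative (Louvain/Leiden) is wired in.
* Binary trajectory formats (DCD/XTC) are out of scope; ensembles enter as
  multi-model PDB, the plain frame CSV, or precomputed contact tables —
  the documented adapter point for heavier IO stacks.
* No p-values or multiple-testing control accompany ρ; with typically 6–8
  ensembles the null spread of a Pearson coefficient is wide, which is why
  ranking is combined with a magnitude cut and why community-level sums
  (which average out pair noise) are reported alongside.
* Altloc handling keeps the first conformer of each alternate-location
  set; occupancy-aware selection would need the occupancy column to be
  trustworthy, which synthetic and minimized structures rarely guarantee.
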