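# dcna — difference and multiensemble contact network analysis

`dcna` analyses molecular-dynamics conformational ensembles as residue
contact networks. It is aimed at structural biologists comparing a protein's
ensembles across perturbations — typically an enzyme simulated free and in
complex with a series of allosteric modulators of known potency — who want
to know *which* residue–residue interactions change with the perturbation
and which of those changes track function.

## The method

For each ensemble, a **contact** exists in a frame when any two heavy atoms
of two nodes are within 4.5 Å; same-chain residue pairs closer than three
sequence positions (i to i+n, n ≥ 3) are excluded, and each ligand (ATP, a
modulator) is a single node exempt from that rule. The **contact
probability** p_c of a pair is the fraction of frames containing the
contact, averaged over replicas. Pairs with p_c < 0.10 in every ensemble
are discarded as too rare to compare.

Downstream, three analyses share these tables:

* **Consensus communities.** Contacts with p_c ≥ 0.9 in *every* ensemble
  form the consensus network. Girvan–Newman edge-betweenness removal
  generates a partition series, each partition scored by Newman–Girvan
  modularity Q = Σᵢ (eᵢᵢ − aᵢ²) on the original network; the maximum-Q
  partition defines the residue communities.
* **dCNA.** For a bound-vs-free comparison, the community-pair difference
  Δf(A,B) = Σ_{i∈A, j∈B} [p_c^bound − p_c^free], flagged significant when
  |Δf| ≥ 0.1. Pairs involving a node present in only one system (the
  modulator itself) are reported separately as binding contacts.
* **Multiensemble correlation.** With an activity constant K (AC50, EC50,
  IC50 or K_d, μM) per modulator, every retained pair's p_c vector across
  the bound ensembles is correlated (Pearson ρ) with log₁₀ K, and likewise
  each community pair's summed inter-community p_c. Pairs with |ρ| > 0.5
  and the top-3 per sign per community pair are ranked as function-linked.
  A switch excludes modulators characterized by K_d only.

Trajectory post-processing (superposition onto the first frame, per-frame
RMSD, per-residue backbone RMSF over N/CA/C/O, slicing to the final stretch
of a run) and a synthetic-data generator with planted communities and
planted activity-responsive contacts complete the toolkit. Lower AC50 means
higher potency: ρ is reported against log K exactly as defined, and its
interpretation on an "activity" scale is left to the user.

## Worked example

A synthetic study with two planted communities of 12 residues, 8
modulator-bound ensembles plus a modulator-free reference, and 3 planted
responder contacts:

```r
library(dcna)
spec <- synthetic_spec(n_residues = 24, n_communities = 2, n_ensembles = 8,
                       n_replicas = 2, n_frames = 500, n_responders = 3, seed = 7)
gen  <- gen_contact_ensembles(spec)
tabs <- filter_rare(gen$tables)

net  <- build_consensus(tabs, threshold = 0.9)
#> consensus_network: 24 nodes, 90 edges
part <- detect_communities(net)
#> community_partition: 2 communities over 24 nodes, Q = 0.5000

classify_deltas(community_delta(tabs[["M01"]], tabs[["apo"]], part))
#>   community_a community_b delta_f n_pairs   label significant
#> 1           1           1  -0.022      45 neutral       FALSE
#> 2           1           2  -0.052       3 neutral       FALSE
#> 3           2           2   0.030      45 neutral       FALSE

x  <- transform_activity(gen$activity)
pc <- pair_correlation(tabs[gen$activity$name], x)
head(pc[order(-abs(pc$rho)), ], 3)
#>  node_i node_j        rho n defined
#>       1     16  0.8567219 8    TRUE
#>       3     24 -0.8491244 8    TRUE
#>      15     20  0.8220394 8    TRUE
```

The partition recovers the two planted blocks exactly (Q = 0.5, the
theoretical value for two equal disconnected modules). The first
bound-vs-free comparison shows no significant community-level shift — the
planted responders move individual contacts by ~0.1, below the 0.1
community-sum threshold at this size. Two of the three strongest
pair correlations (1–16 at ρ = +0.86 and 3–24 at ρ = −0.85) are planted
responders with the matching sign; 15–20 illustrates how wide the null
spread of a Pearson ρ over 8 points is, which is why sign recovery is
assessed over many seeds rather than per pair.

`run_pipeline()` chains all stages from one config (YAML or list) and
writes partition, dCNA, correlation and provenance files;
`inst/cli/dcna.R` wraps it for shell use.

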