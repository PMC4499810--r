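---
title: "Aligning interface-interaction networks with iinalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning interface-interaction networks with iinalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iinalign)
```

# The problem

Interface-interaction networks (IINs) resolve a protein-protein
interaction network down to individual binding sites: each
peptide-recognition domain (such as an SH3 domain) and each short ligand
peptide it binds becomes its own vertex, named `PROTEIN,start,end` with
1-based inclusive amino-acid coordinates, and each edge is a physical
site-site interaction. For peptide-recognition data these networks are
bipartite — edges run only between the domain side and the ligand side —
and their topology is an exaggerated hub-and-spoke: a few promiscuous
domains fan out over many low-degree ligand sites, and different domains
with similar binding specificity often share ligands (a "multi-fan"
pattern).

Aligning two such networks means finding a one-to-one, partition-
respecting mapping between their vertices that both recovers orthologous
relationships and aligns edges. Both goals matter: an alignment with no
aligned edges is not a *network* alignment, but maximizing edge overlap
alone recovers almost no orthology because the repeated fan patterns are
topologically interchangeable. `iinalign` makes the trade-off between the
two explicit and tunable.

# The GreedyPlus model

The aligner works on per-side **base similarity matrices**
`base(u, v) = sum_f w_f * adj_f(u, v)`, a weighted sum of normalized
features (see below), and a single scalar, the **Edge Alignment Weight
(EAW)**. It keeps a working copy `W` of the base matrices and loops:

1. commit the unaligned same-side pair with maximal working score;
2. for every pair of still-unaligned neighbours of the just-committed
   vertices (necessarily on the opposite partition side), add the EAW to
   that pair's working score.

The EAW has an additive effect: a candidate adjacent to `k` committed
pairs has been boosted `k` times. At `eaw = 0` the algorithm is exactly
the greedy vertex aligner (the package tests assert trace identity); at
`eaw = Inf` an edge-extending candidate always wins, which mimics a
seed-and-extend aligner except that alignment resumes when no extension
exists. Intermediate values interpolate: low values suit diverged
networks where vertex evidence should dominate, high values suit close
networks where topology is reliable.

Alignment continues until the smaller side of each partition is
exhausted, so the trace length is
`min(|D1|,|D2|) + min(|L1|,|L2|)`. An optional `minScore` floor stops
early.

Decisions the description of the algorithm leaves open, fixed here:

* **Tie-breaking** is deterministic: domain pairs before ligand pairs,
  then lexicographic on the network-1 id, then the network-2 id.
  Internally the working matrices are stored transposed so that the
  column-major first-maximum realizes exactly this order.
* **Bonus recipients**: only pairs of *currently unaligned* neighbours
  receive the EAW. Committed pairs are fixed; nothing is ever recomputed
  or revoked.
* **`eaw = Inf`** is encoded as a two-key sort (bonus count, then base
  score) rather than arithmetic infinity, avoiding overflow while
  preserving the limiting behaviour.
* GreedyPlus is one-to-one by construction; paralogous groups on either
  side cannot be co-aligned (one of them will pair elsewhere).

# Similarity features

All features are normalized to `[0, 1]` per side over the complete
cross-network pair universe; pairs without data are explicit zeros.

**Topological features.** Nine per-vertex measures with the conventions
of the standard network-analysis tooling: degree; average shortest path
length, closeness (reciprocal mean distance), eccentricity and radiality
computed to reachable vertices only, with isolated vertices scoring 0;
betweenness and stress by unnormalized shortest-path counting per
component; neighbourhood connectivity (mean neighbour degree); and the
topological coefficient (mean shared-neighbour fraction over partners
sharing at least one neighbour, 0 when there is none). The clustering
coefficient is deliberately excluded: it is identically zero on a
bipartite graph. Per-vertex scores on the two networks are turned into a
pair similarity by `raw = M - |score_i - score_j|`, where `M` is the
maximum absolute cross-network difference, then
`adj = log(raw + 1)/log(M + 1)`. The `+1` shift makes the formula total
(`raw = 0` maps to 0, `raw = M` to 1); when every score coincides
(`M = 0`) all pairs map to 1. The result is invariant under shifting or
negating all scores.

**Graphlet degree signatures.** The catalogue of connected graphs on
2–5 vertices is generated programmatically by exhaustive enumeration and
canonicalization: 1 + 2 + 6 + 21 = 30 graphs with 73 automorphism
orbits, the 2-node edge orbit indexed 0. Orbit indices follow the
deterministic generation order (node count, edge count, canonical form),
so they need not coincide with any published numbering; signature
similarity is ordering-invariant. Of the 29 graphs on 3–5 nodes, 20
contain an odd cycle and can never occur as induced subgraphs of a
bipartite network, so a `bipartite_only` restriction drops their orbits
— 50 of 73 coordinates — leaving a 23-orbit signature. (Published
discussions of this loss of resolution quote a drop "from 72 to 20";
our exhaustive enumeration yields 73 orbits unrestricted and 23 under
the bipartite restriction, and the package reports what it enumerates.)
Orbit counting is exact induced-subgraph enumeration (ESU), adequate for
the sparse, desk-scale networks this package targets; no ORCA-style
combinatorial counting is attempted. Signature similarity per orbit is
`w_i |log(u_i+1) - log(v_i+1)| / log(max(u_i,v_i)+2)`, averaged and
subtracted from 1. Orbit weights default to uniform; a dependency
weighting `w_i = 1 - log(o_i)/log(73)` is available behind a flag, with
the dependency counts `o_i` derived programmatically (orbits reachable
through the focal vertex by subgraphs of the orbit's graphlet) rather
than imported as unverifiable constants.

**Sequence features.** Ligand sites are short (at most 30 amino acids),
too short for BLAST statistics, so ligand-side sequence similarity is
computed in-house as the Smith-Waterman local alignment score under
BLOSUM62 with affine gap penalties (defaults: open 10, extend 0.5, the
defaults of the common Java implementation of the algorithm; a gap of
length L costs open + extend * L). Protein- and domain-level BLAST
scores and functional (GO semantic similarity) scores are *imported* as
pairwise score tables, never computed; protein-level scores are lifted
to vertex pairs by broadcasting over each protein's interfaces. Raw
non-negative pair scores are rescaled either linearly by the global
maximum (the default) or as `log(s+1)/log(max+1)`; which scheme the
original study used for sequence features is not recorded, so both are
provided.

# Evaluation metrics

Given a known orthology map (an unordered set of cross-species protein
pairs):

* **OVP** — aligned interface pairs whose parent proteins are orthologs;
* **RPO** — orthologous protein pairs with at least one such aligned
  interface pair (`RPO <= OVP` always);
* **EA** — edge pairs, one per network, with both endpoint pairs
  aligned. Because alignments respect the partition and edges run
  domain-ligand, each aligned edge pair decomposes uniquely into a
  domain pair and a ligand pair and is counted once.

Their maxima are data-dependent: `max_ea = min(|E1|, |E2|)`; `max_rpo`
counts ortholog pairs with at least one same-side vertex pair available;
`max_ovp` is the size of a maximum one-to-one matching in the bipartite
graph joining same-side cross-network vertex pairs of orthologous
proteins (computed with a standard matching algorithm, cross-checked in
the tests by exhaustive search). The matching formalization is our
reading of "maximum possible values"; the original datasets needed to
re-derive the published maxima are not bundled.

# Weight training and feature reduction

Weights (all features plus the EAW, each in `[0, 1]`) are trained by
random-restart hill climbing on the RPO of the resulting alignment.
Each restart draws all parameters uniformly, then sweeps parameters in
random order at four increasingly fine step sizes —
`0.01^(1/4) ≈ 0.316, 0.1, 0.03, 0.01` — trying both directions of a
step before giving up on a parameter and advancing to the next step
size only when a full pass yields no strict improvement. A move is
reverted only when it strictly loses RPO; ties keep the new value, which
lets the climber drift across the large plateaus an integer objective
creates. Ties between restarts are resolved by EA, then restart index.
The desk-scale default is 50 restarts (published-scale runs used
thousands); everything is reproducible from a single integer seed.

Feature reduction is two-stage. First, redundancy: features of a side
whose vectorized matrices lie within Euclidean distance 0.10 of each
other are thinned, preferentially dropping the feature most similar to
the remaining ones. Second, iterative elimination: after each training
run the feature with the lowest mean weight across the top 50 parameter
sets is removed, unless removal would reduce the best achievable RPO.
The "lowest weight in the top results" criterion is read as the mean
(the original procedure does not say mean, median or minimum); the EAW
is never a removal candidate.

# The synthetic-data generator

`generatePair()` emulates the data regime the aligner assumes, so the
whole toolkit is testable without any external download. An ancestor
bipartite network is drawn by preferential attachment: each ligand
attaches to one domain with probability proportional to current degree
plus one — reproducing the exaggerated hub-and-spoke, multi-fan shape of
real IINs — and to a second domain with probability
`meanLigandDegree - 1` (default mean degree 1.3, matching the sparse
edge-to-ligand ratios of the real SH3 data sets, which have roughly
1.2-1.7 interactions per ligand site). Two descendants then diverge
independently: every vertex is deleted with probability
`vertexLossProb`, and every surviving edge has its ligand endpoint
resampled uniformly with probability `rewireProb` (bipartiteness is
preserved by construction; a rewire landing on an existing edge merges
with it). Surviving co-copies of ancestor vertices form the planted
one-to-one vertex map; proteins (one per domain, two ligand sites per
ligand protein by default) inherit orthology when both copies keep at
least one vertex.

Similarity evidence is modelled directly: one informative feature per
side scores planted pairs around `featureInformativeness` (default 0.9)
and all other pairs around its complement, with Gaussian noise of sd
`featureNoise` clamped to `[0, 1]`, plus `nNoiseFeatures` pure `U[0,1]`
features per side. Default divergence (`rewireProb = 0.1`,
`vertexLossProb = 0.05`) and evidence (`mu = 0.9`, `sigma = 0.05`, three
noise features) describe moderately diverged species with one reliable
evidence source among distractors — the planted-recovery regime the
training tests exercise.

What the simulator does *not* emulate: real binding-site sequence
content (features are scores, not sequences), correlated noise between
features, paralogous families (ancestor vertices are copied at most
once per descendant), and one-to-many orthology. Passing the planted-
recovery tests therefore shows the pipeline recovers signal it assumes,
not that real worm/yeast alignments will reach any particular RPO;
loaders for real networks, score tables and orthology unions are
provided for users holding those files.

# Numerical and degenerate-input choices

* Site merging (`mergeSites`): predicted 15-mer peptides on one protein
  are merged into vertices of at most 30 amino acids. Runs of
  overlapping sites whose span exceeds 30 are split by exhaustive search
  over all contiguous partitions, minimizing the summed pairwise residue
  overlap between the resulting vertices, ties broken by fewest vertices
  then leftmost cut. The original data preparation did such splits by
  hand with "minimum sequence overlap"; the exhaustive objective is our
  deterministic reading and is flagged as such, not asserted as the
  original rule.
* Degenerate feature normalization (`M = 0`, all scores equal) yields
  all-ones; all-zero imported score tables stay all-zero.
* Empty sequences score 0 under Smith-Waterman; vertices missing a
  sequence contribute 0-valued pairs.
* Isolated vertices score 0 on distance-based topological features and
  have empty orbit vectors (all zero).
* A simulated scenario that deletes an entire partition side is an
  error, not an empty network.
* Working-score comparisons use exact floating-point equality for tie
  detection; test fixtures use dyadic EAW values (0.25, 0.5, 1) so that
  repeated bonus addition is exact when cross-checking against the
  independent full-rescan simulator.

# Problem sizes used by the tests

The test-suite and acceptance-script problem sizes are chosen as the
smallest instances that still exercise every code path and keep the
brute-force oracles exact: oracle comparisons run on networks of up to
about ten vertices (where exhaustive path, subgraph and alignment
enumeration is feasible), trace-equivalence and metric-invariant checks
on 200 and 60 random instances, and planted-recovery training on ten
simulated scenarios of 20 domains + 150 ligands with 25 restarts each.

# Known limitations

* Orbit counting and the brute-force oracles are exponential in graphlet
  size and are intended for sparse desk-scale networks, not thousand-
  vertex graphs.
* The trained EAW shares the `[0, 1]` range of the feature weights
  during optimization; larger values are available when calling the
  aligner directly.
* GraphML export is provided for interoperability, but the canonical
  formats are the TSV edge/vertex tables.
* Edge attributes (interaction confidence, affinity) are not modelled;
  all interactions are treated as identical.
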