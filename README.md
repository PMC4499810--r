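# iinalign

Alignment of bipartite **interface-interaction networks (IINs)** in R.

An IIN refines a protein–protein interaction network by splitting each
protein into its individual binding sites: one partition holds
peptide-recognition domains (e.g. SH3 domains), the other the short
proline-rich ligand sites they bind, and every edge is a physical
site–site interaction. These networks are extremely sparse, hub-and-spoke
shaped and (for peptide-recognition data) strictly bipartite, which makes
general network aligners behave poorly on them — graphlet signatures lose
most of their resolution because odd cycles cannot occur, and
diffusion-style similarity scores oscillate between the two partitions
instead of converging.

`iinalign` implements **GreedyPlus**, a greedy seed-free aligner designed
for this regime, together with everything needed to feed and evaluate it.

## The algorithm

Let `G1 = (D1 ∪ L1, E1)` and `G2 = (D2 ∪ L2, E2)` be bipartite IINs and
let `base(u, v)` be a weighted sum of normalized per-pair similarity
features (sequence, functional, topological), defined for same-side pairs
only. GreedyPlus maintains a working score matrix `W`, initialized to
`base`, and repeats until the smaller side of each partition is
exhausted:

1. align the unaligned same-side pair `(u, v)` with maximal `W(u, v)`
   (deterministic tie-break: domains first, then lexicographic ids);
2. for every pair `(n1, n2)` of still-unaligned neighbours of `u` and
   `v`, add the **Edge Alignment Weight (EAW)** to `W(n1, n2)`, since
   aligning `(n1, n2)` would now align an edge in each network.

Bonuses accumulate, so a candidate supported by several aligned edges is
promoted several times. `EAW = 0` reduces to a pure greedy vertex
aligner; `EAW = ∞` (implemented as a bonus-count-first sort) always
extends an edge when possible, like a seed-and-extend strategy, but keeps
aligning after frontiers die out. Alignments are scored against known
orthology as **RPO** (orthologous protein pairs represented by at least
one aligned interface pair), **OVP** (aligned interface pairs from
orthologous proteins; `RPO ≤ OVP`) and **EA** (edge pairs aligned), each
with a data-dependent maximum.

Also included: greedy and seed-and-extend baselines, the nine
NetworkAnalyzer-style topological vertex features, graphlet degree
signatures on 2–5-node graphlets with a bipartite-only restriction,
Smith–Waterman peptide similarity (BLOSUM62, affine gaps), random-restart
hill-climbing weight training that maximizes RPO, two-stage similarity
feature reduction, and a duplication-and-divergence simulator that
produces paired networks with planted orthology.

## Worked example

```r
library(iinalign)

## simulate a diverged pair of IINs with planted orthology
scn <- syntheticScenario(nDomains = 20, nLigands = 150,
                         rewireProb = 0.1, vertexLossProb = 0.05, seed = 42)
sim <- generatePair(scn)
sim$net1
#> IIN: 20 domain + 145 ligand vertices, 188 edges

## align with equal feature weights and the default EAW of 0.5
base <- assembleStack(sim$features)
trace <- greedyPlusAlign(sim$net1, sim$net2, base, eaw = 0.5)
evaluateAlignment(trace, sim$net1, sim$net2, sim$orthology)
#> MetricsReport: RPO 59/94 (63%), OVP 75/154 (49%), EA 142/179 (79%)

## upweight the informative feature: planted orthology is fully recovered
w <- WeightVector(c(informative = 1, noise1 = 0, noise2 = 0, noise3 = 0),
                  eaw = 0.3)
trace2 <- greedyPlusAlign(sim$net1, sim$net2,
                          assembleStack(sim$features@features, w), eaw = 0.3)
evaluateAlignment(trace2, sim$net1, sim$net2, sim$orthology)
#> MetricsReport: RPO 94/94 (100%), OVP 154/154 (100%), EA 143/179 (80%)
```

The first report says: with all features weighted equally (three of the
four are pure noise), 59 of the 94 recoverable orthologous protein pairs
are represented in the alignment and 75 aligned interface pairs connect
orthologous proteins, while 79% of the alignable edges are aligned. With
the informative feature alone, every planted orthology is recovered.

A small didactic fixture, `fig10Fixture()`, shows the EAW mechanism
step by step: with `eaw = 1` the third aligned pair is `(C, 3)` — its
working score was boosted twice by earlier alignments of its neighbours —
whereas with `eaw = 0` the base-preferred pair `(E, 3)` wins instead.

A command-line front end is installed with the package
(`inst/scripts/iinalign`) with subcommands `align`, `evaluate`,
`features`, `graphlets`, `train`, `simulate` and `build-network`; see
`?iinDispatch`.

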