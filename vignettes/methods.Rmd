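---
title: "Knowledge-based pair potentials as a docking objective: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based pair potentials as a docking objective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdock)
```

## The model

ppdock scores a protein-protein complex configuration with a
knowledge-based, distance-dependent atom-pair potential. For a receptor
P and a posed ligand B the score is

$$\Delta W \;=\; \sum_{p \in P}\sum_{b \in B,\; d_{p,b} < 5\,\text{Å}}
\Delta W\!\left(T_p, T_b, d_{p,b}\right),$$

the sum over all inter-partner heavy-atom pairs closer than 5 Å of a
binned potential indexed by the two atoms' Sybyl-style types and their
separation. Lower is better. The potential for a type pair is an
inverse-Boltzmann log-ratio of the pair's observed inter-partner
distance density against a reference density,

$$\Delta W(a, b, \text{bin}) = -\ln\frac{g_{ab}(\text{bin})}{g_{\mathrm{ref}}(\text{bin})},$$

anchored to zero in the final bin so all pair potentials share the
value 0 at 5 Å. The knowledge base is any collection of typed
receptor/ligand complexes; `countPairDistances()` accumulates symmetric
per-pair histograms (0.1 Å bins over [0, 5) Å, 50 bins), and
`derivePotentials()` turns them into a `PairPotentialSet`.

Because the same binning is used for the pair and the reference
density, any radial volume correction cancels in the ratio and is
therefore not applied.

### Atom types

Eleven Sybyl-style types cover all heavy atoms of the 20 canonical
amino acids: C.2, C.3, C.ar, N.3, N.am, N.ar, N.pl3, O.2, O.3, O.co2,
S.3 — 121 ordered (66 unordered) type pairs. The residue/atom-to-type
table ships as an editable text configuration
(`system.file("extdata", "atom_types.tsv", package = "ppdock")`);
`readAtomTypeTable()` accepts alternatives. Hydrogens are excluded
everywhere: the potentials describe heavy-atom statistics from
moderate-resolution crystallography where hydrogen positions are not
observed, and the molecular-weight convention (heavy-atom mass sum) is
used consistently wherever weight enters (notably the A_rel power
law).

### Reference state and smoothing

The default reference is the *pooled* (type-averaged) distance density
over all pairs — the convention of this family of scoring functions.
It is pluggable: `derivePotentials(reference =)` accepts any per-bin
density, and the package itself uses a uniform reference for its toy
potentials (below). Pair densities are smoothed toward the reference
with a Dirichlet pseudo-count of `pseudoCount` observations
($\lambda = 1$ by default):

$$g_{ab} = \frac{n_{ab} + \lambda\, g_{\mathrm{ref}}}{N_{ab} + \lambda}.$$

This choice matters at short range. Bins never observed for a pair get
$\Delta W = \ln[(N_{ab}+\lambda)/\lambda] > 0$ — mildly repulsive —
rather than the spurious *attraction* a flat additive pseudo-count
produces there (with +1 per bin, an empty pair bin compares a
pseudo-density of order $1/N_{ab}$ against a pooled density of order
$1/N_{\mathrm{pool}}$, and the resulting ratio rewards exactly the
distances the knowledge base never saw). A pair with no observations
at all degrades gracefully to a flat zero potential.

### Short-range repulsion

Knowledge bases contain no information below contact distance, so
`addRepulsion()` adds a Gaussian wall: for bins below the location of
a pair potential's *first maximum* (scanning from d = 0) plus 0.1 Å,
the term $h\,e^{-d^2/2\sigma^2}$ with $h = 280000$ evaluated at the
bin's lower edge (hence exactly $h$ in the d = 0 bin). The width
$\sigma = 0.8$ Å is configuration, chosen so the wall decays below
0.1 % of its height by 3 Å. The first-maximum search treats plateaus
of exactly equal values — the zero-information walls produced by the
smoothing above — as single points; an initial plateau that strictly
exceeds the next value counts as the barrier top. A strictly
decreasing potential has no interior maximum and falls back to (global
minimum location − bin width). Potentials are not rescaled: the raw
log-ratio values are used as-is.

## Grid scoring and the search

`buildGrids()` precomputes, for each of the 11 types, a rectangular
scalar field over the receptor: each node holds
$\sum_p \Delta W(T_p, t, d_{p,\text{node}})$ over receptor atoms
within 5 Å. The box is centred at the receptor centre of mass with a
5 Å margin beyond the receptor extent on every face, so every position
at which a ligand atom can interact is representable; a sizing rule
that adds 5 Å to the extent in total (rather than per face) would
truncate the interaction shell near the faces and break the
grid/direct equivalence the tests enforce. Scoring a posed ligand then
costs one grid read per atom (`scoreOnGrid()`), with trilinear
interpolation by default and nearest-node lookup as the exact
counterpart of the binned direct sum on lattice-aligned coordinates.

`dock()` performs the exhaustive rigid search:

* **Rotations** come from a deterministic Hopf-style covering of
  SO(3): a golden-angle (Fibonacci) lattice of axis directions crossed
  with a uniform grid of spin angles, $\max(4, \lceil 2\pi/\alpha
  \rceil) \times \max(10, \lceil 11/\alpha^2 \rceil)$ samples at
  resolution $\alpha$. The identity is always included, the covering
  property (every rotation within the resolution of a sample) is
  verified by Monte-Carlo test, and the default 5.6° gives 73 664
  rotations — the conventional exhaustive-search order of magnitude
  (tens of thousands).
* **Translations** scan the ligand's centre of mass over the
  grid-aligned 1 Å lattice (the translational step equals the grid
  spacing), over the whole interaction window or its intersection
  with a restriction sphere for knowledge-driven docking. The ligand
  rotates about its own centre of mass; the rotation centre is a
  convention the package fixes and documents.
* **Retention**: the best translation per rotation is kept (configurable
  to k per rotation), then all retained solutions are merged and
  ranked; ties break by generation order, making the search fully
  deterministic.
* **Staged scoring**: within the grid scan the lattice coincides
  with the grid, so only each rotated atom's fractional offset is
  rounded (nearest-node) or interpolated (trilinear). After ranking,
  the top 200 solutions are rescored by exact direct summation — the
  same objective without grid discretisation — and re-ranked, which
  removes grid-rounding noise from the final ranking at negligible
  cost.
* **Local refinement**: the top 50 solutions are then refined by a
  deterministic rigid-body pattern search on the direct objective
  (translation steps 0.5 → 0.25 → 0.125 Å, rotations about the ligand
  centre 6° → 3° → 1.5°, first-improvement descent) and re-ranked.
  Refinement lets poses leave the search lattice and settle into
  their basin floor — at 15°/1 Å sampling the lattice itself costs
  roughly 0.5–1 Å of pose accuracy and a corresponding score penalty
  on sharp wells, which would otherwise decide ties between basins.
  Under a restriction sphere, moves that would carry the centre of
  mass outside the sphere are rejected, so restriction soundness is
  preserved exactly.

Nearest-node lookup is the default inside `dock()` (trilinear is
available): with the translation lattice aligned to the grid, nearest
lookup keeps the scan an exact binned sum up to atom-offset rounding,
is several-fold cheaper, and the two-stage rescoring makes the final
ranking insensitive to the residual rounding.

## Clustering and ranking protocols

`clusterSolutions()`/`rescoreDecoys()` implement greedy leader
clustering: members are visited in score order and join the first
(earliest-created) cluster whose leader lies within the rmsd
threshold, else found a new cluster. The representative of a cluster
is its best-scored member. Two protocols are preconfigured:

* decoy rescoring — all-atom ligand rmsd, 2.5 Å threshold, clusters
  sorted by size (largest first);
* docking output — ligand backbone rmsd, 5 Å threshold, clusters
  sorted by representative score, with the top 2000 representatives
  the conventional evaluation cut.

Greedy leader clustering is the documented stand-in for the
k-means-style tool used in the original decoy protocol (which is not
specified to reimplementation precision); the unit tests pin its
behaviour against an independent brute-force reimplementation.

`rerankByTyr()` implements the antibody post-filter: the top-N
solutions are reordered by the descending count of tyrosine residues
the antibody partner contributes to the 10 Å interface, stable on
ties.

## Evaluation

`assessQuality()` follows the CAPRI conventions: residue contacts at
5 Å and interfaces at 10 Å (any heavy-atom pair within the cutoff,
boundary inclusive); f_nat is the fraction of reference contacts
reproduced, f_not the fraction of the model's own contacts that are
non-native; l_rmsd is the ligand backbone rmsd after superposing the
receptors on all backbone atoms (no refit on the ligand); i_rmsd is
the backbone rmsd over reference-interface residues after
least-squares fit on those same atoms. Quality classes use the
standard thresholds; the printed criteria double-assign the boundaries
f_nat = 0.3 and 0.5, so classes are evaluated with precedence high >
medium > acceptable > incorrect, which makes the classification
exhaustive and mutually exclusive (property-tested over a dense
lattice of triples). With multiple reference binding modes the
best-scoring class is reported (ties broken by lower i_rmsd) together
with the matched mode index.

`classifyDifficulty()` reproduces the conventional benchmark classes
from the interface C$_\alpha$ rmsd between superposed unbound and
bound forms and the fraction of non-native contacts: easy (< 1.5 Å and
f_not < 0.4), difficult (> 2.2 Å), medium otherwise — the printed
rules leave the exact boundaries 1.5/2.2 and f_not = 0.4 unassigned,
and the medium clause is the documented catch-all.

`randomBaseline()` is the binomial tail $P(X \ge k)$,
$X \sim \mathrm{Bin}(n, p)$: with an acceptable-decoy fraction of
28 % the chance of at least one (three) acceptable decoys in a random
top 5 is 81 % (14 %), and 88 % for at least one below 10 Å in a random
top 10 at p = 0.19 — the reference points against which enrichment by
scoring is judged. `funnelSpearman()` quantifies binding-funnel shape
as the Spearman correlation between scores and rmsds.

### SASA and the A_rel predictor

`sasa()` is a Shrake-Rupley implementation: each atom's sphere of
radius (vdW + 1.4 Å probe) is sampled with a deterministic Fibonacci
point set (960 points by default; isolated-sphere error below 0.5 %),
and points buried inside any neighbour's probe-expanded sphere are
discarded. Bondi-type element radii are bundled. `aRel()` divides the
measured area by the area expected for a folded protein of the same
molecular weight via the power law $A = c\,M^e$ with c = 6.3, e = 0.73
(a Miller-type relation, M in Da, areas in Å²); both constants are
configuration, and the 1.1 decision threshold of `predictSuccess()` is
calibrated against them: docking success is predicted iff *both*
partners have A_rel strictly below 1.1. Partners with larger relative
area are extended or flexible and tend to rearrange on binding, which
rigid docking cannot follow.

## Synthetic fixtures: what they emulate and what they do not

The package is fully testable without downloads via three generators,
all pure functions of a spec plus a mandatory seed.

`makeToyComplex()` builds a bowl-shaped receptor of alanines whose
inner surface carries aspartate "sockets", and a ligand whose lysine
"spokes" place each terminal amine ~2.9 Å from both carboxylate
oxygens of its socket. Three properties make self-redocking a
meaningful recovery test rather than a coin flip: the socket
directions have all-distinct pairwise angles, the per-socket radii
differ (so the spoke-tip constellation is not congruent to any
permuted assignment of sockets), and one amine cannot reach two
sockets at once. The native pose is therefore the unique maximiser of
the salt-bridge score, which is what the headline self-redocking
property (rank-1 recovery at ≤ 2 Å in ≥ 9/10 seeded complexes at
15°/1 Å) actually probes. Residues are placed from idealised templates
with 0.06 Å coordinate jitter — no Ramachandran realism, no side-chain
packing, no conformational change; passing these tests shows the
search and scoring machinery is correct, not that the potentials
rank real unbound complexes.

`makeDecoys()` produces rigid perturbations of the native ligand with
magnitudes ramping from zero to the spec's scales in random
directions, each tagged with its exact all-atom rmsd (the first decoy
is the native pose). `makeKnowledgeBase()` realises prescribed
per-pair distance laws as single-atom pairs on a 20 Å station lattice,
so counted histograms converge exactly to the laws. Distances are
drawn by inverse-CDF stratified sampling by default: at desk-scale
sample counts (10⁴–10⁵) the empirical histograms then match the laws
to the fraction of a bin that the derivation ground-truth checks
assume, while iid sampling (`sampling = "random"`) remains available
for convergence studies.

`toyPotentials()` derives the potential set the toy system is scored
with: a Gaussian salt-bridge law (mean 3.0 Å, σ 0.35, support 2.0–4.2
Å, double weight) for N.3/O.co2 over a uniform 1.8–5 Å contact floor
for all 21 type pairs occurring in the toys, derived against the
*uniform* reference. With a pool this small and deliberately biased,
the pooled reference would imprint the planted well's shape on every
generic pair (each would pick up a spurious ±0.1–0.5 tilt across its
range, rewarding contact-count maximisation); the uniform reference
leaves generic pairs exactly flat inside their support while
preserving the planted well and the unobserved-short-range walls.

## Numerical choices and degenerate inputs

* Distance lookup at scoring time is piecewise-constant (the
  containing bin), matching the derivation's binning; linear
  interpolation between bin centres is available.
* Bin boundaries: a pair at exactly 5 Å does not contribute (strict
  <); contacts and interfaces use inclusive cutoffs.
* Altloc resolution keeps the highest occupancy, ties broken by the
  alphabetically first label; occupancy and B-factors are otherwise
  ignored.
* Score ties anywhere (docking ranks, clustering order, Tyr re-rank)
  break by earlier generation order, keeping every pipeline stage
  byte-deterministic for a fixed seed.
* Empty cases: an empty interface scores 0 with 0 pairs; an empty
  solution list clusters to an empty list; constant inputs to the
  funnel correlation are an error (the rank correlation is undefined).
* Atoms posed outside the grid box contribute zero and are counted —
  by the box rule they are beyond the interaction shell.
* Problem sizes in the test-suite and acceptance runs: toy complexes
  of 24 + 8 residues (~130 + ~60 heavy atoms), 15° rotation sets
  (3 840 rotations) for self-redocking, 200-decoy ensembles, and
  10⁴–10⁵-sample mini knowledge bases. These sizes were chosen so the
  full pipeline exercises every code path at interactive turnaround
  while keeping all statistical checks comfortably powered.

## Known limitations

* The potentials shipped by the fixture machinery are synthetic; real
  applications must derive `PairPotentialSet`s from a curated complex
  collection (hundreds of structures at ≤ 2.5 Å resolution is the
  scale at which the 500-interactions-per-pair significance rule is
  met for most of the 66 pairs).
* The search is rigid: conformational change between unbound and
  bound forms is out of scope, which is exactly the regime the A_rel
  predictor is meant to flag.
* The exhaustive scan is a direct-space implementation; it is
  deliberately simple and deterministic rather than FFT-accelerated,
  and its cost grows with the product of rotation count, window
  volume and ligand size.
* mmCIF input, missing-residue reconstruction and any energy
  refinement of poses are out of scope.
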