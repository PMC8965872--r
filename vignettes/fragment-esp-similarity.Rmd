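---
title: "Electrostatic-shape similarity of anchored fragments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic-shape similarity of anchored fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
field model, the approximations, every tunable that matters, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The field model

A molecule with partial charges $q_i$ (elementary charge) at positions
$\mathbf r_i$ (angstrom) generates the point-charge Coulomb potential

$$V(\mathbf r) = k \sum_i \frac{q_i}{|\mathbf r - \mathbf r_i|}.$$

The Coulomb prefactor $k = 1/(4\pi\varepsilon_0)$ is set to 1 in working
units (`unit_convention()`): the Carbo similarity is invariant to it by
normalization and the Tanimoto similarity because all three overlaps
scale by $k^2$ together, so no physical constant survives into any
reported similarity. Pairwise field similarity is built from the overlap
integrals $O_{AB} = \int V_A V_B \, d\mathbf r$:

* Carbo, $O_{AB}/\sqrt{O_{AA} O_{BB}}$ — a cosine; magnitude-blind, range $[-1, 1]$;
* Tanimoto, $O_{AB}/(O_{AA} + O_{BB} - O_{AB})$ — magnitude-sensitive, range $[-1/3, 1]$.

Raw values can be negative and are the library default (they carry the
most information). Where a $[0,1]$ scale is structurally required — in
the combined ESP+shape score and inside the similarity matrix that
drives tree building and generation — Carbo maps through $(s+1)/2$ and
Tanimoto through $(s + 1/3)/(4/3)$.

## Two integrators

$1/r$ is singular at each atom, so $O_{AB}$ needs regularisation.

**Analytic (default).** Each $1/r$ is replaced by a three-Gaussian
expansion $\sum_k a_k e^{-b_k r^2}$, after which the overlap integral
over all space is an explicit double sum of Gaussian product integrals.
The expansion is fitted once per session by relative least squares
(Levenberg–Marquardt, fixed 200-point logarithmic grid, fixed starting
values — bit-reproducible) over **0.5–6 angstrom**. Three Gaussians can
hold a $\le 5\%$ relative error only over roughly a twelvefold range in
$r$; the window chosen here starts well inside the smallest van der
Waals sphere and ends beyond the interatomic distances that dominate
fragment-scale comparisons, and the fit achieves the 5 % band (the
suite verifies this on a fine grid). A wider window — out to tens of
angstrom — is attractive for long-range faithfulness but provably cannot
meet the accuracy band with $k=3$; accuracy where the field is strong
was preferred over reach where it is weak.

**Monte Carlo.** Uniform rejection sampling in the bounding box of all
(vdW + margin) spheres; points inside any vdW sphere or outside every
margin sphere are rejected, and the estimate is the region volume times
the mean of $V_A V_B$ with a standard error. Defaults: margin 4
angstrom, 10 000 samples, mandatory seed (same seed, same estimate,
bit-exactly). The two integrators compute *different* integrals — the
analytic route integrates smoothed potentials over all space, the MC
route true potentials over a finite shell; for net-charged systems the
true all-space integral does not even converge. They agree on the
normalized similarities, not on raw overlaps, and the test suite
therefore checks each against its own brute-force quadrature oracle:
the analytic sum against a dense midpoint-rule integration of the same
expanded potentials (verifying the closed-form algebra), the MC
estimate against true-Coulomb quadrature restricted to its exact shell
(verifying sampling and region handling), within three standard errors.

**Radii.** Bondi vdW radii, with bromine pinned at 1.8 angstrom — the
convention used for ESP work when the quantum parametrization stops at
argon and heavier halogens need an explicit radius.

## Shape

Shape similarity uses Gaussian spheres: each atom contributes
$\rho_i = p\, e^{-\alpha_i |\mathbf r - \mathbf r_i|^2}$ with $\alpha_i$
fixed by requiring the Gaussian's integral to equal the hard-sphere vdW
volume, and only first-order (pairwise) overlaps are summed, so the
shape Tanimoto $O_{AB}/(O_{AA}+O_{BB}-O_{AB})$ is exactly 1 on
self-comparison and analytic everywhere. With pairwise terms only, the
classical soft weight ($p = 2.7$) systematically overestimates partial
overlaps because the compensating higher-order terms are absent; the
package uses $p = 6$, calibrated so that the pairwise-only Tanimoto
reproduces hard-sphere (voxel-grid) volume-overlap Tanimoto values for
partially overlapping aromatic rings. The voxel oracle in the test
suite bounds the residual error of this approximation.

## The anchored fragment pipeline

Fragmentation cuts every acyclic single bond with at least one end in a
ring. The rule is read literally, so biaryl ring–ring single bonds *are*
cut (both ends are ring atoms) — this yields scaffold-versus-substituent
fragments. Bonds to hydrogen are never cut; formal charges ride along.
Cutting both ends of each bond leaves matched labels, and reassembly at
those labels restores the parent graph (tested by canonical-SMILES
equality over a panel of drug-like structures).

Each fragment is compared through a fixed-frame procedure:

1. a methylene–hexazine anchor is bonded to the primary attachment
   point; all other attachments get methyl caps (electrostatically
   nearly neutral);
2. a conformer ensemble (at most 10) is embedded with the anchor pinned
   to template coordinates;
3. for a pair of fragments, the conformer pair with the highest shape
   Tanimoto — anchor atoms excluded, since the shared anchor would
   inflate every score — is retained, ties resolved to the lowest pair
   of indices;
4. the anchor is deleted and replaced by a hydrogen along the old
   linker direction; all surviving coordinates are untouched
   bit-for-bit, so the alignment frame survives;
5. charges are assigned to the capped fragment (Gasteiger default,
   MMFF94 optional, both via OpenBabel; user-supplied vectors stand in
   for quantum or ML charges, which are declared but deliberately not
   implemented);
6. the retained pair is scored with the configured integrator and
   metric; the reported shape value is recomputed on the same capped
   conformers the ESP sees.

Charging *after* anchor removal keeps the exotic all-nitrogen ring out
of the charge distribution entirely. The anchor graph itself is modeled
with two ring double bonds and one ring NH (a plain N6 ring with
alternating double bonds is not valence-consistent once N-substituted);
all six ring atoms are still nitrogen, so detection and removal remain
unambiguous, and inputs already containing a hexazine are rejected.

**Attachment enumeration.** For fragments with several attachment
points the primary attachment is a comparison context, not a property
of the fragment: the similarity matrix enumerates every pairing of
primary attachments between two fragments and keeps the best value.
Fragment keys (canonical SMILES with the primary attachment dummy-
marked) keep positional isomers distinct.

## The deterministic embedder

No installed package provides seeded — let alone coordinate-pinned —
conformer embedding, and reproducibility here is a contract (same seed,
identical coordinates), so the package carries a small idealized-
geometry builder: isolated rings become regular planar polygons,
acyclic atoms are placed with idealized sp/sp2/sp3 geometry, anti and
staggered torsion defaults, and conformers are generated by seeded
torsion driving in 60-degree steps with a clash filter (no nonbonded
pair closer than half the sum of its vdW radii). Ring traversal
direction is canonicalized from graph invariants (element and heavy
degree along both walks), which makes embeddings independent of input
atom order and places chemically matched rings in matched orientations
within the shared anchor frame. Anchored builds are rooted *at* the
template, so the anchor sits at its reference coordinates exactly, not
within a tolerance.

The cost of this design: geometries are idealized rather than
force-field-minimized (planar saturated rings, no pyramidal inversion),
and fused, bridged or spiro ring systems are rejected by the embedder
with a clear error. Fragmentation, encoding and generation handle fused
systems fine — only 3D embedding is restricted. For the monocyclic
fragments of the fixture chemistry this is the right trade: the anchor
frame, not conformational fine structure, carries the comparison.

## Encoding

Pairwise similarities (renormalized, so non-negative) drive a greedy
bottom-up pairing: most similar nodes merge first, inter-node
similarity being the mean over all leaf pairs (UPGMA-style — smooth and
order-independent), ties broken by the lexicographically smallest pair
of node keys. An unconstrained "odd node waits for the next round"
greedy can produce leaf depths differing by more than one, so rounds
are disciplined: the first round performs exactly $n - 2^{D-1}$ merges
($D = \lceil \log_2 n \rceil$), which reduces the list to a power of
two, and every later round pairs all of its nodes; the globally most
similar pair is still always the first merge, and leaf depths can never
differ by more than one. Codes read left = 1 / right = 0 along the
root-to-leaf path; leaves one level shallower are padded with a
*trailing* zero — because no path can pass through another leaf, tree
codes are prefix-free and trailing padding provably cannot collide,
whereas padding at the root end can.

## Generation

A lead molecule becomes an ordered list of fragment slots (its own
fragments' codes plus the cut topology). An episode applies five policy
actions, each flipping one of the last three bits of one slot's code —
staying inside the similar-fragment neighbourhood of the tree — or
doing nothing; a flip that lands on a code with no fragment behind it,
or on a fragment whose attachment count cannot fit the slot, is a
blocked move (state unchanged), the discrete analogue of bumping into a
wall. Decoding an arbitrary state still reports such mismatches as
invalid rather than repairing them. The terminal molecule earns

$$R = 0.25 + 0.25\,\#\{\text{satisfied ranges}\}$$

(0 if invalid): molecular weight 320–420 Da, clogP 2.3–4.3, topological
PSA 45–65 square angstrom, all computed by OpenBabel (its
atom-contribution Wildman–Crippen-type logP is the documented stand-in
for proprietary clogP). Equal weighting of validity and the three
property increments is the simplest scheme that makes the reward 1
exactly on the sweet spot.

The agent is a deliberately minimal actor–critic: two one-hidden-layer
networks (32 tanh units) over the concatenated slot bits, softmax
policy with an entropy bonus of 0.01, value baseline, batches of 32
episodes, Adam at learning rate $10^{-3}$ on the batch-mean gradient
with batch-normalized advantages — the standard small-scale policy
gradient recipe, with every stochastic draw under one seed. Epochs are
200 episodes (a desk-scale choice); the learning experiment in the
acceptance suite runs 60 epochs over five seeds against a
zero-learning-rate control, and "learning" means the last ten epochs'
sweet-spot fraction exceeds the first ten for at least four seeds while
the control shows no comparable gain (its mean gain below half the
learning runs' mean).

## What the fixtures emulate — and what they do not

The synthetic inputs are built in code, seeded, and regenerable
bit-identically:

* **Point-charge systems** (up to 8 atoms, 6-angstrom box, charges in
  $[-1,1]$) exercise every identity the metrics must satisfy with no
  chemistry in the way.
* **The heteroaromatic panel** — twelve substituted benzenes, azines
  and azoles — emulates a scaffold-hopping library at monocyclic scale.
  Its designed bioisostere pair is the two methylisoxazoles: their ring
  fragments carry the same 1,2-oxazole ring anchored on the two carbons
  flanking the O–N pair, so within the shared anchor frame the ring
  nitrogen (with the oxygen) walks by one position while composition
  and shape stay fixed. The panel was designed, using the package's own
  all-against-all scan, so that this field-preserving walk outranks
  every other pair under the ESP metric while a topological fingerprint
  ranks a graph near-duplicate (the 2,3-/3,4-lutidine ring fragments)
  higher — the qualitative contrast that motivates 3D similarity. What
  the toy panel does **not** show: behaviour on fused bicyclic
  scaffolds, conformationally rich fragments, or charge models beyond
  Gasteiger/MMFF94; passing tests here demonstrate the machinery and
  the contrast, not field-quality rankings on real chemistry.
* **The lead set** — eight benzamide-scaffold leads whose own fragments
  form the twelve-fragment generator library. Their properties straddle
  the target windows without any lead sitting inside all three, and an
  exhaustive enumeration over the action-reachable states (attachment-
  compatible codes sharing each slot's frozen high bits) verifies at
  fixture-build time that sweet-spot states exist and are reachable
  from several leads.

## Numerical choices and degenerate inputs

* Similarity matrices assign failed pairs similarity 0 and report them;
  a fragment whose capped form has all-zero partial charges makes the
  self-overlap vanish and is a hard error, not a silent zero.
* Monte Carlo with no accepted samples (degenerate geometry) is an
  error; potentials are not evaluated within $10^{-8}$ angstrom of an
  atom.
* SDF output rounds coordinates to the format's four decimals; all
  in-memory math uses full precision.
* Ring-free molecules fragment to a single zero-attachment fragment and
  are flagged rather than rejected.
* Every stochastic step (torsion sampling, MC sampling, episode
  sampling, network initialization) draws from a seed that flows from
  one `run_config()` field, and internal seeding never perturbs the
  caller's RNG stream.

## Known limitations

* The embedder's idealized geometry ignores strain and
  stereochemistry, and refuses fused ring systems.
* Gasteiger charges are crude; heteroatom-walk similarities are
  correspondingly conservative. The charge interface accepts
  user-supplied vectors precisely so better charges can be dropped in.
* The generator's action space never grows the slot count, so
  generated molecules inherit each lead's fragment topology.
* Raw ESP overlaps from the two integrators are not comparable to each
  other (different integrals); compare similarities, not overlaps.
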