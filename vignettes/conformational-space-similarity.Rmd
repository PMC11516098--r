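---
title: "Conformational-space similarity profiling and contrastive molecular representation learning with csmol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational-space similarity profiling with csmol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Most 2D molecular similarity measures compare static structures. csmol
implements a similarity framework built on the idea that a small molecule
is an ensemble of accessible 3D conformations, and that two molecules are
similar when their *conformational spaces* overlap — even when their 2D
scaffolds differ. The package has two halves:

1. **A descriptor pipeline** that turns a pair of molecules into
   conformational-space-similarity (CSS) labels: conformer ensembles are
   generated under two strain-energy regimes, aligned-and-scored
   conformer-by-conformer in both directions, and reduced to a fixed
   descriptor vector.
2. **A contrastive learner**: a Weisfeiler–Lehman-style message-passing
   encoder maps each molecule graph to a fixed-length vector, and
   per-descriptor projection heads regress the CSS labels from ordered
   pairs of encodings. After training, the encodings alone support
   zero-shot virtual screening, target identification, and downstream
   property (QSAR/ADMET) models.

### CSS descriptors

For an ordered pair (query A, reference B) and a conformational scheme
*s*, the ensemble-vs-ensemble score matrix is reduced to its maximum and
minimum, giving four raw descriptors per direction: `Global_MAX`,
`Global_MIN`, `Near_MAX`, `Near_MIN`. The advanced descriptors are fixed
arithmetic transforms, per direction:

- `MaxSim` — the maximum of the four raw values;
- `MaxDistance` — their minimum;
- `MaxOverlap = (MaxSim + MaxDistance) / 2`;
- `MaxAggregation = (Global_MAX + Near_MAX) / 2`;

and the `Cross*` family averages each descriptor over the two directions,
making it symmetric under pair exchange. `MaxSim` is read as a
*per-direction* maximum over both schemes; the alternative reading
(maximizing over directions as well) would make the `Cross*` family
redundant, which is why the per-direction form is adopted.

2D similarity uses the maximum common substructure:
`similarity = N_bonds(MCS) / min(N_bonds(A), N_bonds(B))`, with
element-agnostic atom matching. Two policy choices were genuinely open:
whether bond order must match (default: no — only ring membership must
agree, so aromatic and saturated ring systems can align under the
element-agnostic regime; both behaviors are exposed), and whether the
common subgraph must be connected (default: yes, the chemically standard
reading; the exact search is branch-and-bound with a node budget and an
explicit `exact` flag when the budget is hit).

### Conformer ensembles

Two schemes define the ensembles, with strain thresholds per rotatable
bond of **1.4806 kcal/mol** (global) and **0.5060 kcal/mol**
(near-native) and RMSD clustering cutoffs of **1 Å** and **2 Å**
respectively. Strain is energy above the ensemble minimum. For rigid
molecules the threshold uses `max(n_rotatable_bonds, 1)` so the rule
never degenerates to "strain ≤ 0". Filtering precedes clustering;
clustering is energy-ascending leader clustering, so every representative
is the lowest-energy member of its cluster and representatives are
pairwise separated by more than the cutoff.

The generation backend is a contract — any function returning
(coordinates, energy) per conformer. The built-in backend is seeded
distance-geometry embedding (ETKDG) followed by MMFF94 minimization,
driven through a bundled helper script; it was chosen over the available
torsion-driving alternatives because it is exactly reproducible for a
fixed seed, which the labeling pipeline's determinism contract requires.
RMSD uses heavy atoms only with optimal (Kabsch) superposition and no
graph-automorphism symmetry correction — a known limitation for highly
symmetric molecules, which can overstate RMSD and so retain slightly too
many representatives.

### The conformer-pair scorer

The proprietary alignment scorer used to produce the original labels is
replaced by a pluggable interface: any function mapping a conformer pair
to [0, 1] is admissible. The built-in scorer is

`score(query → ref) = shape term × feature-coverage term`

where the shape term is `1 / (1 + mean |Δm|)` over USR-style
rotation-invariant distance moments (mean, σ, cube-root skew of
heavy-atom distances to four reference points), and the coverage term is
the fraction of the *reference's* pharmacophore feature types (donor,
acceptor, aromatic, hydrophobe, cation, anion; SMARTS rules shipped as an
editable YAML config) that also occur in the query. Normalizing by the
reference makes the score directional, mimicking query-onto-reference
superposition. Identity pairs score exactly 1.

### Dataset construction

Labeled pairs are classified into three regions of the (MCS, MaxSim)
plane: **analogous** (MCS ≥ 0.6 and MaxSim ≥ 0.6), **dense**, and
**sparse**. The dense/sparse boundary in the source material is shown
only as an elliptical region in a figure; csmol fits a 2D Gaussian to a
calibration sample of non-analogous pairs and sets the Mahalanobis radius
so that ~30% of that sample is dense. The sampler fills per-region
quotas at the 0.30 : 0.65 : 0.05 composition, emits every pair in both
orders (exchanging the directional columns), and records the achieved
composition in a manifest when a quota is unreachable.

Scaffold splitting assigns whole Bemis–Murcko scaffolds: a seeded shuffle
is scanned greedily, each scaffold going to the side (train vs test,
7 : 3 by molecule count) with the larger remaining deficit, followed by a
small swap pass that moves single scaffolds while it reduces the count
imbalance — the greedy pass alone can overshoot by up to half the largest
scaffold. One tenth of the training molecules (again whole scaffolds) is
carved out as validation. Pairs inherit a partition from their members:
both on the training side → train (validation when both are validation
molecules); exactly one training-side member → cross; none → test.

SMILES augmentation writes a random atom-ordering SMILES with
probability 0.9 (configurable); every output re-canonicalizes to the
same molecule.

### Encoder, heads and training

The encoder does `n_layers` rounds of message passing: each node
aggregates LeakyReLU-transformed (neighbor ⊕ bond-feature) messages by
summation and combines them with a linear transform of its own state; the
readout is a per-node MLP followed by the arithmetic mean, which makes
encodings invariant to atom renumbering (tested to 1e-6). Reference
scale is 4 layers × 2048 dimensions; desk-scale experiments use 2 × 64.

Node features (width 27) cover atom type (13-slot vocabulary with an
explicit "other" slot), hybridization, formal charge, chiral tag,
ring and aromatic flags; bond features are a 4-slot bond-type one-hot.
Ring perception and Hückel-style aromaticity are computed in-package and
cross-checked against OpenBabel SMARTS counts in the tests.

Each projection head consumes the *ordered* concatenation of two
encodings: a rectifier expands to 5× the concatenated width (the
expansion is applied to the concatenation, since that is what the head
consumes), batch normalization, reduction to 1024, then a cascade
1024 → 512 → 256 → 128 → 1 with LeakyReLU between all linear layers and
a sigmoid output. "Reducing from 1024 to 128 and repeating three times"
is realized as the three-stage cascade; an ablation flag replaces the
rectifier with a direct reduction to 256. One head per descriptor; the
default set is the eight advanced CSS descriptors plus MCS.

Training uses AdamW (base rate 1e-4, batch 512 at reference scale) with
weighted MSE summed over heads — the weights are unspecified in the
source material, so the default is uniform, with per-head weights and a
positive-emphasis scheme (up-weighting pairs with label MaxSim > 0.6)
exposed. The schedule is linear warmup from 0.1× the base rate over
30 000 steps, then a periodic cosine oscillating between 1× and 0.5×
with a 10 000-step period (restart-free oscillation between the bounds;
the restart-at-peak variant is config-switchable). Validation every 500
steps scores the mean Spearman correlation across heads; training stops
after 50 validations without improvement or at a configurable step cap.
Batch-norm inference uses running statistics frozen at the best
checkpoint. Gradients for every layer are hand-derived and verified
against numerical differentiation in the test suite.

## What the synthetic fixtures emulate

Everything is testable offline through generated data:

- `gen_library()` enumerates a drug-like grammar (~20 ring-system
  templates × ~22 substituents, all ≤ 30 heavy atoms), canonicalizes,
  deduplicates, and subsamples with a per-scaffold cap. The
  `family_size` mode instead builds structural-analog series (one
  template, many substituents), emulating the analog content of real
  libraries — needed for the analogous region and for planted screening
  benchmarks.
- `gen_surrogate_labels()` replaces the minutes-per-pair conformer
  pipeline with a *known* smooth ground truth: a fixed random projection
  of hashed path fingerprints, compared by cosine and squashed to
  [0, 1], plus U(−0.02, 0.02) noise on the raw descriptors. Advanced
  descriptors are then computed exactly, so the label algebra holds by
  construction, and self-pairs have noise-free value 1. The projection
  seed is a constant: the kernel is the same function at every user
  seed, only the noise varies.
- `gen_screening_benchmark()` plants one analog family as actives with
  held-out references and draws diverse decoys, so a competent similarity
  method must enrich the actives.

What the fixtures do **not** emulate: real conformational energetics,
activity cliffs, assay noise, tautomers/protonation states, and the
chemical-space distribution of real vendor libraries. Passing the
recovery experiments therefore shows that the descriptor algebra, the
training machinery and the evaluation stack are correct — not that the
desk-scale model matches the published screening performance, which
depends on the full-scale trained weights and proprietary alignment
backend.

## Desk-scale experiment design

The reference experiments (shared by the tests and
`scripts/acceptance.R`) use sizes chosen to finish in minutes on one CPU:

- **Recovery**: 150-molecule family-structured library; 2 000 training
  pairs, 200 validation pairs (monitoring/model selection), 1 000
  held-out pairs disjoint from training; encoder 2 layers × 64; heads
  scaled proportionally (rectifier to 128, cascade 128 → 64 → 32); batch
  64; 2 000 steps. The schedule keeps its shape with horizons scaled to
  the run (warmup = steps/10, period = steps/2) and a base rate of 1e-3
  matched to the small batch — the reference 1e-4 is tied to batch 512
  on millions of pairs. The shuffled-label control permutes the
  training labels only.
- **Screening**: 10 actives, 2 references, 300 decoys — a realistic
  active/decoy imbalance that also makes the BEDROC null distribution
  (100 random rankings) tight enough for a meaningful z-score.
- **Sampler composition**: 240 molecules in 20 families of 12; at this
  size the library contains over 600 analogous pairs, so the 5% quota of
  a 10 000-pair sample is reachable.
- **Property decoder**: labels constructed from a linear functional of a
  frozen random encoder's encodings — a recovery oracle with a known
  answer; the shuffled-label control checks the no-signal case.

## Numerical choices and degenerate inputs

- BEDROC is the rank-sum RIE statistic rescaled by its *analytic*
  minimum and maximum at the given (n, N, α), so best/worst rankings give
  exactly 1/0; α defaults to 160.9 (weights ≈ the top 1%). An
  independent direct-sum implementation is the test oracle.
- Ranking ties are broken by stable molecule-id order and recorded;
  BEDROC is rank-sensitive, so the policy is part of the contract.
- Affinities are converted to nM internally; unit-less affinities are an
  error, not a guess.
- Multi-fragment SMILES are rejected (salt stripping is upstream);
  single-atom molecules are a defined-degenerate error for MCS
  similarity (division by zero); conformers with fewer than 3 heavy
  atoms are a degenerate-geometry error for the scorer.
- A validation Spearman over a constant prediction vector is defined as
  0 rather than NA.

## Known limitations

- No stereochemistry: the 2D parse does not carry chiral tags (the
  feature slot exists and is always "none"), and MCS matching is not
  stereo-aware.
- RMSD without symmetry correction (above).
- The MCS budget fallback can, in principle, return a non-maximal
  substructure on very large pairs; the result carries `exact = FALSE`.
- The built-in scorer is a deliberately simple open stand-in: it ranks
  shape- and pharmacophore-similar conformers sensibly but does not
  reproduce any proprietary aligner's numbers.

## A worked example

```{r}
library(csmol)

a <- parse_molecule("CC(=O)Nc1ccc(O)cc1", "paracetamol")
b <- parse_molecule("CC(=O)Nc1ccc(OC)cc1", "analog")
mcs_similarity(a, b)$similarity

mols <- list(paracetamol = a, analog = b)
labels <- label_pairs(mols, data.frame(id_a = "paracetamol", id_b = "analog"),
                      budget = 50, seed = 1)
labels[, c("MaxSim", "MaxDistance", "MaxOverlap", "CrossSim", "MCS")]

# desk-scale training and screening
rec <- recovery_experiment(seed = 1, steps = 2000)
rec$heldout_spearman_maxsim
scr <- screening_experiment(rec$checkpoint, seed = 1)
scr$result$bedroc
```
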