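# csmol — conformational-space similarity and contrastive molecular representation learning

Ligand-based drug discovery leans on molecular similarity: screen a
library against known actives, guess a ligand's targets from its
neighbors, model a property from structural analogs. Classical 2D
fingerprints miss pairs of molecules whose flat structures differ but
whose accessible 3D conformations overlap — exactly the pairs that
matter for scaffold hopping. `csmol` is an R toolkit for practitioners
and method developers that (i) quantifies similarity over full conformer
ensembles, and (ii) distills that signal into a learned molecular
representation usable without any 3D computation at inference time.

## The method

**CSS descriptors.** For an ordered molecule pair (query A, reference
B), conformer ensembles are generated under two strain-energy regimes —
*global* (strain ≤ 1.4806 kcal/mol per rotatable bond, clustered at
1 Å) and *near-native* (0.5060 kcal/mol, 2 Å) — and every query
conformer is scored against every reference conformer by a directional
shape × pharmacophore-coverage score in [0, 1]. The score matrix per
scheme reduces to raw descriptors (Global_MAX, Global_MIN, Near_MAX,
Near_MIN per direction), from which the advanced descriptors follow:

    MaxSim        = max of the four raw values        (per direction)
    MaxDistance   = min of the four raw values
    MaxOverlap    = (MaxSim + MaxDistance) / 2
    MaxAggregation= (Global_MAX + Near_MAX) / 2
    Cross*        = mean of the two directions        (symmetric)

2D similarity is the element-agnostic maximum common substructure,
`N_bonds(MCS) / min(N_bonds(A), N_bonds(B))`.

**Contrastive learning.** A message-passing (Weisfeiler–Lehman-style)
graph encoder maps each molecule to a fixed-length vector; per-descriptor
projection heads (5× rectifier expansion → batch norm → 1024 → 512 → 256
→ 128 → sigmoid) regress the CSS labels from ordered pairs of encodings.
Training: AdamW, weighted MSE over heads, linear warmup then periodic
cosine schedule, early stopping on mean validation Spearman. The trained
encodings support cosine/Pearson zero-shot screening (BEDROC at
α = 160.9, AUROC, EF1%), target identification, and a projection-head
style property decoder (QSAR/ADMET) with optional encoder fine-tuning.

Everything is testable offline: deterministic fixture generators build
molecule libraries from a scaffold grammar, surrogate CSS labels with a
known ground-truth kernel, planted screening benchmarks, bioactivity
tables, and property tasks.

## A worked example

```r
library(csmol)

a <- parse_molecule("CC(=O)Nc1ccc(O)cc1", "paracetamol")
a
#> <csmol_molecule> paracetamol
#>   CC(=O)Nc1ccc(O)cc1
#>   heavy atoms: 11  bonds: 11  rotatable: 1
#>   scaffold: c1ccccc1

b <- parse_molecule("CC(=O)Nc1ccc(OC)cc1", "analog")
mcs_similarity(a, b)$similarity
#> [1] 1          # the smaller molecule embeds entirely in the larger

labels <- label_pairs(list(paracetamol = a, analog = b),
                      data.frame(id_a = "paracetamol", id_b = "analog"),
                      budget = 50, seed = 1)
labels[, c("MaxSim", "MaxDistance", "MaxOverlap", "CrossSim", "MCS")]
#>   MaxSim MaxDistance MaxOverlap CrossSim MCS
#> 1 0.6843      0.6535     0.6689   0.6843   1
```

`MaxSim = 0.684` says the best-matching conformer pair of the two
ensembles agrees well in shape and shares all pharmacophore feature
types; the narrow `MaxSim`–`MaxDistance` gap says the two conformational
spaces overlap consistently, not just at one conformation — as expected
for a methyl-ether analog of the same scaffold.

Desk-scale training and screening (a few minutes on one CPU):

```r
rec <- recovery_experiment(seed = 1, steps = 2000)
rec$heldout_spearman_maxsim
#> [1] 0.8879     # MaxSim head recovers the label kernel on unseen pairs

scr <- screening_experiment(rec$checkpoint, seed = 1)
scr$result$bedroc
#> [1] 0.684      # planted actives strongly enriched (null mean ~ 0.03)
```

## Command line

A thin CLI over the package functions is installed as `exec/csmol`:

```sh
csmol mcs --a "CCO" --b "CCC"
csmol conformers --in lib.smi --scheme global --out ens/ --seed 1
csmol css --library lib.smi --pairs pairs.csv --out labels.csv --seed 1
csmol fixtures --preset screening --seed 1 --out bench/
```

See `vignettes/conformational-space-similarity.Rmd` for the model,
parameter choices, fixture design, and limitations.
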