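---
title: "Hybrid graph neural networks for ADC payload activity: model, training and interpretability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid graph neural networks for ADC payload activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Antibody-drug conjugates (ADCs) deliver a cytotoxic small-molecule
payload — here chiefly DNA Topoisomerase I inhibitors — to tumor cells.
Predicting whether a candidate payload is active (IC50 below 100 µM,
binarized with strict inequality: a value exactly at the cutoff is
negative) from its chemical structure alone lets a discovery team rank
candidates before synthesis. `adcgnn` implements a hybrid graph neural
network for this binary bioactivity classification task, together with
the surrounding protocol: molecular-graph featurization with optional 3D
conformers, scaffold-split benchmarking, an eight-metric evaluation
panel, component-ablation factories, and an attention-based
interpretability framework.

## Molecular graphs

A molecule enters the model as its heavy-atom graph. Each atom carries
five 2D features — atomic number, heavy-atom degree, attached hydrogen
count, implicit valence (the implicit-hydrogen count), and an
aromaticity flag — plus, when a conformer is available, its centered 3D
coordinates as three extra feature columns. Hydrogens are implicit:
they appear as counts on their heavy atom, never as nodes. Every bond
contributes both directed edges `(i, j)` and `(j, i)`; self-loops are
never stored in the graph (the attention layer adds them transiently).

Parsing, canonicalization and kekulized bond orders come from OpenBabel
(via ChemmineOB/ChemmineR); duplicates are collapsed by canonical
SMILES on ingestion. Aromaticity is perceived in-package with a Hückel
4n+2 electron count over the kekulized graph (every ring atom must be
sp2 or a lone-pair N/O/S heteroatom; exocyclic double bonds contribute
no π electrons). This rule reproduces the perception of the major
toolkits on ordinary organic chemistry — benzene, heteroaromatics,
fused aromatics, quinones, fulvenes — but makes no attempt at exotic
systems (azulene-type nonalternant aromatics are classified per-ring,
not per-π-system). Features are stored as raw numeric values by
default; a one-hot element encoding over a fixed vocabulary is
available as a configuration switch.

Coordinates are centered at the molecular centroid before storage;
rotation is deliberately *not* canonicalized for user-supplied poses,
since docking-derived poses carry meaningful orientation only up to the
receptor frame and the model consumes coordinates as plain features.
Conformers generated by `embed_coords()` (OpenBabel `gen3d`, MMFF94
where parameterized) are additionally rotated to a canonical
principal-axes orientation, because the conformer search cannot be
seeded through the toolkit API: repeated embeddings agree up to small
numerical differences, not bitwise. Fully 2D pipelines are bitwise
reproducible end to end. Conformer sets are deduplicated greedily in
input order with a best-superposition (Kabsch) RMSD cutoff of 1.5 Å.

Atom indices are 1-based throughout the R API, as is idiomatic; the
JSON-lines interchange format written by `write_graphs_jsonl()` uses
0-based indices so that files are directly consumable outside R.

## The architecture

The full model is the sequence

  MPNN → GAT × 3 (8 heads each) → GraphSAGE → mean pooling → linear head.

The layers implement, per node $i$ with neighborhood $N(i)$:

* **MPNN** — $h_i' = \sigma\!\left(W h_i + \sum_{j \in N(i)} M(h_i, h_j)\right)$,
  where the message function $M$ is a one-hidden-layer MLP on the
  concatenation $[h_i \| h_j]$. The pairwise MLP is the most general
  form consistent with the update's signature; no bond features enter,
  matching the featurization above.
* **GAT** — per head, $e_{ij} = \mathrm{LeakyReLU}\!\left(a^\top [W h_i \| W h_j]\right)$,
  $\alpha_{ij} = \mathrm{softmax}_{j \in N(i)}(e_{ij})$ and
  $h_i' = \sigma\!\left(\sum_j \alpha_{ij} W h_j\right)$. A transient
  self-loop is added inside the layer so every softmax has nonempty
  support. Heads are concatenated in the first two attention layers and
  averaged in the third (the standard multi-head convention). The
  LeakyReLU slope is 0.2.
* **GraphSAGE** — $h_i' = \sigma\!\left(W h_i + \frac{1}{|N(i)|}\sum_j W h_j\right)$,
  full-neighborhood mean aggregation without sampling; an empty
  neighborhood contributes a zero mean.
* **Readout** — global average pooling over each molecule's node
  embeddings followed by an affine map to one logit per task; sigmoid
  scores at inference with a 0.5 decision threshold.

$\sigma$ is ReLU everywhere except inside the attention logits. Hidden
width defaults to 64 (the width must be divisible by the head count
where heads are concatenated); widths, depths and the initialization
scheme (Glorot-uniform, seeded) are package choices — the architecture
source states none. The three attention layers have independent
parameters.

Ablation variants (`smiles_only`, `no_mpnn`, `no_gat`, `no_sage`) drop
the named stage; `smiles_only` uses the identical stack but excludes
the coordinate columns, and perturbing coordinates provably cannot
change its output. Five-layer single-architecture baselines
(`baseline_mpnn5`, `baseline_gat5`, `baseline_sage5`, `baseline_gcn5`)
stack five copies of one layer type. A variant that requires 3D input
fails loudly when coordinates are absent; nothing is zero-filled.

The whole engine — forward passes, hand-derived backward passes, AdamW —
is vectorized base R over a block-diagonal batch graph. Correctness is
established two independent ways in the test suite: every layer is
compared against a literal per-node brute-force evaluation of its
update equation on hundreds of random graphs, and every gradient is
compared against central-difference numerical differentiation.

## Training protocol

Optimization uses AdamW (decoupled weight decay, default 0.01) with an
initial learning rate of 1e-4 by default, up to 1000 epochs with early
stopping at patience 50, monitoring validation ROC-AUC. Mini-batches
are formed by a node-count budget (default 2000 atoms per batch), a
dynamic batch-sizing policy that keeps the work per step roughly
constant across molecules of different sizes.

Two details matter in practice:

* **Tie-breaking at the monitor's ceiling.** On an easily separable
  task the validation ROC-AUC reaches 1.0 long before the sigmoid
  scores separate around the 0.5 threshold. The early-stopping rule
  therefore treats an exact tie in the monitored metric with a lower
  validation cross-entropy as an improvement: ranking quality decides
  first, calibration second. The returned parameters are always from
  the best epoch, never a later one.
* **Leakage control for multi-conformer data.** When one molecule has
  several 3D records, all records share the molecule's partition
  (splits operate on `mol_id`), and at evaluation the per-molecule
  score is the mean over its records. Any other choice leaks test
  structures into training.

Splitting is 8:1:1 train/validation/test. The scaffold strategy groups
molecules by Bemis-Murcko scaffold (ring systems plus linkers, side
chains stripped, exocyclic multiple bonds retained), sorts groups by
size (descending, ties by scaffold string) and assigns each group to
the partition with the largest remaining deficit — deterministic for a
fixed input, and no scaffold ever straddles partitions. A dataset whose
molecules all share one scaffold cannot be split and lands in train
with a warning.

`evaluate_model()` reports the eight-metric panel: accuracy,
sensitivity, specificity, MCC, ROC-AUC (trapezoidal rule over the ROC
curve), F1, balanced accuracy, and PR-AUC (step interpolation, i.e.
average precision). With a single observed class the ranking metrics
are reported as `NA`, never as 0. Each metric is cross-checked in the
tests against an independent formulation (Mann-Whitney ranks for
ROC-AUC, the Pearson-correlation identity for MCC, pROC, and literal
threshold loops).

## Interpretability

`collect_attention()` records every attention coefficient
(molecule × layer × head × directed edge, self-edges included).
`summarize_attention()` reduces them per layer to: the Shannon entropy
(natural log) of the pooled, renormalized weight distribution; the raw
weights' mean and standard deviation; the head-importance distribution
(each head's share of total attention mass — plotted but never defined
in the source literature, so defined here); its variance
("diversity"); and the **effective number of heads**,
$\exp(H(\text{head importance}))$ — the perplexity of the head
distribution, which is 1 when a single head dominates and equals the
head count when all heads contribute equally. These closed-form
extremes are asserted in the tests.

The per-atom attention score is the mean weight an atom *attracts*
from its attending neighbors at the final attention layer, averaged
over heads, self-edges included. The direction matters: the weights an
atom pays out sum to one by construction, so their mean is identically
$1/(\deg+1)$ and carries only degree information; the attracted
direction is the informative one. On the planted-ester task the
trained model's final layer gives motif atoms substantially higher mean
attention than background atoms (per-molecule contrasts on the order of
+0.1 to +0.2 depending on the seed; paired one-sided test across
held-out motif-bearing molecules, p far below 0.05).

Atom scores are aggregated over chemically meaningful atom sets:

* **SMARTS patterns** (`attribute_smarts`) via the package's
  substructure matcher. The matcher supports the SMARTS subset needed
  for functional-group queries — organic-subset and aromatic atoms,
  bracket atoms with alternatives/negation and #n, H-count, degree,
  ring and charge primitives, the five bond symbols, branches and ring
  closures — and rejects unsupported constructs (recursive SMARTS,
  stereo) with an error naming the pattern.
* **Murcko scaffolds** (`attribute_murcko`), one entry per distinct
  scaffold; acyclic molecules form the empty-scaffold entry with no
  matched atoms.
* **BRICS fragments** (`attribute_brics`): the 16-class retrosynthetic
  bond-cleavage rule set is implemented as atom-environment predicates
  with the standard allowed-pair table; fragments are keyed by the
  canonical SMILES of the fragment subgraph (open valences
  hydrogen-filled, no dummy atoms). The cleaved-bond sets are verified
  in the tests against values frozen from an independent
  implementation.
* **Ring systems** (`ring_system_attribution`), e.g. five-membered
  rings.

With attention forced uniform, every attribution collapses to the same
mean — asserted to 1e-9 — so any reported contrast between
substructures reflects the model, not the bookkeeping.

## The synthetic benchmark

Because the original payload dataset is not redistributable, the
package ships a generator whose default task stands in for it at desk
scale: `generate_motif_task()` composes prefix + backbone + substituent
SMILES from a pool of alkyl chains, carbocycles and (hetero)aromatic
rings, plants an ester linkage (`COC(=O)` — the same pharmacophore the
attention analysis highlights) in the positives, and verifies with the
package's own matcher that every positive contains the motif and every
negative contains none before optional label noise is applied. Defaults
are 600 molecules at a 0.5 positive fraction with no label noise —
large enough for a stable scaffold-split 8:1:1 at desk scale, small
enough that the full pipeline (3D embedding included) runs in minutes
on one CPU. The backbone pool spans many Murcko scaffolds so the
scaffold split genuinely withholds ring systems.

What the generator does *not* emulate: docking-pose geometry, binding
energies, activity cliffs, assay noise structure, or the size and
polycyclic complexity of real Topoisomerase I inhibitors. Passing the
end-to-end tests therefore demonstrates that the architecture, training
loop, splitting and attribution machinery are correct and that the
model can discover a planted pharmacophore on held-out scaffolds — not
that the reported literature-scale figures would be reproduced on the
original data.

Problem sizes used by the automated checks are deliberate package
choices: the end-to-end run trains the full 64-unit model on the
600-molecule task for up to 150 epochs; the ablation comparison trains
full vs. the four five-layer baselines at width 32 for up to 40 epochs
over three seeds; learnability and noise-monotonicity checks use a
16-unit two-layer model. At these scales the synthetic task is solved
essentially perfectly, so the ablation check is directional (the hybrid
model must keep pace with every baseline) rather than a reproduction of
the published gaps.

## Numerical choices and degenerate inputs

* Attention softmax: computed with a global max shift; exact, with no
  per-group clamping. Logit spreads that could underflow this scheme
  (≈700 nats) do not arise with gradient-clipped, weight-decayed
  training.
* Empty neighborhoods: the SAGE mean is zero; the MPNN sum is empty;
  the GAT softmax always contains the self-edge.
* Masked labels: missing entries contribute exactly zero to the binary
  cross-entropy and its gradient; an all-masked batch is an error.
* Boundary IC50 exactly at the cutoff is negative (strict inequality).
* Single-class evaluation partitions: ranking metrics are undefined
  (`NA`), and the training monitor treats an undefined metric as no
  improvement.
* Checkpoints are JSON (format-tagged); parameters round-trip through
  decimal text to ~15 significant digits, so reloaded models agree to
  1e-12 relative rather than bitwise; a rewritten checkpoint is
  byte-identical.
* Conformer pruning is greedy in input order (first-seen conformer
  wins), which makes deduplication deterministic and idempotent.

## Known limitations

* Aromaticity perception is per-ring Hückel; nonalternant fused
  aromatics and charged aromatic systems beyond simple cations/anions
  are out of scope.
* The SMARTS subset excludes recursive environments and
  stereochemistry.
* BRICS environments involving rare chemistry (e.g. L2-type special
  cases folded into the amine class by the reference implementation)
  follow the reference's published simplification.
* 3D embedding is single-conformer and only as reproducible as the
  underlying toolkit allows (see above); supplying your own SDF
  conformers bypasses this entirely.
* Training is CPU-bound base R: ample for datasets of thousands of
  small molecules, not for million-molecule screens.
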