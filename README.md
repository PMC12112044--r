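# adcgnn

Hybrid graph neural networks for predicting the bioactivity of
antibody-drug-conjugate (ADC) payloads from chemical structure.

ADC payloads — here chiefly DNA Topoisomerase I inhibitors — are
labeled active when their IC50 falls strictly below 100 µM. `adcgnn`
turns SMILES strings (optionally with 3D conformers) into attributed
molecular graphs and classifies them with a hybrid architecture

    MPNN → GAT × 3 (8 heads) → GraphSAGE → global mean pooling → linear head

whose layers implement, per atom *i* with neighbors *N(i)*:

* message passing: *h′ᵢ = σ(W hᵢ + Σⱼ M(hᵢ, hⱼ))*, with an MLP message
  function on [hᵢ ‖ hⱼ];
* multi-head attention: *eᵢⱼ = LeakyReLU(aᵀ[W hᵢ ‖ W hⱼ])*,
  *αᵢⱼ = softmaxⱼ(eᵢⱼ)*, *h′ᵢ = σ(Σⱼ αᵢⱼ W hⱼ)*;
* neighborhood mean aggregation: *h′ᵢ = σ(W hᵢ + (1/|N(i)|) Σⱼ W hⱼ)*.

Around the model the package provides the full protocol: Bemis-Murcko
scaffold splitting (no scaffold straddles partitions), AdamW training
with early stopping and node-budget dynamic batching, an eight-metric
evaluation panel (accuracy, sensitivity, specificity, MCC, ROC-AUC, F1,
balanced accuracy, PR-AUC), ablation-variant and five-layer baseline
factories, and an attention-based interpretability framework: attention
entropy and effective-heads summaries plus substructure attribution via
SMARTS patterns, Murcko scaffolds, BRICS fragments and ring systems. A
synthetic planted-motif generator makes the entire pipeline testable
without any external download. The forward/backward engine is written
in vectorized base R and verified against brute-force evaluations of
the layer equations and numerical gradients.

## Worked example

Train the full 3D model on the planted-ester benchmark and inspect what
the attention learned:

```r
library(adcgnn)

task   <- generate_motif_task(motif_task_spec(n_molecules = 300, seed = 7))
graphs <- graphs_from_table(task[, c("smiles", "mol_id", "label")],
                            deduplicate = FALSE)
graphs <- embed_graph_coords(graphs, seed = 7)      # OpenBabel conformers
split  <- scaffold_split(graphs, c(0.8, 0.1, 0.1), seed = 7)
parts  <- apply_split(graphs, split)

fit <- train_model(make_variant(model_config("full", hidden_dim = 64, seed = 7)),
                   parts$train, parts$valid,
                   train_config(learning_rate = 2e-3, max_epochs = 60,
                                patience = 30, seed = 7))
evaluate_model(fit$model, parts$test)
#> accuracy 1.0000 | sens 1.0000 | spec 1.0000 | MCC 1.0000 | ROC-AUC 1.0000 |
#> F1 1.0000 | bal.acc 1.0000 | PR-AUC 1.0000 (n+ 14, n- 17)

records <- collect_attention(fit$model, c(parts$valid, parts$test))
summarize_attention(records)[, c("layer", "entropy", "effective_heads")]
#>   layer  entropy effective_heads
#> 1     1 9.440594               8
#> 2     2 9.492893               8
#> 3     3 9.246243               8

att <- attribute_smarts(c(parts$valid, parts$test), records,
                        c("COC(=O)", "C[OH]"))
att[[1]]
#> <smarts 'COC(=O)': 27 molecule(s), 108 atom(s), attention 0.4769 +/- 0.1855>
```

The test set here is scaffold-held-out: the model classifies ester
presence perfectly on ring systems it never saw, and the ester atoms
attract markedly more attention than the background (the per-atom score
is the mean attention an atom attracts at the final attention layer).

The same pipeline is scriptable from a shell:

```sh
exec/adcgnn synth --kind motif-task --n 600 --seed 7 --out task.csv
exec/adcgnn train --data task.csv --split scaffold --seed 7 \
    --epochs 150 --lr 0.002 --out runs/full
exec/adcgnn interpret --checkpoint runs/full/checkpoint.json \
    --data task.csv --out runs/interpret
```

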