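# mmkge — multimodal knowledge-graph embeddings

`mmkge` is an R toolkit for representation learning on heterogeneous
biomedical knowledge graphs whose nodes carry multimodal attributes:
biological sequences for genes and proteins, SMILES strings for small
molecules, and free-text descriptions for any entity. It is aimed at
computational biologists who want to test whether attribute information
and graph structure *together* improve link prediction — finding unseen
drug–target, drug–disease or protein–disease edges — on graphs of desk
scale, entirely on one CPU.

## What it implements

For a knowledge graph G = (V, R, E, D, d) — typed nodes V, relation
labels R, directed triples E, and a partial attribute map d — the
pipeline is:

1. **Modality encoding** — deterministic, trainable-state-free encoders
   per modality: hashed k-mer counts for sequences, character n-grams for
   SMILES, hashed bag-of-words for descriptions (all L2-normalized,
   768-dimensional by default). Precomputed language-model embeddings can
   be dropped in via `load_external_embeddings()`. Missing attributes are
   imputed with per-node-seeded N(0, 1/d) vectors.
2. **Fusion** — one vector per node by elementwise mean, attention fusion
   (`alpha_i = softmax(q' W_i x_i)`), or relation-guided dual adaptive
   fusion (ReDAF: `omega_m = softmax(<V, tanh(v_m)> / sigma(zeta_r))`).
3. **Graph contrastive learning** — a two-layer GCN refined with DGI
   (patch-vs-summary discrimination), GGD (edge-reconstruction BCE) or
   GRACE (two-view InfoNCE, temperature 0.5), with random feature-masking
   and edge-dropping augmentation.
4. **Link prediction** — a two-layer relational graph convolutional
   encoder (basis-decomposed relation weights, self-loops) scored by
   DistMult `f(h,r,t) = sum_d h_d r_d t_d`, trained with
   `L = L_BCE + alpha * lambda * (||X||^2 + ||Z||^2)` on random-walk
   subgraph batches, with type-constrained negative corruption.
5. **Evaluation** — average precision and F1 under 1:1 / 1:3 / 1:5
   negative ratios, per-relation precision at 1:10, benchmark grids over
   initialization regimes (random / direct features / GCL-refined), and
   embedding export for latent-space inspection.

A synthetic-data module generates multimodal knowledge graphs with
planted block structure (the same latent blocks drive edges *and*
attribute strings), plus a planted-DistMult generator for parameter
recovery checks — so the whole pipeline is testable with no downloads.

## A worked example

```r
library(mmkge)

sim <- synthetic_knowledge_graph()   # default fixture: 130 nodes, seed 7
kg <- sim$kg
kg
#> <knowledge_graph> 130 nodes (disease: 30, drug: 40, gene_protein: 60),
#>   807 triples, 4 relations

enc   <- encode_kg_modalities(kg, d_embed = 256, seed = 1)
fused <- fuse_nodes(enc, method = "none", seed = 1)
gcl   <- pretrain_gcl(kg, fused, "grace",
                      gcl_config(epochs = 60, hidden = 64, dim = 64, seed = 1))
split <- split_edges(kg, seed = 1)
split
#> <edge_split> train 485 / valid 161 / test 161 (seed 1)

model <- train_link_predictor(kg, split, gcl$embeddings,
                              kge_config(epochs = 50, lr = 0.003, hidden = 64,
                                         dim = 64, walk_roots = 100, seed = 1))
evaluate_link_predictor(model, split, ratio_k = 1)[c("ap", "f1")]
#> $ap
#> [1] 0.7301221
#> $f1
#> [1] 0.7559524
```

The AP of 0.73 against 0.5 chance says the model ranks held-out true
edges well above corrupted ones; training the same predictor from random
features instead of the GRACE-refined embeddings gives a lower AP
(0.65 seed-averaged at 1:1 in the shipped benchmark, versus 0.73 for
GRACE-refined initialization), which is the package's scaled-down version
of the attribute-plus-structure claim. Harder negative ratios (1:3, 1:5)
lower both chance level and achieved AP.

`run_benchmark()` executes the full grid (initialization x fusion x GCL
objective x negative ratio, shared splits and evaluation negatives) and
`write_eval_report()` emits a CSV with columns
`init,fusion,gcl,ratio,ap,f1`.

## Command-line use

A thin wrapper over the exported functions lives at `inst/cli/mmkge.R`:

```sh
Rscript inst/cli/mmkge.R simulate --config run.yaml
Rscript inst/cli/mmkge.R encode   --config run.yaml
# ... fuse | pretrain | split | train | evaluate | benchmark | export
```

Each stage reads one YAML config (global seed, data paths or a
`synthetic:` block, per-stage hyperparameters), writes its outputs plus a
JSON manifest (config hash, derived seeds, package version, input
checksums) into the output directory, and logs line-delimited JSON.

## Package layout

```
R/kg_core.R            graph container, I/O, splits, negatives, walks
R/synthetic_data.R     planted-block multimodal graph generator
R/modality_encoding.R  hashing encoders, imputation, external adapters
R/fusion.R             mean / attention / ReDAF fusion
R/gcl.R                GCN encoder, DGI / GGD / GRACE objectives
R/kge.R                RGCN + DistMult link predictor, checkpoints
R/evaluation.R         AP / F1 / per-relation precision, benchmark grid
R/cli.R                YAML-configured pipeline entry point
vignettes/             methods vignette (models, conventions, choices)
```
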