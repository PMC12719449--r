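---
title: "Multimodal knowledge-graph embeddings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal knowledge-graph embeddings: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmkge)
```

## The problem

Biomedical knowledge graphs connect typed entities — genes and proteins,
drugs, diseases — through typed relations (drug–target interactions,
indications, protein–protein interactions). Link prediction on such graphs
proposes unobserved but plausible edges, e.g. drug-repurposing candidates.
Two sources of information are available per node: its *attributes*
(amino-acid or nucleotide sequences, SMILES strings, free-text
descriptions) and its *relational context* (the edges it participates in).
`mmkge` implements a pipeline that combines both: per-modality attribute
encoders, fusion of modalities into one vector per node, self-supervised
refinement by graph contrastive learning (GCL), and link prediction with a
relational graph convolutional encoder (RGCN) scored by DistMult.

Formally the graph is $G = (V, R, E, D, d)$: nodes $V$, relation labels
$R$, directed triples $E \subseteq V \times R \times V$, an attribute
dataset $D$, and a partial map $d$ attaching attributes to the subset of
nodes that have them.

## Modality encoding

Each modality is encoded by a deterministic map from strings to
$\mathbb{R}^{d}$ ($d = 768$ by default):

* **Sequences** — counts of all overlapping $k$-mers ($k = 3$ by default),
  hashed into $d$ buckets by a fixed polynomial hash, L2-normalized.
* **SMILES strings** — the same construction over character $n$-grams
  ($n = 2$).
* **Descriptions** — lowercased whitespace tokens, term-frequency
  weighted, hashed, L2-normalized.

These encoders are deliberately *frozen*: they carry no trainable state,
so the contract "any deterministic map string → $\mathbb{R}^d$" is
honored, and embeddings computed by external language models can be
substituted through `load_external_embeddings()` without touching the rest
of the pipeline. Missing attributes are imputed with
$\mathcal{N}(0, 1/d)$ draws seeded per `(global seed, node, modality)`, so
an imputed node receives the same vector in every epoch and every run.
The imputation distribution is a package choice (only "random
initialization" is prescribed); per-node seeding was chosen over per-epoch
resampling so that downstream training sees a stationary input.

## Fusion

Per-node modality vectors $x_1, \dots, x_M$ are combined into one vector:

* **none** — elementwise mean (the unweighted baseline).
* **attention** — $h_i = W_i x_i$, $\alpha_i = \mathrm{softmax}(q^\top
  h_i)$, output $\sum_i \alpha_i h_i$, with learnable-shaped projections
  $W_i \in \mathbb{R}^{128 \times 768}$ and query $q$.
* **ReDAF** — relation-guided dual adaptive fusion: scores
  $s_m = \langle V, \tanh(v_m)\rangle / \sigma(\zeta_r)$, weights
  $\omega = \mathrm{softmax}(s)$, output $\sum_m \omega_m v_m$. The
  temperature $\zeta_r$ is per-relation with a global fallback $\zeta_0$
  used whenever fusion happens outside a single relation's context (as in
  GCL pre-training).

Three design points deserve a note:

* The ReDAF score as usually written is a vector (an elementwise product
  inside an exponential); a softmax over modalities needs scalars, and the
  inner-product reduction is the only one that makes the expression
  well-defined. That reduction is what is implemented.
* A `final_mean` flag (default on at the matrix level) scales the
  weighted sum by $1/M$, so that every fusion method ends in a balanced
  mean-style aggregation; the scale is absorbed by the first linear layer
  downstream, so the flag changes nothing statistically and exists only
  to make the convention explicit and testable.
* Fusion parameters are randomly initialized and *frozen*. The fusion
  stage feeds GCL as a fixed featurizer; no objective in the pipeline
  back-propagates into it. Treating the projections as frozen random maps
  keeps every stage independently testable; swapping in trained
  projections would be an API-compatible extension.
* Encoders emit 768-dimensional vectors (language-model width) and fusion
  projects to 128 (graph-embedding width); this split is the convention
  used throughout the package.

## Graph contrastive learning

A two-layer GCN encoder (hidden width 128, dropout 0.2) is trained on the
homogeneous projection of the graph (edge types dropped, reciprocal
duplicates collapsed) with one of three objectives:

* **DGI** — discriminate (node embedding, graph summary) pairs from
  corrupted pairs. The summary is $s = \sigma(\mathrm{mean}(Z))$ and the
  discriminator the standard bilinear $\sigma(h^\top W s)$; the
  corruption is row-shuffling of features (the standard formulation of
  the method).
* **GGD** — an edge-reconstruction BCE over logits $z_i^\top z_j$,
  positive edges against uniformly sampled non-edges, *summed* (not
  averaged). This objective, as adopted here, is an edge-reconstruction
  loss rather than the group-discrimination contrast the name originally
  referred to. Because the sum runs over a stochastic number of surviving
  edges, early stopping tracks the per-term mean.
* **GRACE** — two-view InfoNCE with a shared two-layer projector and
  temperature $\tau = 0.5$. By default the denominator runs over
  inter-view pairs only; the canonical variant with intra-view negatives
  is available behind `grace_full_negatives = TRUE`, and a symmetrized
  loss behind `grace_symmetric = TRUE` (both default off).

Views are produced by masking node features and dropping edges, each with
rate 0.2 (the rates are package choices; diffusion-style augmentation is
out of scope for cost). All probabilities are clamped to
$[10^{-7}, 1 - 10^{-7}]$ before any logarithm. Training is full-batch
(one optimizer step per epoch at this scale) with Adam at learning rate
0.001, cosine annealing, warm-up of 5 steps — warm-up counts optimizer
steps, and a 200-step warm-up would span two hundred epochs here — gradient
clipping at norm 1.0 and early-stopping patience 3. GCL runs whole-graph by
default; `per_node_type = TRUE` refines each node type's induced subgraph
separately.

## Link prediction

The relational encoder runs two rounds of per-relation message passing
with mean aggregation over the *undirected* view of each relation
(messages flow both ways through one $W_r$ — a convention choice; relation
direction still matters through the type-constrained corruption), a
self-loop transform per layer, ReLU
between layers, and dropout 0.2 in training mode. Relation-specific
weights use basis decomposition with $\min(|R|, 4)$ bases. Triples are
scored by DistMult, $f(h, r, t) = \sum_d h_d r_d t_d$, through a sigmoid.

The training loss is
$L = L_{\mathrm{BCE}} + \alpha L_{\mathrm{reg}}$ with
$L_{\mathrm{reg}} = \lambda (\lVert X \rVert^2 + \lVert Z \rVert^2)$,
where $X$ are the encoded entity embeddings and $Z$ the relation
embedding table (only the relation table — not the RGCN weights — enters
the penalty). Both $\alpha$ and $\lambda$ are 0.01 and multiply, giving an
effective coefficient of $10^{-4}$; both knobs are exposed. Two numerical
points:

* `kge_loss()` computes this loss exactly as stated. During batch-wise
  training, however, the penalty's *gradient* is distributed across the
  epoch's batches: the penalty is a function of whole embedding tables,
  and applying its full gradient at every batch step overwhelms the
  batch-mean BCE gradient near the origin — the DistMult score is
  bilinear, so its BCE gradient vanishes quadratically there, and the
  collapsed all-zero solution becomes a local optimum. Distributing the
  penalty makes one epoch minimize $L_{\mathrm{BCE}} + \alpha
  L_{\mathrm{reg}}$ in aggregate.
* Validation loss for checkpoint selection and early stopping is the
  predictive BCE alone; including the penalty would mask improvements as
  embedding norms legitimately grow.

Each epoch draws a random-walk subgraph (walk length 10; GraphSAINT-style
node-induced union of walks, walking the undirected untyped view),
restricts training positives to it, resamples type-constrained negatives,
and steps on batches of 128 triples. Message passing uses the training
partition only — validation and test triples never enter the encoder's
graph. Negative corruption replaces head or tail (probability ½ each)
with a node whose type matches the relation's observed signature.
Training negatives are unfiltered by default (cheap, standard for sparse
graphs); `neg_mode = "filtered"` removes corruptions that collide with
*any* known positive — the filtered contract is defined against the full
positive set — which matters on dense graphs where uniform corruptions
frequently hit true edges. Evaluation negatives are always filtered and
fixed per split seed.

## Splitting and negative ratios

Edges are split uniformly at random 60/20/20. Validation and test take
$\lfloor 0.2\,|E| \rfloor$ each and the remainder goes to train — the one
convention consistent with both published split tables, reproduced
exactly by `split_sizes()`. Triples are directed and reciprocal pairs are
*not* collapsed before splitting; the inverse-edge leakage this can allow
is noted as a limitation. Evaluation
attaches $k$ negatives per positive for $k \in \{1, 3, 5\}$ (and 10 for
the per-relation table); chance-level AP is $1/(1+k)$, which the test
suite verifies by a permutation null.

## The synthetic generator

`generate_synthetic_kg()` emulates the structure of an attribute-rich
biomedical graph at desk scale: three node types with subtypes
(protein-coding/non-coding genes, small-molecule/antibody drugs), four
relations (drug–protein, protein–protein, drug–disease, disease–protein),
and a planted latent block structure in which the same block assignment
drives both edge formation (within-block probability $p_{\mathrm{in}} =
0.3$, across $p_{\mathrm{out}} = 0.02$) and the attribute strings
(block-biased residue frequencies, block-specific SMILES fragments,
block-keyword token bags). Ten percent of nodes have all attributes
masked. The default fixture is 60 gene/protein, 40 drug and 30 disease
nodes, 3 blocks, seed 7.

The correlation between attribute signal and graph signal is the point:
it creates the regime in which fusion + GCL should beat random
initialization, which is what the benchmark property checks. What the
generator does *not* emulate: biochemical realism of sequences or SMILES
(strings are schema-valid and block-informative, nothing more), scale-free
degree distributions, relation-specific attribute semantics, or curation
noise. Passing tests therefore demonstrate correctness of the machinery
and the expected *qualitative* ordering on planted structure — not
performance claims about real knowledge graphs.

A second generator, `simulate_distmult_kg()`, plants a DistMult model
itself: standard-normal entity and relation vectors (80 entities, 3
relations, dimension 16 by default), every ordered pair becoming an edge
with probability $\sigma(\text{score})$. "Unit" vectors in the sense of
unit *norm* would put every edge probability in $[0.38, 0.62]$ — near
coin flips that neither a learner nor the true model could rank well — so
unit-variance entries are used, giving a strong planted signal. This
graph is ~50% dense; the recovery check therefore trains with filtered
negatives (see above), since with uniform corruption roughly a quarter of
"negatives" would be held-out true edges, actively teaching the model to
rank them low.

## Problem sizes and study conditions

The package defaults mirror the full-scale recipe (768-dimensional
encoders, 128-dimensional fusion/GCL/KGE, 100 epochs, learning rate
0.001, batch 128, dropout 0.2, walk length 10, Adam with cosine annealing,
warm-up 200 steps for the batch-rich KGE stage, clipping 1.0, patience 3,
$\alpha = \lambda = 0.01$, $\tau = 0.5$). The shipped tests and the
acceptance script run scaled-down instances chosen as the package's
standard desk-scale conditions: the default synthetic fixture with
256-dimensional encoders and 64-dimensional embeddings, GCL for 60
epochs, link predictors for 50 epochs at learning rate 0.003 (patience 6)
over three replicate seeds; the planted-recovery check uses one-hot
features, hidden width 48, embedding dimension 24, 100 epochs at learning
rate 0.003, patience 8. These sizes are stated here so results are
reproducible exactly; they are choices, not tuned constants.

## Known limitations

* All training is CPU-bound, hand-derived matrix backpropagation; it is
  meant for graphs of $10^2$–$10^4$ edges, not millions.
* Inverse-edge leakage across split partitions is possible if a corpus
  stores reciprocal pairs; no deduplication is applied.
* Fusion parameters are frozen rather than trained end-to-end.
* The hashing encoders are bag-of-$k$-mers; they carry no long-range
  sequence information, so their block signal is compositional only.
* GCL can be run whole-graph or per node type; whole-graph is the default
  and the per-type variant is an option, with no strong evidence either
  way at desk scale.

## A minimal session

```{r example, eval = FALSE}
sim <- synthetic_knowledge_graph()          # planted fixture, seed 7
kg <- sim$kg
enc <- encode_kg_modalities(kg, d_embed = 256, seed = 1)
fused <- fuse_nodes(enc, method = "attention", dim = 64, seed = 1,
                    relations = kg$relations)
gcl <- pretrain_gcl(kg, fused, "grace",
                    gcl_config(epochs = 60, hidden = 64, dim = 64, seed = 1))
split <- split_edges(kg, seed = 1)
model <- train_link_predictor(kg, split, gcl$embeddings,
                              kge_config(epochs = 50, lr = 0.003,
                                         hidden = 64, dim = 64, seed = 1))
evaluate_link_predictor(model, split, ratio_k = 1)[c("ap", "f1")]
```
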