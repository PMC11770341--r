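# schicexpr

Predicting single-cell gene expression from single-cell Hi-C contacts with an
edge-gated graph transformer.

Assays that profile chromatin conformation and the transcriptome in the same
single cell are rare compared with the volume of contact-only single-cell
Hi-C data. `schicexpr` learns the mapping from a cell's intrachromosomal
contacts to its per-gene expression levels, so contact-only cells can be
annotated with predicted expression. It is aimed at computational genomics
researchers studying the relationship between 3D genome organization and
transcription.

## Method at a glance

Each chromosome of each cell is one graph instance. Nodes are genes, carrying
a 100-d feature vector (PCA of a 768-d sequence embedding concatenated with 3
chromatin-state coverage fractions — identical across cells). To overcome
per-cell contact sparsity, each cell is pooled with its *k* = 20 most similar
same-type cells (cosine similarity of binned contact patterns) into a
*meta-cell*; an edge joins genes *i*, *j* when any member has a contact
between the two gene regions, with features
`[c₀, c₁, …, c₂₀, mean(c), log₁₀ d(i,j)]` — per-member contact counts, their
mean, and the genomic midpoint distance.

The model is a 3-block, 10-head graph transformer in which every head `h`
computes, for each edge `j → i`, queries/keys/values `q, k, v` and an encoded
edge `e`, and two exponential-dot-product attention scores

    α1 ∝ exp(qᵀe / √d),    α2 ∝ exp(qᵀ(k + e) / √d)

normalized over the neighbourhood `N(i)` and mixed by a learned sigmoid gate
`ρ = σ(W_l[α1; α2; α1−α2])`, `α = ρ·α1 + (1−ρ)·α2`. Messages
`Σ_j α (v_j + e_ij)` are concatenated across heads (averaged in the last
block), passed through a gated residual
`ReLU(LayerNorm((1−β)ĝ + β r))`, and the edge features are updated to the
per-head `(α, e)` concatenation between blocks. A final affine readout gives
one expression value per gene, clamped to [0, 1] at inference.

Training uses AdamW under a hybrid imbalance-aware L1 loss for ~92%-zero
targets: with probability 0.1 per batch, plain mean L1; otherwise zero
targets are downsampled to match the nonzero count and weighted 0.4 : 0.6
(zero : nonzero). Evaluation covers accuracy (|error| < 0.1), AP, F1, PCC,
MCC, SCC, AUC, mean absolute error, two naive one-hop baselines, K-means/
UMAP cell-type clustering (ARI), and per-graph Wilcoxon signed-rank model
comparison. The model, including analytic gradients, is implemented in base
R matrix algebra and verified against equation-level and finite-difference
oracles in the test suite. A synthetic generator with a planted
contact → expression signal makes the whole pipeline testable offline; see
`vignettes/methods.Rmd` for the full model description and design rationale.

## Worked example

Simulate a small dataset (3 cell types × 12 cells, 2 chromosomes × 25 genes),
build meta-cell graphs, train, and evaluate on a held-out cell type:

```r
library(schicexpr)

dd <- file.path(tempdir(), "demo")
simulate_dataset(sim_config(n_cell_types = 3, cells_per_type = 12,
                            n_chromosomes = 2, genes_per_chromosome = 25,
                            contacts_per_cell = 400, signal_strength = 3,
                            seed = 42), dd)
ds <- load_dataset(dd)
built <- build_graph_dataset(ds, k = 5, n_components = 16, bin_size = 2e4,
                             splits = list(train = "type1", val = "type2",
                                           test = "type3"))
built$graphs[[1]]
#> <gene_graph> cell type1_c001 chr1: 22 genes, 3 undirected edges, 8-d edge features
built$projection
#> <projection_model> 771 -> 16 dims, 64.69% of total variance captured

sp <- built$manifest$split
mc <- model_config(n_blocks = 3, n_heads = 10, head_dim = 16,
                   in_node_dim = 16, in_edge_dim = 8, seed = 1)
fit <- train_model(built$graphs[sp == "train"], built$graphs[sp == "val"], mc,
                   train_config(learning_rate = 1e-3, batch_size = 8,
                                max_epochs = 20, seed = 2))
fit$best_val; fit$best_epoch
#> best validation L1 0.0305 at epoch 15

ev <- evaluate_model(fit$params, built$graphs[sp == "test"], mc)
ev$model
#> <eval_report> n=552
#>   accuracy 0.931  AP 0.488  F1 0.500  PCC 0.821
#>   MCC 0.474  SCC 0.238  AUC 0.714  avg|err| 0.0326
c(ev$naive1$avg_abs_error, ev$naive2$avg_abs_error)
#> 0.0305 0.0306
ev$vs_naive1$mean_p
#> 0.1239
```

Reading the output: on the 552 held-out gene–cell observations, 93% of
predictions fall within 0.1 of the normalized truth and the mean absolute
error is 0.033 — at this toy scale the trained model roughly matches the
one-hop baselines (0.031), and the per-graph Wilcoxon mean P of 0.12 says
the difference is not significant here. At the larger problem sizes used by
the acceptance checks (30 cells per type, 40 genes per chromosome, stronger
planted signal) the trained meta-cell model beats both baselines and its
no-meta-cell variant; the vignette discusses why margins shrink with problem
size. Graphs can be serialized with `write_graph_dataset()` and training
histories with `write_history()`; `k = 0` builds the single-cell
(no meta-cell) variant.

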