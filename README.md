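# scscc — contrastive clustering of single-cell RNA-seq data

Unsupervised clustering of cells is the pivotal step between a raw scRNA-seq
count matrix and every downstream annotation task, and it is hard for the
usual reasons: tens of thousands of genes, extreme sparsity (dropout), strong
technical noise. `scscc` clusters cells by first *learning* an embedding in
which clusters are geometrically crisp, then running K-means on it.

The embedding is trained with two self-supervised objectives over paired
corrupted views of each cell (random gene masking with probability
`p_m` plus scaled Gaussian noise, `x̃ = m ⊙ x + α ε`):

* an **instance-contrastive (InfoNCE) loss** on projected features
  `h = g(f(x̃))` — the two views of a cell attract, the other `2N − 2` views in
  the minibatch repel, with cosine similarity at temperature `τ_i`:

  `ℓ_a = −log [ exp(ρ(h_a, h_pos)/τ_i) / Σ_{b≠a} exp(ρ(h_a, h_b)/τ_i) ]`

* a **swapped-prediction loss** over `K` learnable prototypes
  `C ∈ R^{K×t}`: each view's soft assignment
  `P = softmax(H Cᵀ / τ_s)` is trained to predict the *other* view's
  Sinkhorn-balanced target `Q = Sinkhorn(H Cᵀ)` (row sums 1, column sums
  `N/K`), `L_sw = −Σ_i Σ_j [ q¹_ij log p²_ij + q²_ij log p¹_ij ]`.

Training pretrains the encoder on the instance loss, then refines embedding
and prototypes with the swapped loss, stopping early when K-means labels and
prototype labels agree (consensus ARI above `tol`). Everything — the
three-layer encoder, projection head, prototypes, Adam, and the analytic
backpropagation through both losses — is implemented in base R matrix algebra;
all gradients are verified against finite differences in the test suite.

The package also provides the standard scRNA-seq preprocessing chain
(filtering, median-library-size log-normalization, highly-variable-gene
selection by dispersion, per-gene z-scoring), the four clustering validity
indices (ARI, NMI, silhouette, Davies–Bouldin), a negative-binomial + dropout
count simulator with planted populations, and CSV/TSV/MatrixMarket readers.

## Worked example

```r
library(scscc)

# 500 cells, 1,000 genes, 4 planted populations, 70% dropout
fx <- separable_fixture(seed = 1)

fit <- scscc(
  fx$counts, K = 4, n_hvg = 500,
  dims  = network_dims(n_in = 500, d = 64, t = 32, K = 4),
  train = train_config(batch_size = 64, pretrain_epochs = 30,
                       total_epochs = 60, lr = 5e-3, seed = 1,
                       kmeans_restarts = 20),
  truth = fx$labels)

fit
#> Contrastive clustering fit (scscc)
#>   cells: 500   embedding dim: 64   K: 4   objective: full
#>   stopped at epoch 60 (max_epochs); consensus ARI max: 0.973
#>   cluster sizes: 122, 133, 120, 125

round(fit$metrics, 3)
#>   ARI   NMI    SC   DBi
#> 0.850 0.803 0.432 0.873
```

`fit$metrics` reports agreement with the planted labels (ARI and NMI are 1 for
perfect recovery, near 0 for chance) and two internal indices computed on the
learned embedding: silhouette (−1..1, higher = crisper clusters) and
Davies–Bouldin (≥ 0, lower is better). A silhouette of ≈ 0.43 on the
embedding — versus 0.011 for the same labels on the raw preprocessed input —
is the "clustering-friendly geometry" the swapped module is designed to
produce. `labels(fit)` returns the cluster assignments, `fit$embedding` the
cells × 64 representation, `plot(fit)` a PCA scatter of it, and
`predict(fit, newcounts)` embeds or labels new cells.

A command-line wrapper (`inst/cli/scscc.R`) exposes `fit`, `evaluate` and
`simulate` subcommands for shell use.

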