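# Shared fixtures and a session cache for the expensive end-to-end runs, so
# the recovery and ablation tests reuse the same fitted models.

.scscc_test_cache <- new.env(parent = emptyenv())

# The analysis configuration used for the 500-cell, 1000-gene benchmark
# fixture: top half of genes by dispersion, modest embedding width, 8 updates
# per epoch, reduced epoch budget.
acceptance_fit <- function(counts, labels, seed, objective = "full") {
  suppressWarnings(scscc(
    counts, K = 4, n_hvg = 500,
    dims = network_dims(n_in = 500, d = 64, t = 32, K = 4),
    train = train_config(batch_size = 64, pretrain_epochs = 30,
                         total_epochs = 60, lr = 5e-3, seed = seed,
                         kmeans_restarts = 20),
    objective = objective, truth = labels, metrics = FALSE))
}

# Fit the full model on the canonical fixture for seeds 1..10 (once per test
# session) and report truth ARI plus PCA+K-means and K-means-on-input
# baselines per seed.
recovery_results <- function() {
  if (!is.null(.scscc_test_cache$recovery)) return(.scscc_test_cache$recovery)
  res <- lapply(1:10, function(sd) {
    fx <- separable_fixture(seed = sd)
    X <- suppressWarnings(preprocess_counts(fx$counts, n_hvg = 500))
    pc <- stats::prcomp(X, rank. = 20)$x
    fit <- acceptance_fit(fx$counts, fx$labels, seed = sd)
    list(ari = unname(fit$metrics["ARI"]),
         baseline_pca = ari(fx$labels, kmeans_cluster(pc, 4, seed = sd)),
         baseline_input = ari(fx$labels, kmeans_cluster(X, 4, seed = sd)),
         stop_epoch = fit$stop_epoch, ari_max = fit$ari_max)
  })
  .scscc_test_cache$recovery <- res
  res
}

# A small, fast, dense training fixture for trainer unit tests.
tiny_problem <- function(seed = 3, m = 60, n_genes = 40, K = 3) {
  sim <- simulate_counts(sim_config(m = m, n_genes = n_genes, K = K,
                                    fold = 5, marker_frac = 0.2,
                                    dropout_rate = 0.2, seed = seed))
  sim
}

tiny_fit <- function(seed = 1, ...) {
  sim <- tiny_problem()
  suppressWarnings(scscc(
    sim$counts, K = 3, n_hvg = 30,
    dims = network_dims(n_in = 30, hidden = c(32, 16), d = 8, t = 4, K = 3,
                        proj_hidden = 16),
    train = train_config(batch_size = 20, pretrain_epochs = 4,
                         total_epochs = 8, lr = 5e-3, seed = seed),
    truth = sim$labels, metrics = FALSE, ...))
}
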