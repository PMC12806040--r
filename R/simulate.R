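# Synthetic scRNA-seq count generator: K latent populations, negative-binomial
# overdispersed counts with cluster-specific marker genes, per-cell library
# factors, and independent Bernoulli dropout zero-inflation.

#' Simulation configuration
#'
#' @param m number of cells.
#' @param n_genes number of genes.
#' @param K number of populations, >= 2.
#' @param proportions mixing proportions, length K, summing to 1 (default
#'   equal).
#' @param fold fold-change applied to each population's marker genes
#'   (default 4).
#' @param marker_frac fraction of genes up-regulated per population (default
#'   0.1; marker sets are drawn independently per population).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline per-gene
#'   mean expression (defaults 0 and 0.5: baseline means around 1 count).
#' @param dispersion negative-binomial dispersion; the NB size parameter is
#'   `1 / dispersion` (default 0.5, i.e. size 2 — moderate overdispersion).
#' @param dropout_rate mean independent zeroing probability in `[0, 1)`
#'   (default 0.7, a typical high-sparsity droplet regime).
#' @param dropout_sd per-cell spread of the dropout probability (default 0:
#'   one shared rate). When positive, each cell gets its own detection rate,
#'   Beta-distributed with mean `dropout_rate`, emulating the cell-quality /
#'   detection-efficiency variation of droplet protocols.
#' @param lib_sigma log-normal sigma of per-cell library factors (default 0.3).
#' @param seed integer seed.
#' @return validated list of class `scscc_sim`.
#' @export
sim_config <- function(m = 500, n_genes = 1000, K = 4,
                       proportions = rep(1 / K, K),
                       fold = 4, marker_frac = 0.1,
                       base_meanlog = 0, base_sdlog = 0.5,
                       dispersion = 0.5, dropout_rate = 0.7, dropout_sd = 0,
                       lib_sigma = 0.3, seed = 0) {
  if (K < 2) stop("K must be >= 2")
  if (length(proportions) != K || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must have length K and sum to 1")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (dropout_sd < 0) stop("dropout_sd must be >= 0")
  if (dropout_sd > 0 && dropout_rate == 0) stop("dropout_sd needs dropout_rate > 0")
  if (dropout_sd > 0 &&
      dropout_sd^2 >= dropout_rate * (1 - dropout_rate)) {
    stop("dropout_sd too large for a Beta law with mean dropout_rate")
  }
  if (fold <= 0) stop("fold must be positive")
  structure(list(m = m, n_genes = n_genes, K = K, proportions = proportions,
                 fold = fold, marker_frac = marker_frac,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 dropout_sd = dropout_sd, lib_sigma = lib_sigma, seed = seed),
            class = "scscc_sim")
}

#' Simulate a labeled scRNA-seq count matrix
#'
#' Cells are drawn from K populations by the mixing proportions. Gene j of a
#' cell in population k has negative-binomial counts with mean
#' `lib_i * mu_kj` (size `1 / dispersion`), where `mu_kj` is the baseline
#' gene mean times `fold` on that population's marker genes, and `lib_i` is a
#' log-normal per-cell library factor. Entries are then independently zeroed
#' with probability `dropout_rate`. Deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (cells x genes, see [count_matrix()]), `labels`
#'   (integer population of each cell), and `means` (the K x n_genes mean
#'   profile matrix actually used).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "scscc_sim"))
  with_local_seed(cfg$seed, {
    base <- stats::rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog)
    if (all(base == 0)) stop("infeasible config: all-zero gene means")
    mu <- matrix(rep(base, each = cfg$K), cfg$K, cfg$n_genes)
    n_mark <- max(1L, round(cfg$marker_frac * cfg$n_genes))
    for (k in seq_len(cfg$K)) {
      mk <- sample.int(cfg$n_genes, n_mark)
      mu[k, mk] <- mu[k, mk] * cfg$fold
    }
    labels <- sample.int(cfg$K, cfg$m, replace = TRUE, prob = cfg$proportions)
    lib <- stats::rlnorm(cfg$m, 0, cfg$lib_sigma)
    MU <- lib * mu[labels, , drop = FALSE]
    counts <- matrix(
      stats::rnbinom(cfg$m * cfg$n_genes, mu = MU, size = 1 / cfg$dispersion),
      cfg$m, cfg$n_genes
    )
    if (cfg$dropout_rate > 0) {
      if (cfg$dropout_sd > 0) {
        # per-cell detection rate: Beta with mean dropout_rate, sd dropout_sd
        v <- cfg$dropout_sd^2
        c0 <- cfg$dropout_rate * (1 - cfg$dropout_rate) / v - 1
        p_cell <- stats::rbeta(cfg$m, cfg$dropout_rate * c0,
                               (1 - cfg$dropout_rate) * c0)
      } else {
        p_cell <- rep(cfg$dropout_rate, cfg$m)
      }
      keep <- matrix(stats::runif(cfg$m * cfg$n_genes), cfg$m,
                     cfg$n_genes) >= p_cell
      counts <- counts * keep
    }
    dimnames(counts) <- list(paste0("cell_", seq_len(cfg$m)),
                             paste0("gene_", seq_len(cfg$n_genes)))
    list(counts = count_matrix(counts), labels = labels, means = mu)
  })
}

#' Canonical separable benchmark fixture
#'
#' 500 cells, 1,000 genes, 4 equal populations with strong marker structure
#' (4-fold shifts on 10% of genes per population) and 0.7 dropout: sparse and
#' noisy enough that a PCA + K-means baseline is imperfect, yet separable
#' enough that the contrastive pipeline can recover the populations.
#'
#' @param seed integer seed.
#' @return list with `counts` and `labels` (see [simulate_counts()]).
#' @export
separable_fixture <- function(seed = 0) {
  sim <- simulate_counts(sim_config(m = 500, n_genes = 1000, K = 4,
                                    fold = 4, marker_frac = 0.1,
                                    dropout_rate = 0.7, seed = seed))
  sim[c("counts", "labels")]
}

#' Small random fixtures for loss testing
#'
#' Generates unit-norm feature matrices and row-stochastic assignment/target
#' matrices of matched shapes, deterministically per seed.
#'
#' @param batch number of rows.
#' @param dim feature dimension.
#' @param K number of assignment columns (default 3).
#' @param seed integer seed.
#' @return list with `H1`, `H2` (batch x dim, unit-norm rows), `P1`, `P2`,
#'   `Q1`, `Q2` (batch x K, row-stochastic).
#' @export
loss_fixture <- function(batch = 6, dim = 5, K = 3, seed = 0) {
  with_local_seed(seed, {
    rand_feat <- function() {
      l2_normalize_rows(matrix(stats::rnorm(batch * dim), batch, dim))
    }
    rand_stoch <- function() {
      M <- matrix(stats::rexp(batch * K), batch, K)
      M / rowSums(M)
    }
    list(H1 = rand_feat(), H2 = rand_feat(),
         P1 = rand_stoch(), P2 = rand_stoch(),
         Q1 = rand_stoch(), Q2 = rand_stoch())
  })
}
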