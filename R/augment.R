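# Stochastic augmentation: random gene masking plus scaled Gaussian noise.
#
# Each cell x is corrupted twice per forward pass:
#   view_k = m_k * x + alpha * eps_k,   m_k ~ Bernoulli(1 - p_m),  eps_k ~ N(0,1)
# The two views of the same cell form a positive pair; the other 2N - 2
# augmented rows of the minibatch are its negatives. All draws consume R's
# current RNG stream so a run seeded once is bit-reproducible.

#' Augmentation configuration
#'
#' @param p_m masking probability in `[0, 1)`: each gene of each view is
#'   independently zeroed with this probability. High masking (default 0.8)
#'   produces more discriminative negatives on sparse scRNA-seq input.
#' @param alpha Gaussian noise weight, >= 0 (default 0.1; sensible range
#'   0.01-0.1). Noise is added to every entry, including masked ones.
#' @return a validated list of class `scscc_aug`.
#' @export
augmentation_config <- function(p_m = 0.8, alpha = 0.1) {
  if (!is.numeric(p_m) || length(p_m) != 1 || p_m < 0 || p_m >= 1) {
    stop("p_m must be a single value in [0, 1)")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    stop("alpha must be a single non-negative value")
  }
  structure(list(p_m = p_m, alpha = alpha), class = "scscc_aug")
}

#' Sample a gene retention mask
#'
#' Each entry is independently 1 (retain) with probability `1 - p_m` and 0
#' (mask) with probability `p_m`, drawn from R's current RNG stream.
#'
#' @param n_genes mask length.
#' @param p_m masking probability in `[0, 1)`.
#' @return binary vector of length `n_genes`.
#' @export
sample_mask <- function(n_genes, p_m) {
  if (p_m < 0 || p_m >= 1) stop("p_m must be in [0, 1)")
  if (p_m == 0) return(rep(1, n_genes))
  as.numeric(stats::runif(n_genes) >= p_m)
}

#' Augment one expression vector into a positive pair
#'
#' @param x finite numeric expression vector.
#' @param cfg an [augmentation_config()].
#' @return list with `view1`, `view2`, `mask1`, `mask2`; each
#'   `view_k = mask_k * x + alpha * noise_k` with independent masks and noise.
#' @export
augment_pair <- function(x, cfg = augmentation_config()) {
  if (!all(is.finite(x))) stop("expression vector must be finite")
  n <- length(x)
  m1 <- sample_mask(n, cfg$p_m)
  m2 <- sample_mask(n, cfg$p_m)
  e1 <- if (cfg$alpha > 0) stats::rnorm(n) else numeric(n)
  e2 <- if (cfg$alpha > 0) stats::rnorm(n) else numeric(n)
  list(view1 = m1 * x + cfg$alpha * e1,
       view2 = m2 * x + cfg$alpha * e2,
       mask1 = m1, mask2 = m2)
}

#' Augment a minibatch into two corrupted views
#'
#' Applies the masking + noise corruption to every row, independently for the
#' two views. Masks (and, when `keep_noise = TRUE`, the raw noise draws) are
#' returned so the corruption is fully reconstructable:
#' `view_k - alpha * noise_k == mask_k * X` exactly.
#'
#' Draw order is fixed and documented: mask1, mask2, noise1, noise2, each
#' filled column-major over the batch, so seeded runs are bit-reproducible.
#'
#' @param X_batch numeric matrix, batch x genes.
#' @param cfg an [augmentation_config()].
#' @param keep_noise also return the noise matrices (default FALSE).
#' @return list with `view1`, `view2`, `mask1`, `mask2` (and `noise1`,
#'   `noise2` if requested), all batch x genes.
#' @export
augment_batch <- function(X_batch, cfg = augmentation_config(),
                          keep_noise = FALSE) {
  X_batch <- as.matrix(X_batch)
  if (nrow(X_batch) == 0) stop("empty batch")
  n <- length(X_batch)
  dm <- dim(X_batch)
  msk <- function() {
    if (cfg$p_m == 0) return(array(1, dm))
    array(as.numeric(stats::runif(n) >= cfg$p_m), dm)
  }
  nse <- function() {
    if (cfg$alpha == 0) return(array(0, dm))
    array(stats::rnorm(n), dm)
  }
  m1 <- msk(); m2 <- msk()
  e1 <- nse(); e2 <- nse()
  out <- list(view1 = m1 * X_batch + cfg$alpha * e1,
              view2 = m2 * X_batch + cfg$alpha * e2,
              mask1 = m1, mask2 = m2)
  if (keep_noise) {
    out$noise1 <- e1
    out$noise2 <- e2
  }
  out
}
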