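# Training objectives.
#
# Instance loss: InfoNCE over the 2N projected features of a minibatch's two
# views, cosine similarity, temperature tau_i; the positive of an anchor is
# the other view of the same cell, all other 2N - 2 features are negatives.
#
# Swapped prediction loss: cross-entropy between each view's soft prototype
# assignment P and the OTHER view's Sinkhorn-balanced target Q; Q is treated
# as a constant during backpropagation.

#' Loss configuration
#'
#' @param tau_i instance-loss temperature, > 0 (default 0.1).
#' @param tau_s assignment temperature, > 0 (default 0.1).
#' @param kappa weight of the instance loss in the combined objective,
#'   `L = L_sw + kappa * L_ins`. Default NULL = automatic rule: 0.01, switching
#'   to 1 when the dataset exceeds 10,000 cells.
#' @param sinkhorn_iters alternating row/column balancing passes (default 3).
#' @param sinkhorn_eps entropic regularization of the balancing (default 0.05).
#' @param include_self include the anchor's own e^{1/tau} term in the InfoNCE
#'   denominator (default FALSE, the SimCLR convention; TRUE only shifts the
#'   loss floor).
#' @param mean_over_batch divide the swapped loss by the batch size. Default
#'   TRUE for training (keeps the objective scale batch-size independent);
#'   the bare [swapped_loss()] function defaults to the plain sum.
#' @return validated list of class `scscc_loss`.
#' @export
loss_config <- function(tau_i = 0.1, tau_s = 0.1, kappa = NULL,
                        sinkhorn_iters = 3, sinkhorn_eps = 0.05,
                        include_self = FALSE, mean_over_batch = TRUE) {
  if (tau_i <= 0 || tau_s <= 0) stop("temperatures must be positive")
  if (!is.null(kappa) && kappa < 0) stop("kappa must be >= 0")
  if (sinkhorn_iters < 1) stop("sinkhorn_iters must be a positive integer")
  if (sinkhorn_eps <= 0) stop("sinkhorn_eps must be positive")
  structure(list(tau_i = tau_i, tau_s = tau_s, kappa = kappa,
                 sinkhorn_iters = as.integer(sinkhorn_iters),
                 sinkhorn_eps = sinkhorn_eps,
                 include_self = isTRUE(include_self),
                 mean_over_batch = isTRUE(mean_over_batch)),
            class = "scscc_loss")
}

#' Cosine similarity of two vectors
#'
#' @param h1,h2 nonzero numeric vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(h1, h2) {
  n1 <- sqrt(sum(h1^2)); n2 <- sqrt(sum(h2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for a zero vector")
  sum(h1 * h2) / (n1 * n2)
}

#' InfoNCE instance-contrastive loss
#'
#' Features are L2-normalized internally so similarities are cosine. For
#' anchor a, `l_a = -ln( exp(sim(a, pos(a))/tau) / sum_b exp(sim(a, b)/tau) )`
#' where the sum runs over the other 2N - 1 features (the anchor's self-term
#' is excluded unless `include_self`). The loss is the mean of `l_a` over all
#' 2N anchors.
#'
#' @param H1,H2 batch x t feature matrices of the two views (N >= 2 rows).
#' @param tau_i temperature, > 0.
#' @param include_self include the self-similarity term in the denominator.
#' @param grad also return analytic gradients with respect to H1 and H2.
#' @return scalar loss, or (with `grad = TRUE`) list `loss`, `dH1`, `dH2`.
#' @export
infonce_loss <- function(H1, H2, tau_i = 0.1, include_self = FALSE,
                         grad = FALSE) {
  H1 <- as.matrix(H1); H2 <- as.matrix(H2)
  if (!identical(dim(H1), dim(H2))) stop("H1 and H2 must have the same shape")
  N <- nrow(H1)
  if (N < 2) stop("InfoNCE needs at least 2 cells per batch (no negatives)")
  U <- l2_normalize_rows_safe(rbind(H1, H2))
  M <- 2L * N
  S <- tcrossprod(U) / tau_i
  if (!include_self) diag(S) <- -Inf
  pos <- c((N + 1):M, 1:N)  # partner index of each anchor
  lse <- row_logsumexp(S)
  s_pos <- S[cbind(seq_len(M), pos)]
  li <- -(s_pos - lse)
  loss <- mean(li)
  if (!grad) return(loss)

  P <- exp(S - lse)  # row-softmax over the allowed terms (diag 0 if excluded)
  G <- P / (M * tau_i)
  G[cbind(seq_len(M), pos)] <- G[cbind(seq_len(M), pos)] - 1 / (M * tau_i)
  dU <- (G + t(G)) %*% U
  # back through row normalization: u = h / |h| (zero rows: zero subgradient)
  H <- rbind(H1, H2)
  nrm <- sqrt(rowSums(H * H))
  dH <- (dU - rowSums(dU * U) * U) / pmax(nrm, 1e-12)
  dH[nrm < 1e-12, ] <- 0
  list(loss = loss, dH1 = dH[1:N, , drop = FALSE],
       dH2 = dH[(N + 1):M, , drop = FALSE])
}

#' Sinkhorn-balanced assignment targets
#'
#' Balances `exp(logits / eps)` by alternating row and column normalization
#' (iterative proportional fitting in log space) toward row sums 1 and column
#' sums `batch / K`, preventing collapse of all cells onto one prototype. Rows
#' are renormalized to sum to exactly 1 on return.
#'
#' @param logits finite batch x K score matrix.
#' @param eps entropic regularization (default 0.05); larger values give
#'   smoother targets.
#' @param iters number of row+column balancing passes (default 3; a few dozen
#'   reach convergence, the default follows the online-clustering regime).
#' @return batch x K nonnegative matrix with unit row sums.
#' @export
sinkhorn_targets <- function(logits, eps = 0.05, iters = 3) {
  logits <- as.matrix(logits)
  if (!all(is.finite(logits))) stop("logits must be finite")
  N <- nrow(logits); K <- ncol(logits)
  if (N < K) {
    warning("batch size (", N, ") below number of prototypes (", K,
            "); column balancing is ill-posed")
  }
  L <- logits / eps
  L <- L - max(L)  # stabilize before any exp
  log_colsum_target <- log(N / K)
  for (i in seq_len(iters)) {
    L <- L - row_logsumexp(L)                       # rows -> 1
    L <- sweep(L, 2, col_logsumexp(L)) + log_colsum_target  # cols -> N/K
  }
  Q <- exp(L - row_logsumexp(L))
  if (!all(is.finite(Q))) {
    stop("overflow in Sinkhorn balancing; increase eps")
  }
  Q
}

#' Swapped prediction loss
#'
#' Cross-entropy in the swapped direction:
#' `L_sw = -sum_i sum_j [ q1_ij ln p2_ij + q2_ij ln p1_ij ]`,
#' summed over the batch (set `mean_over_batch` for a size-comparable
#' variant). Probabilities are clamped at 1e-12 before the log, with a warning
#' when clamping occurs.
#'
#' @param P1,P2 batch x K row-stochastic soft assignments of views 1 and 2.
#' @param Q1,Q2 batch x K balanced targets of views 1 and 2.
#' @param mean_over_batch divide by the batch size (default FALSE).
#' @return scalar loss, >= 0.
#' @export
swapped_loss <- function(P1, P2, Q1, Q2, mean_over_batch = FALSE) {
  P1 <- as.matrix(P1); P2 <- as.matrix(P2)
  Q1 <- as.matrix(Q1); Q2 <- as.matrix(Q2)
  if (!identical(dim(P1), dim(P2)) || !identical(dim(P1), dim(Q1)) ||
      !identical(dim(P1), dim(Q2))) {
    stop("P1, P2, Q1, Q2 must all share one shape")
  }
  if (any(P1 < 1e-12) || any(P2 < 1e-12)) {
    warning("clamping assignment probabilities at 1e-12 before the log")
    P1 <- pmax(P1, 1e-12)
    P2 <- pmax(P2, 1e-12)
  }
  L <- -sum(Q1 * log(P2) + Q2 * log(P1))
  if (mean_over_batch) L <- L / nrow(P1)
  L
}

# Gradient of the swapped loss with respect to the two logit matrices
# (logits -> P via soft_assign at temperature tau_s; Q held constant):
# dL/dlogits_k = (P_k - Q_other) / tau_s, scaled by 1/N under the mean variant.
swapped_loss_grad <- function(P1, P2, Q1, Q2, tau_s, mean_over_batch = FALSE) {
  sc <- if (mean_over_batch) nrow(P1) * tau_s else tau_s
  list(dlogits1 = (P1 - Q2) / sc, dlogits2 = (P2 - Q1) / sc)
}

#' Combined objective
#'
#' @param L_sw swapped prediction loss.
#' @param L_ins instance-contrastive loss.
#' @param kappa trade-off weight, >= 0.
#' @return `L_sw + kappa * L_ins`.
#' @export
total_loss <- function(L_sw, L_ins, kappa) {
  if (!is.finite(L_sw) || !is.finite(L_ins)) stop("losses must be finite")
  if (kappa < 0) stop("kappa must be >= 0")
  L_sw + kappa * L_ins
}

#' Automatic instance-loss weight
#'
#' The default trade-off rule: 0.01 for datasets of at most 10,000 cells, 1
#' above that.
#'
#' @param n_cells number of cells in the dataset.
#' @return numeric kappa.
#' @export
auto_kappa <- function(n_cells) if (n_cells > 10000) 1 else 0.01
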