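# Training orchestration: minibatch optimization of the combined objective
# with a pretraining phase (swapped + instance loss) and a fine-tuning phase
# (swapped loss only), consensus early stopping (ARI between K-means labels on
# the embedding and argmax prototype labels), and final K-means clustering.

#' Training configuration
#'
#' @param batch_size minibatch size N, >= 2 (default 256). The last minibatch
#'   of an epoch keeps its natural smaller size (a trailing singleton is
#'   folded into the previous batch).
#' @param pretrain_epochs epochs with the instance loss active (default 100).
#' @param total_epochs total epochs, >= pretrain_epochs (default 300).
#' @param tol early-stop threshold in (0, 1]: training stops once the ARI
#'   between K-means labels and prototype labels exceeds it (default 0.99).
#' @param lr Adam learning rate (default 1e-3).
#' @param lr_schedule `"constant"` (default) or `"cosine"`: cosine decay of
#'   the learning rate from `lr` to `lr/100` over the epochs, the usual
#'   schedule in the contrastive-learning family; stabilizes the late
#'   refinement phase.
#' @param seed integer seed controlling initialization, augmentation,
#'   shuffling and K-means restarts (default 0).
#' @param check_interval epochs between early-stop checks after pretraining
#'   (default 1).
#' @param kmeans_restarts K-means restarts inside the early-stop check and for
#'   the final labels (default 10).
#' @return validated list of class `scscc_train`.
#' @export
train_config <- function(batch_size = 256, pretrain_epochs = 100,
                         total_epochs = 300, tol = 0.99, lr = 1e-3,
                         lr_schedule = c("constant", "cosine"),
                         seed = 0, check_interval = 1, kmeans_restarts = 10) {
  lr_schedule <- match.arg(lr_schedule)
  if (batch_size < 2) stop("batch_size must be >= 2")
  if (pretrain_epochs < 1 || pretrain_epochs > total_epochs) {
    stop("need 0 < pretrain_epochs <= total_epochs")
  }
  if (tol <= 0 || tol > 1) stop("tol must be in (0, 1]")
  if (lr <= 0) stop("lr must be positive")
  if (check_interval < 1) stop("check_interval must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 total_epochs = as.integer(total_epochs),
                 tol = tol, lr = lr, lr_schedule = lr_schedule, seed = seed,
                 check_interval = as.integer(check_interval),
                 kmeans_restarts = as.integer(kmeans_restarts)),
            class = "scscc_train")
}

#' Argmax prototype labels
#'
#' Assigns each cell to its most similar prototype (via the soft assignment of
#' the projected, normalized features); ties go to the lowest prototype index.
#'
#' @param state an `scscc_model`.
#' @param X preprocessed expression matrix, cells x n_in.
#' @param tau_s assignment temperature (default 0.1; the argmax is
#'   temperature-invariant, the argument only matters for the probabilities).
#' @return integer label vector in `1..K`.
#' @export
prototype_labels <- function(state, X, tau_s = 0.1) {
  H <- project(state, embed(state, X))
  P <- soft_assign(prototype_logits(state, H), tau_s)
  max.col(P, ties.method = "first")
}

#' Consensus early-stopping check
#'
#' @param S K-means labels on the current embedding.
#' @param S_tilde prototype labels, same length.
#' @param tol ARI threshold in (0, 1].
#' @param ari_max running maximum consensus ARI (default -1).
#' @return list with `stop` (TRUE iff `ARI(S, S_tilde) > tol`), `ari_cur`, and
#'   the updated `ari_max`.
#' @export
check_early_stop <- function(S, S_tilde, tol, ari_max = -1) {
  if (length(S) != length(S_tilde)) stop("label vectors must have equal length")
  ari_cur <- ari(S, S_tilde)
  list(stop = ari_cur > tol, ari_cur = ari_cur,
       ari_max = max(ari_max, ari_cur))
}

#' Extract final cell embeddings
#'
#' Encoder forward pass on the un-augmented preprocessed matrix (no masking or
#' noise at inference), so repeated calls are identical.
#'
#' @param state an `scscc_model`.
#' @param X preprocessed expression matrix.
#' @return m x d embedding matrix.
#' @export
extract_embeddings <- function(state, X) embed(state, X)

# ---- one optimization step on a minibatch -----------------------------------
# Returns losses and the updated model/optimizer. Q is a constant (no gradient
# flows through the Sinkhorn balancing).
train_step <- function(state, opt, Xb, aug_cfg, loss_cfg, lr,
                       w_sw, w_ins, kappa) {
  av <- augment_batch(Xb, aug_cfg)
  fe1 <- mlp_forward(state$encoder, av$view1, cache = TRUE, training = TRUE)
  state$encoder <- fe1$net
  fe2 <- mlp_forward(state$encoder, av$view2, cache = TRUE, training = TRUE)
  state$encoder <- fe2$net
  fp1 <- mlp_forward(state$projection, fe1$out, cache = TRUE, training = TRUE)
  state$projection <- fp1$net
  fp2 <- mlp_forward(state$projection, fe2$out, cache = TRUE, training = TRUE)
  state$projection <- fp2$net
  H1 <- fp1$out; H2 <- fp2$out

  dH1 <- matrix(0, nrow(H1), ncol(H1))
  dH2 <- dH1
  L_sw <- 0; L_ins <- 0
  dC <- array(0, dim(state$C))

  if (w_sw > 0) {
    if (state$normalize) {
      Cn <- l2_normalize_rows_safe(state$C)
      H1n <- l2_normalize_rows_safe(H1)
      H2n <- l2_normalize_rows_safe(H2)
    } else {
      Cn <- state$C; H1n <- H1; H2n <- H2
    }
    lg1 <- tcrossprod(H1n, Cn)
    lg2 <- tcrossprod(H2n, Cn)
    Q1 <- sinkhorn_targets(lg1, loss_cfg$sinkhorn_eps, loss_cfg$sinkhorn_iters)
    Q2 <- sinkhorn_targets(lg2, loss_cfg$sinkhorn_eps, loss_cfg$sinkhorn_iters)
    P1 <- soft_assign(lg1, loss_cfg$tau_s)
    P2 <- soft_assign(lg2, loss_cfg$tau_s)
    L_sw <- swapped_loss(P1, P2, Q1, Q2, loss_cfg$mean_over_batch)
    g <- swapped_loss_grad(P1, P2, Q1, Q2, loss_cfg$tau_s,
                           loss_cfg$mean_over_batch)
    dHn1 <- g$dlogits1 %*% Cn * w_sw
    dHn2 <- g$dlogits2 %*% Cn * w_sw
    dCn <- (crossprod(g$dlogits1, H1n) + crossprod(g$dlogits2, H2n)) * w_sw
    if (state$normalize) {
      dH1 <- dH1 + backprop_rownorm(H1, H1n, dHn1)
      dH2 <- dH2 + backprop_rownorm(H2, H2n, dHn2)
      dC <- dC + backprop_rownorm(state$C, Cn, dCn)
    } else {
      dH1 <- dH1 + dHn1
      dH2 <- dH2 + dHn2
      dC <- dC + dCn
    }
  }

  if (w_ins > 0) {
    res <- infonce_loss(H1, H2, loss_cfg$tau_i, loss_cfg$include_self,
                        grad = TRUE)
    L_ins <- res$loss
    dH1 <- dH1 + w_ins * res$dH1
    dH2 <- dH2 + w_ins * res$dH2
  }

  bp1 <- mlp_backward(state$projection, fp1, dH1)
  bp2 <- mlp_backward(state$projection, fp2, dH2)
  be1 <- mlp_backward(state$encoder, fe1, bp1$dX)
  be2 <- mlp_backward(state$encoder, fe2, bp2$dX)

  grads <- c(
    Map(`+`, mlp_grad_list(be1), mlp_grad_list(be2)),
    Map(`+`, mlp_grad_list(bp1), mlp_grad_list(bp2)),
    list(dC)
  )
  params <- c(mlp_params(state$encoder), mlp_params(state$projection),
              list(state$C))
  upd <- adam_update(opt, grads, params, lr)
  ne <- length(mlp_params(state$encoder))
  np <- length(mlp_params(state$projection))
  state$encoder <- mlp_set_params(state$encoder, upd$params[seq_len(ne)])
  state$projection <- mlp_set_params(state$projection,
                                     upd$params[ne + seq_len(np)])
  state$C <- upd$params[[ne + np + 1L]]

  list(state = state, opt = upd$state, L_sw = L_sw, L_ins = L_ins)
}

# d(loss)/d(M) given d(loss)/d(Mn) where Mn = M with L2-normalized rows.
# Zero rows (normalized as zeros) get zero gradient, the subgradient choice.
backprop_rownorm <- function(M, Mn, dMn) {
  nrm <- sqrt(rowSums(M * M))
  out <- (dMn - rowSums(dMn * Mn) * Mn) / pmax(nrm, 1e-12)
  out[nrm < 1e-12, ] <- 0
  out
}

#' Fit a contrastive clustering model to a count matrix
#'
#' The main entry point. Preprocesses the counts (filter, median-library-size
#' log-normalization, highly-variable-gene selection, per-gene z-score), then
#' trains the encoder/projection/prototype model by minibatch Adam on
#' `L = L_sw + kappa * L_ins` for the pretraining epochs and on the swapped
#' loss alone afterwards, checking the K-means/prototype consensus ARI for
#' early stopping. Final labels are K-means on the learned embedding.
#'
#' @param counts cells x genes count matrix (see [count_matrix()]), or an
#'   already-preprocessed real matrix if `preprocess = FALSE`.
#' @param K number of clusters.
#' @param n_hvg number of highly variable genes (default 2000).
#' @param dims optional [network_dims()]; defaults to hidden `c(512, 256)`,
#'   `d = 128`, `t = 32` for the actual input width.
#' @param aug an [augmentation_config()].
#' @param loss a [loss_config()]; `kappa = NULL` applies the automatic
#'   small/large dataset rule (see [auto_kappa()]).
#' @param train a [train_config()].
#' @param objective `"full"` (default) trains both objectives;`"instance"` and
#'   `"swap"` are single-objective ablations (instance-only has no prototypes
#'   to agree with, so no early stopping).
#' @param pretrain what the pretraining phase minimizes under the full
#'   objective: `"instance"` (default) uses the instance loss alone, so the
#'   encoder first learns disentangled representations which the swapped phase
#'   then refines; `"combined"` uses `L_sw + kappa * L_ins` throughout
#'   pretraining. With heavily masked views the combined form lets the swapped
#'   term dominate before any structure exists and can collapse all
#'   assignments to uniform; see the package vignette.
#' @param truth optional ground-truth labels; when supplied the fitted object
#'   carries ARI/NMI in its metric report.
#' @param preprocess set FALSE when `counts` is already a preprocessed
#'   expression matrix.
#' @param metrics compute the metric report (silhouette/Davies-Bouldin need
#'   the full distance matrix; default TRUE for up to 5000 cells).
#' @param verbose print per-epoch losses.
#' @return an object of class `scscc`: list with `labels`, `embedding`,
#'   `model`, `trainlog` (data.frame: epoch, L_sw, L_ins, L, ari_consensus),
#'   `ari_max`, `stop_epoch`, `stop_reason`, `metrics`, `centers`,
#'   `preprocessing`, and the configurations used.
#' @export
scscc <- function(counts, K, n_hvg = 2000, dims = NULL,
                  aug = augmentation_config(),
                  loss = loss_config(),
                  train = train_config(),
                  objective = c("full", "instance", "swap"),
                  pretrain = c("instance", "combined"),
                  truth = NULL, preprocess = TRUE, normalize = TRUE,
                  metrics = NULL, verbose = FALSE) {
  objective <- match.arg(objective)
  pretrain <- match.arg(pretrain)
  cl <- match.call()

  if (preprocess) {
    X <- preprocess_counts(counts, n_hvg = n_hvg)
    prep <- list(genes = colnames(X),
                 gene_center = attr(X, "gene_center"),
                 gene_scale = attr(X, "gene_scale"),
                 s_mid = attr(X, "size_factors")$s_mid,
                 steps = steps_applied(X))
    if (!is.null(truth) && nrow(X) != length(truth)) {
      ids <- rownames(counts)
      if (is.null(ids)) ids <- paste0("cell_", seq_len(nrow(counts)))
      truth <- truth[ids %in% rownames(X)]
    }
  } else {
    X <- as.matrix(counts)
    prep <- list(genes = colnames(X), steps = attr(X, "steps"))
  }
  m <- nrow(X)
  if (K < 2) stop("K must be >= 2")
  if (!is.null(truth) && length(truth) != m) {
    stop("truth labels must match the number of (retained) cells")
  }
  if (is.null(metrics)) metrics <- m <= 5000
  kappa <- if (is.null(loss$kappa)) auto_kappa(m) else loss$kappa

  if (is.null(dims)) {
    dims <- network_dims(n_in = ncol(X), K = K)
  } else {
    if (dims$n_in != ncol(X)) stop("dims$n_in must equal ncol of the input")
    if (dims$K != K) stop("dims$K must equal K")
  }

  fit <- with_local_seed(train$seed, {
    state <- init_model(dims, normalize = normalize)
    opt <- adam_init(lapply(
      c(mlp_params(state$encoder), mlp_params(state$projection),
        list(state$C)), dim_or_len))
    n_e <- train$total_epochs
    n_pre <- train$pretrain_epochs
    log <- data.frame(epoch = seq_len(n_e), L_sw = NA_real_,
                      L_ins = NA_real_, L = NA_real_,
                      ari_consensus = NA_real_)
    ari_max <- -1
    stop_epoch <- n_e
    stop_reason <- "max_epochs"
    snapshot <- state

    for (epoch in seq_len(n_e)) {
      use_ins <- switch(objective,
                        full = epoch <= n_pre,
                        instance = TRUE,
                        swap = FALSE)
      w_sw <- if (objective == "instance") 0 else
        if (objective == "full" && pretrain == "instance" && epoch <= n_pre) 0 else 1
      w_ins <- if (!use_ins) 0 else
        if (objective == "full" && pretrain == "combined") kappa else 1

      lr_e <- if (identical(train$lr_schedule, "cosine")) {
        train$lr * (0.01 + 0.99 * 0.5 * (1 + cos(pi * (epoch - 1) / n_e)))
      } else train$lr

      idx <- sample.int(m)
      starts <- seq(1, m, by = train$batch_size)
      batches <- lapply(starts, function(s) {
        idx[s:min(s + train$batch_size - 1L, m)]
      })
      nb <- length(batches)
      if (nb > 1 && length(batches[[nb]]) < 2) {
        batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
        batches <- batches[-nb]
      }

      sw_sum <- 0; ins_sum <- 0
      diverged <- FALSE
      for (b in batches) {
        st <- train_step(state, opt, X[b, , drop = FALSE], aug, loss,
                         lr_e, w_sw, w_ins, kappa)
        if (!is.finite(st$L_sw) || !is.finite(st$L_ins)) {
          diverged <- TRUE
          break
        }
        state <- st$state; opt <- st$opt
        sw_sum <- sw_sum + st$L_sw
        ins_sum <- ins_sum + st$L_ins
      }
      if (diverged) {
        warning("non-finite loss at epoch ", epoch,
                "; reverting to the last completed epoch")
        state <- snapshot
        stop_epoch <- epoch
        stop_reason <- "divergence"
        break
      }
      snapshot <- state
      nb <- length(batches)
      L_sw_ep <- if (w_sw > 0) sw_sum / nb else NA_real_
      L_ins_ep <- if (w_ins > 0) ins_sum / nb else 0
      L_ep <- if (objective == "instance") L_ins_ep
        else if (objective == "swap" || epoch > n_pre) L_sw_ep
        else if (pretrain == "combined") total_loss(L_sw_ep, L_ins_ep, kappa)
        else L_ins_ep
      log[epoch, c("L_sw", "L_ins", "L")] <- c(L_sw_ep, L_ins_ep, L_ep)
      if (verbose) {
        message(sprintf("epoch %3d  L=%.4f  L_sw=%.4f  L_ins=%.4f",
                        epoch, L_ep, L_sw_ep, L_ins_ep))
      }

      if (objective != "instance" && epoch > n_pre &&
          (epoch - n_pre) %% train$check_interval == 0) {
        Z <- extract_embeddings(state, X)
        S <- kmeans_cluster(Z, K, restarts = train$kmeans_restarts)
        S_t <- prototype_labels(state, X, loss$tau_s)
        chk <- check_early_stop(S, S_t, train$tol, ari_max)
        ari_max <- chk$ari_max
        log$ari_consensus[epoch] <- chk$ari_cur
        if (chk$stop) {
          stop_epoch <- epoch
          stop_reason <- "early_stop"
          break
        }
      }
      stop_epoch <- epoch
    }
    log <- log[seq_len(stop_epoch), , drop = FALSE]

    Z <- extract_embeddings(state, X)
    S <- kmeans_cluster(Z, K, restarts = train$kmeans_restarts)
    centers <- do.call(rbind, lapply(seq_len(K), function(j) {
      if (any(S == j)) colMeans(Z[S == j, , drop = FALSE]) else rep(NA_real_, ncol(Z))
    }))
    list(state = state, Z = Z, S = S, centers = centers, log = log,
         ari_max = ari_max, stop_epoch = stop_epoch,
         stop_reason = stop_reason)
  })

  met <- if (metrics) {
    suppressWarnings(evaluate_clustering(fit$Z, fit$S, truth))
  } else {
    out <- c(ARI = NaN, NMI = NaN, SC = NaN, DBi = NaN)
    if (!is.null(truth)) {
      out["ARI"] <- ari(truth, fit$S)
      out["NMI"] <- nmi(truth, fit$S)
    }
    out
  }

  structure(list(labels = fit$S, embedding = fit$Z, model = fit$state,
                 trainlog = fit$log, ari_max = fit$ari_max,
                 stop_epoch = fit$stop_epoch, stop_reason = fit$stop_reason,
                 metrics = met, centers = fit$centers, K = K,
                 objective = objective, pretrain = pretrain, kappa = kappa,
                 config = list(aug = aug, loss = loss, train = train),
                 preprocessing = prep, call = cl),
            class = "scscc")
}

dim_or_len <- function(x) if (is.matrix(x)) dim(x) else length(x)
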