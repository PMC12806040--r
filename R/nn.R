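# Minimal fully-connected network machinery: forward pass with cache,
# analytic backward pass, optional batch normalization on hidden layers,
# Adam updates. Internal; the user-facing surface is in model.R / scscc().
#
# A net is a list of layers; layer l holds W (in x out) and b (length out),
# plus batch-norm parameters (gamma, beta) and running statistics
# (running_mean, running_var) on hidden layers when enabled. Hidden layers are
# linear -> [batchnorm] -> ReLU; the final layer is plain linear (a terminal
# ReLU would confine outputs to the positive orthant and break cosine
# geometry).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

mlp_init <- function(sizes, batchnorm = FALSE) {
  nl <- length(sizes) - 1L
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- sizes[l]
    # He initialization for ReLU-fed layers, Glorot-like for the linear output
    sd <- if (l < nl) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    lay <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sd),
                 fan_in, sizes[l + 1]),
      b = numeric(sizes[l + 1])
    )
    if (batchnorm && l < nl) {
      lay$gamma <- rep(1, sizes[l + 1])
      lay$beta <- numeric(sizes[l + 1])
      lay$running_mean <- numeric(sizes[l + 1])
      lay$running_var <- rep(1, sizes[l + 1])
    }
    layers[[l]] <- lay
  }
  structure(list(layers = layers, sizes = sizes, batchnorm = batchnorm),
            class = "scscc_mlp")
}

# Forward pass. `training` selects batch statistics (and updates the running
# ones) for batch-norm layers; inference uses the running statistics. Returns
# out, per-layer cache for the backward pass, and the (possibly updated) net.
mlp_forward <- function(net, X, cache = FALSE, training = FALSE) {
  nl <- length(net$layers)
  caches <- if (cache) vector("list", nl) else NULL
  A <- X
  for (l in seq_len(nl)) {
    lay <- net$layers[[l]]
    lin <- sweep(A %*% lay$W, 2, lay$b, "+")
    cc <- list(input = A)
    if (!is.null(lay$gamma)) {
      if (training) {
        mu <- colMeans(lin)
        v <- colMeans(lin^2) - mu^2
        net$layers[[l]]$running_mean <-
          BN_MOMENTUM * lay$running_mean + (1 - BN_MOMENTUM) * mu
        net$layers[[l]]$running_var <-
          BN_MOMENTUM * lay$running_var + (1 - BN_MOMENTUM) * v
      } else {
        mu <- lay$running_mean
        v <- lay$running_var
      }
      inv_sd <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(sweep(lin, 2, mu), 2, inv_sd, "*")
      out <- sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+")
      cc$xhat <- xhat
      cc$inv_sd <- inv_sd
      A <- out
    } else {
      A <- lin
    }
    if (l < nl) {
      A[A < 0] <- 0  # ReLU on hidden layers only
      cc$post <- A
    }
    if (cache) caches[[l]] <- cc
  }
  if (cache) list(out = A, caches = caches, net = net) else A
}

# Backward pass: dOut is dL/d(output). Returns per-layer parameter gradients
# (W, b and, for batch-norm layers, gamma, beta) and dX. Batch-norm backward
# uses the standard batch-statistics formulas; the ReLU derivative is 1 on the
# open positive part.
mlp_backward <- function(net, fw, dOut) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  delta <- dOut
  for (l in rev(seq_len(nl))) {
    lay <- net$layers[[l]]
    cc <- fw$caches[[l]]
    if (l < nl) delta[cc$post <= 0] <- 0  # through ReLU of this layer
    g <- list()
    if (!is.null(lay$gamma)) {
      g$gamma <- colSums(delta * cc$xhat)
      g$beta <- colSums(delta)
      n <- nrow(delta)
      dxhat <- sweep(delta, 2, lay$gamma, "*")
      delta <- sweep(
        dxhat - matrix(colMeans(dxhat), n, ncol(dxhat), byrow = TRUE) -
          cc$xhat * matrix(colMeans(dxhat * cc$xhat), n, ncol(dxhat),
                           byrow = TRUE),
        2, cc$inv_sd, "*")
    }
    g$W <- crossprod(cc$input, delta)
    g$b <- colSums(delta)
    grads[[l]] <- g
    delta <- tcrossprod(delta, lay$W)
  }
  list(layers = grads, dX = delta)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(shapes) {
  st <- lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
  list(slots = st, t = 0L)
}

adam_update <- function(state, grads, params, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    sl <- state$slots[[i]]
    sl$m <- beta1 * sl$m + (1 - beta1) * g
    sl$v <- beta2 * sl$v + (1 - beta2) * g * g
    params[[i]] <- params[[i]] - lr * (sl$m / bc1) / (sqrt(sl$v / bc2) + eps)
    state$slots[[i]] <- sl
  }
  list(state = state, params = params)
}

# Flatten a net's trainable parameters into a list, in a fixed order
# (per layer: W, b, then gamma, beta where present). Running statistics are
# state, not parameters, and stay inside the net.
mlp_params <- function(net) {
  out <- list()
  for (lay in net$layers) {
    out <- c(out, list(lay$W, lay$b))
    if (!is.null(lay$gamma)) out <- c(out, list(lay$gamma, lay$beta))
  }
  out
}

mlp_set_params <- function(net, params) {
  k <- 1L
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- params[[k]]
    net$layers[[l]]$b <- as.numeric(params[[k + 1L]])
    k <- k + 2L
    if (!is.null(net$layers[[l]]$gamma)) {
      net$layers[[l]]$gamma <- as.numeric(params[[k]])
      net$layers[[l]]$beta <- as.numeric(params[[k + 1L]])
      k <- k + 2L
    }
  }
  net
}

mlp_grad_list <- function(bw) {
  out <- list()
  for (g in bw$layers) {
    out <- c(out, list(g$W, g$b))
    if (!is.null(g$gamma)) out <- c(out, list(g$gamma, g$beta))
  }
  out
}

mlp_n_params <- function(net) {
  sum(vapply(mlp_params(net), length, 0L))
}
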