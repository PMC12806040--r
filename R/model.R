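# Trainable components: encoder f (3 fully-connected layers, ReLU on hidden),
# projection head g (2 fully-connected layers, ReLU on hidden), and a K x t
# prototype matrix C acting as learnable cluster anchors in the projected
# feature space.

#' Network dimensions
#'
#' @param n_in number of input genes.
#' @param hidden encoder hidden widths (two values give the standard
#'   three-layer encoder). Default `c(512, 256)`.
#' @param d embedding dimension (must satisfy `d < n_in`). Default 128.
#' @param t projected feature dimension. Default 32.
#' @param K number of prototypes / clusters, >= 2.
#' @param proj_hidden projection-head hidden width. Default 256.
#' @param batchnorm batch-normalize hidden layers (default FALSE; available as the standard
#'   device of this encoder family; inference uses running statistics, so
#'   embeddings stay deterministic).
#' @return validated list of class `scscc_dims`.
#' @export
network_dims <- function(n_in, hidden = c(512, 256), d = 128, t = 32, K,
                         proj_hidden = 256, batchnorm = FALSE) {
  if (any(c(n_in, hidden, d, t, proj_hidden) < 1)) stop("all widths must be >= 1")
  if (d >= n_in) stop("embedding dimension d must be smaller than n_in")
  if (K < 2) stop("K must be >= 2")
  structure(list(n_in = n_in, hidden = hidden, d = d, t = t, K = K,
                 proj_hidden = proj_hidden, batchnorm = isTRUE(batchnorm)),
            class = "scscc_dims")
}

#' Initialize model state
#'
#' Builds the encoder, projection head and prototype matrix with
#' He/Glorot-style Gaussian initialization, deterministically for a given
#' seed. Prototype rows are drawn standard normal and then L2-normalized.
#'
#' @param dims a [network_dims()] object.
#' @param seed integer seed; if NULL the current RNG stream is consumed.
#' @param normalize L2-normalize projected features and prototype rows before
#'   the prototype inner product (default TRUE, keeping assignment logits on
#'   the cosine scale used by the instance loss).
#' @return list of class `scscc_model` with `encoder`, `projection`, `C`,
#'   `dims`, `seed`, `normalize`.
#' @export
init_model <- function(dims, seed = NULL, normalize = TRUE) {
  if (!inherits(dims, "scscc_dims")) stop("dims must come from network_dims()")
  build <- function() {
    enc <- mlp_init(c(dims$n_in, dims$hidden, dims$d), dims$batchnorm)
    prj <- mlp_init(c(dims$d, dims$proj_hidden, dims$t), dims$batchnorm)
    C <- matrix(stats::rnorm(dims$K * dims$t), dims$K, dims$t)
    C <- l2_normalize_rows(C)
    list(encoder = enc, projection = prj, C = C)
  }
  parts <- if (is.null(seed)) build() else with_local_seed(seed, build())
  structure(c(parts, list(dims = dims, seed = seed, normalize = normalize)),
            class = "scscc_model")
}

#' Number of trainable parameters of a model
#' @param state an `scscc_model`.
#' @return integer count over encoder, projection head and prototypes.
#' @export
n_parameters <- function(state) {
  mlp_n_params(state$encoder) + mlp_n_params(state$projection) +
    length(state$C)
}

check_finite <- function(M, what) {
  if (!all(is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)
    stop("non-finite values in ", what, " (first bad batch row: ",
         bad[1, 1], ")")
  }
  M
}

#' Encode a (possibly augmented) view into cell embeddings
#'
#' @param state an `scscc_model`.
#' @param X batch x n_in matrix.
#' @return batch x d embedding matrix Z.
#' @export
embed <- function(state, X) {
  X <- as.matrix(X)
  if (ncol(X) != state$dims$n_in) {
    stop("input has ", ncol(X), " columns; encoder expects ", state$dims$n_in)
  }
  check_finite(mlp_forward(state$encoder, X), "embedding output")
}

#' Project embeddings into the contrastive feature space
#'
#' @param state an `scscc_model`.
#' @param Z batch x d embedding matrix.
#' @return batch x t deep-feature matrix H.
#' @export
project <- function(state, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != state$dims$d) {
    stop("input has ", ncol(Z), " columns; projection head expects ",
         state$dims$d)
  }
  check_finite(mlp_forward(state$projection, Z), "projected features")
}

#' Prototype similarity scores
#'
#' Inner products between deep features and prototype rows. With
#' `normalize = TRUE` (the model default) both are L2-normalized first, so the
#' scores are cosine similarities in `[-1, 1]`.
#'
#' @param state an `scscc_model`.
#' @param H batch x t deep features.
#' @param normalize override the model's normalization flag.
#' @return batch x K score matrix.
#' @export
prototype_logits <- function(state, H, normalize = state$normalize) {
  H <- as.matrix(H)
  if (ncol(H) != ncol(state$C)) {
    stop("feature dimension ", ncol(H), " does not match prototype dimension ",
         ncol(state$C))
  }
  if (normalize) {
    tcrossprod(l2_normalize_rows_safe(H), l2_normalize_rows_safe(state$C))
  } else {
    tcrossprod(H, state$C)
  }
}

#' Temperature-smoothed soft assignments
#'
#' Row-wise softmax of `logits / tau_s`: each row is a probability vector over
#' the K prototypes.
#'
#' @param logits batch x K score matrix.
#' @param tau_s assignment temperature, > 0 (default 0.1).
#' @return batch x K row-stochastic matrix.
#' @export
soft_assign <- function(logits, tau_s = 0.1) {
  if (!is.numeric(tau_s) || length(tau_s) != 1 || tau_s <= 0) {
    stop("tau_s must be a single positive value")
  }
  softmax_rows(as.matrix(logits) / tau_s)
}

# ---- shared numeric helpers -------------------------------------------------

l2_normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M * M))
  if (any(nrm == 0)) stop("cannot L2-normalize a zero row")
  M / nrm
}

# Zero rows (e.g. a fully ReLU-dead feature row at initialization) are left
# as zeros instead of erroring: they then score 0 against every prototype,
# i.e. a uniform soft assignment, the sensible limit.
l2_normalize_rows_safe <- function(M) {
  nrm <- pmax(sqrt(rowSums(M * M)), 1e-12)
  M / nrm
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

row_logsumexp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

col_logsumexp <- function(M) {
  mx <- apply(M, 2, max)
  mx + log(colSums(exp(sweep(M, 2, mx))))
}

# Evaluate expr-like thunk under a temporary seed, restoring the caller's RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
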