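# Independent brute-force oracles: deliberately dumb loop implementations of
# every quantity the package computes in vectorized form. They share no code
# with the package internals.

oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# InfoNCE per the printed definition, triple loop, anchor self-term excluded.
oracle_infonce <- function(H1, H2, tau) {
  N <- nrow(H1)
  feats <- vector("list", 2 * N)
  for (i in 1:N) feats[[i]] <- H1[i, ]
  for (i in 1:N) feats[[N + i]] <- H2[i, ]
  pos <- c((N + 1):(2 * N), 1:N)
  total <- 0
  for (a in 1:(2 * N)) {
    num <- exp(oracle_cosine(feats[[a]], feats[[pos[a]]]) / tau)
    den <- 0
    for (b in 1:(2 * N)) {
      if (b != a) den <- den + exp(oracle_cosine(feats[[a]], feats[[b]]) / tau)
    }
    total <- total - log(num / den)
  }
  total / (2 * N)
}

oracle_swapped <- function(P1, P2, Q1, Q2) {
  s <- 0
  for (i in seq_len(nrow(P1))) {
    for (j in seq_len(ncol(P1))) {
      s <- s - Q1[i, j] * log(max(P2[i, j], 1e-12)) -
        Q2[i, j] * log(max(P1[i, j], 1e-12))
    }
  }
  s
}

# Iterative proportional fitting on exp(logits / eps): multiplicative row and
# column scaling toward row sums 1 and column sums N/K, final row rescale.
oracle_sinkhorn_ipf <- function(logits, eps, iters) {
  M <- exp(logits / eps)
  N <- nrow(M); K <- ncol(M)
  for (it in seq_len(iters)) {
    for (i in 1:N) M[i, ] <- M[i, ] / sum(M[i, ])
    for (j in 1:K) M[, j] <- M[, j] * (N / K) / sum(M[, j])
  }
  for (i in 1:N) M[i, ] <- M[i, ] / sum(M[i, ])
  M
}

# ARI from explicit enumeration of all unordered pairs.
oracle_ari <- function(U, V) {
  n <- length(U)
  a <- b <- c_ <- d <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      su <- U[i] == U[j]
      sv <- V[i] == V[j]
      if (su && sv) a <- a + 1
      else if (su && !sv) b <- b + 1
      else if (!su && sv) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- n * (n - 1) / 2
  e <- (a + b) * (a + c_) + (c_ + d) * (b + d)
  if (tot^2 - e == 0) return(1)
  (tot * (a + d) - e) / (tot^2 - e)
}

oracle_nmi <- function(U, V) {
  n <- length(U)
  uu <- unique(U); vv <- unique(V)
  mi <- 0
  for (p in uu) {
    for (q in vv) {
      npq <- sum(U == p & V == q)
      if (npq > 0) {
        mi <- mi + (npq / n) * log(n * npq / (sum(U == p) * sum(V == q)))
      }
    }
  }
  hu <- 0
  for (p in uu) hu <- hu - (sum(U == p) / n) * log(sum(U == p) / n)
  hv <- 0
  for (q in vv) hv <- hv - (sum(V == q) / n) * log(sum(V == q) / n)
  if (hu + hv == 0) return(0)
  2 * mi / (hu + hv)
}

oracle_silhouette <- function(X, S) {
  m <- nrow(X)
  dmat <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) dmat[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  ks <- unique(S)
  s <- numeric(m)
  for (i in 1:m) {
    own <- which(S == S[i] & seq_len(m) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- Inf
    for (k in setdiff(ks, S[i])) b <- min(b, mean(dmat[i, S == k]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbi <- function(X, S) {
  ks <- sort(unique(S))
  cent <- list(); scat <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    Xi <- X[S == ks[ki], , drop = FALSE]
    cent[[ki]] <- colMeans(Xi)
    scat[ki] <- mean(apply(Xi, 1, function(r) sqrt(sum((r - cent[[ki]])^2))))
  }
  r <- numeric(length(ks))
  for (i in seq_along(ks)) {
    best <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (scat[i] + scat[j]) / dij)
    }
    r[i] <- best
  }
  mean(r)
}

l2norm_rows_for_test <- function(M) M / sqrt(rowSums(M^2))

# random row-stochastic matrix
rand_stochastic <- function(n, k) {
  M <- matrix(rexp(n * k), n, k)
  M / rowSums(M)
}

# random label vector guaranteed to use each of k labels at least once
rand_labels <- function(n, k) {
  stopifnot(n >= k)
  c(seq_len(k), sample.int(k, n - k, replace = TRUE))[sample.int(n)]
}
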