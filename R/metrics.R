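# Final clustering and the four validity indices: adjusted Rand index and
# normalized mutual information against ground truth; silhouette and
# Davies-Bouldin on the embedding itself.

#' K-means clustering with k-means++ seeding and restarts
#'
#' Runs `restarts` independent K-means fits (Hartigan-Wong via
#' [stats::kmeans()]), each initialized with k-means++ center seeding, and
#' keeps the solution with the lowest total within-cluster sum of squares.
#' Deterministic for a given `seed`.
#'
#' @param Z numeric matrix, observations x features.
#' @param K number of clusters, `1 <= K <= nrow(Z)`.
#' @param seed optional integer; when given, the caller's RNG state is
#'   preserved. When NULL the current stream is consumed.
#' @param restarts number of restarts (default 10).
#' @param iter.max K-means iteration cap per restart.
#' @return integer label vector in `1..K`.
#' @export
kmeans_cluster <- function(Z, K, seed = NULL, restarts = 10, iter.max = 100) {
  Z <- as.matrix(Z)
  m <- nrow(Z)
  if (K > m) stop("K (", K, ") exceeds the number of observations (", m, ")")
  if (K == 1) return(rep(1L, m))
  run <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(Z, K)
      km <- suppressWarnings(
        stats::kmeans(Z, centers = centers, iter.max = iter.max)
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best$cluster
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to the squared distance to the nearest chosen one.
kmeanspp_centers <- function(Z, K) {
  m <- nrow(Z)
  idx <- integer(K)
  idx[1] <- sample.int(m, 1)
  d2 <- colSums((t(Z) - Z[idx[1], ])^2)
  for (k in 2:K) {
    if (all(d2 == 0)) {
      idx[k] <- sample.int(m, 1)  # duplicated data: fall back to uniform
    } else {
      idx[k] <- sample.int(m, 1, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(Z) - Z[idx[k], ])^2))
  }
  Z[idx, , drop = FALSE] + 0  # drop names, force copy
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two labelings, computed
#' from the pair counts a (same/same), b (same in U only), c (same in V only),
#' d (different in both). Value in `[-1, 1]`; 1 is perfect agreement.
#'
#' @param U,V equal-length label vectors (any atomic type).
#' @return scalar ARI.
#' @export
ari <- function(U, V) {
  pc <- pair_counts(U, V)
  tot <- pc$a + pc$b + pc$c + pc$d  # choose(n, 2)
  e <- (pc$a + pc$b) * (pc$a + pc$c) + (pc$c + pc$d) * (pc$b + pc$d)
  den <- tot^2 - e
  if (den == 0) return(1)  # both partitions trivial and identical
  (tot * (pc$a + pc$d) - e) / den
}

#' Pair counts underlying the adjusted Rand index
#'
#' @param U,V equal-length label vectors.
#' @return list with pair counts `a`, `b`, `c`, `d` (summing to choose(n, 2))
#'   and the contingency `table`.
#' @export
pair_counts <- function(U, V) {
  if (length(U) != length(V)) stop("label vectors must have equal length")
  n <- length(U)
  tab <- table(U, V)
  a <- sum(choose(tab, 2))
  sameU <- sum(choose(rowSums(tab), 2))
  sameV <- sum(choose(colSums(tab), 2))
  b <- sameU - a
  c_ <- sameV - a
  d <- choose(n, 2) - a - b - c_
  list(a = a, b = b, c = c_, d = d, table = tab)
}

#' Normalized mutual information
#'
#' Mutual information between the two labelings divided by the arithmetic mean
#' of their entropies (natural logs). Value in `[0, 1]`; 1 for identical
#' nondegenerate partitions. When either labeling is a single cluster the
#' denominator entropy can be 0; the result is then defined as 0 with a
#' warning.
#'
#' @param U,V equal-length label vectors.
#' @return scalar NMI.
#' @export
nmi <- function(U, V) {
  if (length(U) != length(V)) stop("label vectors must have equal length")
  n <- length(U)
  tab <- table(U, V) / n
  pu <- rowSums(tab)
  pv <- colSums(tab)
  hu <- -sum(pu * log(pu), na.rm = TRUE)
  hv <- -sum(pv * log(pv), na.rm = TRUE)
  if (hu + hv == 0) {
    warning("both labelings are single clusters; NMI defined as 0")
    return(0)
  }
  pq <- tab[tab > 0]
  ep <- outer(pu, pv)[tab > 0]
  mi <- sum(pq * log(pq / ep))
  2 * mi / (hu + hv)
}

#' Mean silhouette coefficient
#'
#' For each point, `(b - a) / max(a, b)` where `a` is its mean distance to its
#' own cluster (excluding itself) and `b` the smallest mean distance to any
#' other cluster; Euclidean distances. Singleton clusters get silhouette 0
#' (with a warning), as does the degenerate 0/0 case of coincident points.
#'
#' @param X numeric matrix, observations x features.
#' @param S label vector.
#' @return mean silhouette, in `[-1, 1]`.
#' @export
silhouette_score <- function(X, S) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (length(S) != m) stop("labels must match the number of rows")
  S <- as.integer(factor(S))
  k <- max(S)
  if (k < 2) stop("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(X))
  sizes <- tabulate(S, k)
  if (any(sizes == 1)) warning("singleton cluster(s): their silhouette is 0")
  # mean distance from every point to every cluster, via indicator algebra
  Ind <- outer(S, seq_len(k), "==") * 1
  sums <- D %*% Ind                       # m x k total distance to cluster
  s <- numeric(m)
  for (i in seq_len(m)) {
    ci <- S[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1)
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio
#' `(scatter_I + scatter_J) / d(centroid_I, centroid_J)`, where scatter is the
#' mean Euclidean distance of members to their own centroid. Lower is better;
#' 0 when every member sits on its centroid.
#'
#' @param X numeric matrix, observations x features.
#' @param S label vector with at least 2 clusters.
#' @return scalar index, >= 0.
#' @export
davies_bouldin <- function(X, S) {
  X <- as.matrix(X)
  S <- as.integer(factor(S))
  k <- max(S)
  if (k < 2) stop("Davies-Bouldin undefined for a single cluster")
  cent <- matrix(0, k, ncol(X))
  scat <- numeric(k)
  for (j in seq_len(k)) {
    Xi <- X[S == j, , drop = FALSE]
    cent[j, ] <- colMeans(Xi)
    scat[j] <- mean(sqrt(rowSums(sweep(Xi, 2, cent[j, ])^2)))
  }
  Dc <- as.matrix(stats::dist(cent))
  r <- numeric(k)
  for (i in seq_len(k)) {
    dij <- Dc[i, -i]
    if (any(dij == 0)) {
      j <- setdiff(seq_len(k), i)[which(dij == 0)[1]]
      stop("coincident centroids for clusters ", i, " and ", j)
    }
    r[i] <- max((scat[i] + scat[-i]) / dij)
  }
  mean(r)
}

#' Clustering metric report
#'
#' ARI and NMI require ground truth and are NaN without it; silhouette and
#' Davies-Bouldin are computed from the embedding and predicted labels (NaN,
#' with a warning, when undefined, e.g. a collapsed single-cluster labeling).
#'
#' @param Z embedding matrix, cells x d.
#' @param S predicted label vector.
#' @param truth optional ground-truth label vector.
#' @return named numeric vector `c(ARI, NMI, SC, DBi)`.
#' @export
evaluate_clustering <- function(Z, S, truth = NULL) {
  res <- c(ARI = NaN, NMI = NaN, SC = NaN, DBi = NaN)
  if (!is.null(truth)) {
    res["ARI"] <- ari(truth, S)
    res["NMI"] <- nmi(truth, S)
  }
  res["SC"] <- tryCatch(silhouette_score(Z, S), error = function(e) {
    warning(conditionMessage(e)); NaN
  })
  res["DBi"] <- tryCatch(davies_bouldin(Z, S), error = function(e) {
    warning(conditionMessage(e)); NaN
  })
  res
}
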