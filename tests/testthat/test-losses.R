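test_that("cosine similarity handles the canonical cases", {
  expect_equal(cosine_sim(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_sim(c(0, 0), c(1, 0)), "zero vector")
})

test_that("InfoNCE matches closed forms", {
  # all 2N features identical: every term in the softmax is equal, so
  # l = ln(2N - 1) for every anchor
  for (N in c(3, 5, 8)) {
    Hi <- matrix(1, N, 4)
    expect_equal(infonce_loss(Hi, Hi, 0.1), log(2 * N - 1), tolerance = 1e-12)
  }

  # aligned positives, mutually orthogonal negatives, tau = 0.1:
  # l = -ln( e^{10} / (e^{10} + (2N - 2) e^{0}) )
  N <- 4
  H <- diag(N)
  expect_equal(infonce_loss(H, H, 0.1),
               -log(exp(10) / (exp(10) + (2 * N - 2))), tolerance = 1e-10)

  expect_error(infonce_loss(matrix(1, 1, 3), matrix(1, 1, 3), 0.1), "at least 2")
})

test_that("InfoNCE agrees with the triple-loop oracle and is rotation invariant", {
  set.seed(51)
  for (rep in 1:5) {
    H1 <- matrix(rnorm(30), 6, 5)
    H2 <- matrix(rnorm(30), 6, 5)
    tau <- runif(1, 0.05, 1)
    expect_equal(infonce_loss(H1, H2, tau), oracle_infonce(H1, H2, tau),
                 tolerance = 1e-10)
  }

  # common rotation of all features leaves the loss unchanged
  H1 <- matrix(rnorm(30), 6, 5)
  H2 <- matrix(rnorm(30), 6, 5)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(infonce_loss(H1 %*% Q, H2 %*% Q, 0.2),
               infonce_loss(H1, H2, 0.2), tolerance = 1e-10)
})

test_that("InfoNCE decreases as positive-pair similarity increases", {
  # anchor pairs at a controlled angle; negatives held fixed
  set.seed(57)
  H1 <- l2norm_rows_for_test(matrix(rnorm(4 * 6), 4, 6))
  noise <- l2norm_rows_for_test(matrix(rnorm(4 * 6), 4, 6))
  losses <- sapply(c(0.2, 0.5, 0.9, 0.99), function(r) {
    H2 <- l2norm_rows_for_test(r * H1 + (1 - r) * noise)
    infonce_loss(H1, H2, 0.2)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("Sinkhorn balancing hits the prescribed marginals", {
  # constant logits: exactly uniform
  Q <- sinkhorn_targets(matrix(2, 6, 3))
  expect_equal(Q, matrix(1 / 3, 6, 3))

  # convergence on random logits: rows 1, columns N/K within 1e-6
  set.seed(52)
  L <- matrix(rnorm(64 * 8), 64, 8)
  Qc <- sinkhorn_targets(L, eps = 0.05, iters = 2000)
  expect_lt(max(abs(rowSums(Qc) - 1)), 1e-6)
  expect_lt(max(abs(colSums(Qc) - 64 / 8)), 1e-6)
  expect_true(all(Qc >= 0))

  # 4x2 fixture: converged result matches the IPF oracle
  L2 <- matrix(c(0.5, -1, 2, 0, 1, -0.3, 0.2, 0.9), 4, 2)
  expect_equal(sinkhorn_targets(L2, eps = 0.1, iters = 500),
               oracle_sinkhorn_ipf(L2, 0.1, 500), tolerance = 1e-6)

  # row-permutation equivariance
  set.seed(53)
  L3 <- matrix(rnorm(15), 5, 3)
  p <- sample(5)
  expect_equal(sinkhorn_targets(L3, iters = 50)[p, ],
               sinkhorn_targets(L3[p, ], iters = 50), tolerance = 1e-12)

  expect_error(sinkhorn_targets(matrix(c(1, Inf), 1, 2)), "finite")
  expect_warning(sinkhorn_targets(matrix(rnorm(6), 2, 3)), "ill-posed")
})

test_that("swapped loss matches closed forms and the loop oracle", {
  # uniform P and Q: 2N ln K under the printed sum convention
  N <- 5; K <- 3
  U <- matrix(1 / K, N, K)
  expect_equal(swapped_loss(U, U, U, U), 2 * N * log(K), tolerance = 1e-12)
  expect_equal(swapped_loss(U, U, U, U, mean_over_batch = TRUE), 2 * log(K),
               tolerance = 1e-12)

  # perfect swapped agreement with one-hot everything: loss at the clamp floor
  I3 <- diag(3)[c(1, 2, 3, 1), ]
  expect_warning(l0 <- swapped_loss(I3, I3, I3, I3), "clamping")
  expect_lt(l0, 1e-8)

  set.seed(54)
  for (rep in 1:5) {
    P1 <- rand_stochastic(5, 3); P2 <- rand_stochastic(5, 3)
    Q1 <- rand_stochastic(5, 3); Q2 <- rand_stochastic(5, 3)
    expect_equal(swapped_loss(P1, P2, Q1, Q2), oracle_swapped(P1, P2, Q1, Q2),
                 tolerance = 1e-10)
    expect_gte(swapped_loss(P1, P2, Q1, Q2), 0)
  }

  expect_error(swapped_loss(U, U[1:3, ], U, U), "shape")
})

test_that("the combined objective is a weighted sum", {
  expect_equal(total_loss(2, 3, 0), 2)
  expect_equal(total_loss(2, 3, 1), 5)
  expect_equal(total_loss(2.0, 3.0, 0.01), 2.03)
  expect_error(total_loss(Inf, 1, 0.1), "finite")
  expect_equal(auto_kappa(500), 0.01)
  expect_equal(auto_kappa(10001), 1)
})

test_that("loss configuration is validated", {
  expect_error(loss_config(tau_i = 0), "temperatures")
  expect_error(loss_config(kappa = -1), "kappa")
  expect_error(loss_config(sinkhorn_eps = 0), "positive")
  cfg <- loss_config()
  expect_equal(cfg$tau_i, 0.1)
  expect_equal(cfg$tau_s, 0.1)
  expect_equal(cfg$sinkhorn_iters, 3L)
  expect_equal(cfg$sinkhorn_eps, 0.05)
})

test_that("analytic gradients match central finite differences", {
  set.seed(55)
  H1 <- matrix(rnorm(12), 4, 3)
  H2 <- matrix(rnorm(12), 4, 3)
  tau <- 0.3
  res <- infonce_loss(H1, H2, tau, grad = TRUE)
  eps <- 1e-6
  for (M in c("dH1", "dH2")) {
    target <- if (M == "dH1") H1 else H2
    for (i in seq_along(target)) {
      up <- target; up[i] <- up[i] + eps
      dn <- target; dn[i] <- dn[i] - eps
      fd <- if (M == "dH1") {
        (infonce_loss(up, H2, tau) - infonce_loss(dn, H2, tau)) / (2 * eps)
      } else {
        (infonce_loss(H1, up, tau) - infonce_loss(H1, dn, tau)) / (2 * eps)
      }
      expect_lt(abs(fd - res[[M]][i]) / max(abs(fd), 1e-8), 1e-4)
    }
  }

  # swapped loss: d L / d logits = (P - Q_other) / tau_s with Q fixed
  set.seed(56)
  lg1 <- matrix(rnorm(12), 4, 3)
  lg2 <- matrix(rnorm(12), 4, 3)
  Q1 <- rand_stochastic(4, 3); Q2 <- rand_stochastic(4, 3)
  ts <- 0.2
  swl <- function(l1, l2) {
    swapped_loss(soft_assign(l1, ts), soft_assign(l2, ts), Q1, Q2)
  }
  g1 <- (soft_assign(lg1, ts) - Q2) / ts
  for (i in seq_along(lg1)) {
    up <- lg1; up[i] <- up[i] + eps
    dn <- lg1; dn[i] <- dn[i] - eps
    fd <- (swl(up, lg2) - swl(dn, lg2)) / (2 * eps)
    expect_lt(abs(fd - g1[i]) / max(abs(fd), 1e-8), 1e-4)
  }
})
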