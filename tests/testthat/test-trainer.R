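test_that("training configuration is validated", {
  expect_error(train_config(batch_size = 1), "batch_size")
  expect_error(train_config(pretrain_epochs = 10, total_epochs = 5), "pretrain")
  expect_error(train_config(tol = 0), "tol")
  expect_error(train_config(lr = -1), "lr")
})

test_that("same-seed runs produce identical logs and labels", {
  f1 <- tiny_fit(seed = 4)
  f2 <- tiny_fit(seed = 4)
  expect_identical(f1$trainlog, f2$trainlog)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$embedding, f2$embedding)
  f3 <- tiny_fit(seed = 5)
  expect_false(identical(f1$trainlog, f3$trainlog))
})

test_that("phase semantics: instance loss is zero after pretraining", {
  fit <- tiny_fit(seed = 6)
  tl <- fit$trainlog
  n_pre <- fit$config$train$pretrain_epochs
  post <- tl[tl$epoch > n_pre & !is.na(tl$L), ]
  expect_true(nrow(post) >= 1)
  expect_true(all(post$L_ins == 0))
  # pretraining epochs carry a positive instance loss
  pre <- tl[tl$epoch <= n_pre, ]
  expect_true(all(pre$L_ins > 0))
  # under instance-led pretraining the swapped loss is not part of the
  # pretraining objective
  expect_true(all(is.na(pre$L_sw)))
  expect_true(all(post$L_sw > 0))
})

test_that("pretrain_epochs = total_epochs is pure pretraining", {
  sim <- tiny_problem()
  fit <- suppressWarnings(scscc(
    sim$counts, K = 3, n_hvg = 30,
    dims = network_dims(n_in = 30, hidden = c(32, 16), d = 8, t = 4, K = 3,
                        proj_hidden = 16),
    train = train_config(batch_size = 20, pretrain_epochs = 5,
                         total_epochs = 5, lr = 5e-3, seed = 2),
    metrics = FALSE))
  expect_true(all(fit$trainlog$L_ins > 0))
  expect_equal(fit$stop_epoch, 5L)
  expect_equal(fit$stop_reason, "max_epochs")
})

test_that("the epoch-mean objective trends down early in training", {
  sim <- tiny_problem(seed = 8, m = 80)
  fit <- suppressWarnings(scscc(
    sim$counts, K = 3, n_hvg = 30,
    dims = network_dims(n_in = 30, hidden = c(32, 16), d = 8, t = 4, K = 3,
                        proj_hidden = 16),
    train = train_config(batch_size = 20, pretrain_epochs = 20,
                         total_epochs = 20, lr = 5e-3, seed = 3),
    metrics = FALSE))
  L <- fit$trainlog$L
  expect_lt(mean(L[16:20]), mean(L[1:5]))
})

test_that("prototype labels are argmax assignments with low-index ties", {
  dims <- network_dims(n_in = 10, hidden = c(8, 6), d = 4, t = 3, K = 3,
                       proj_hidden = 5)
  st <- init_model(dims, seed = 12)
  X <- matrix(rnorm(50), 5, 10)
  lab <- prototype_labels(st, X)
  P <- soft_assign(prototype_logits(st, project(st, embed(st, X))), 0.1)
  for (i in 1:5) {
    expect_equal(lab[i], which.max(P[i, ]))
  }

  # a duplicated prototype produces exact ties -> lower index wins
  st$C[2, ] <- st$C[3, ]
  lab2 <- prototype_labels(st, X)
  expect_false(any(lab2 == 3))

  # permutation equivariance (positive biases keep every feature row alive,
  # avoiding the uniform-assignment tie of an all-ReLU-dead row)
  st2 <- init_model(dims, seed = 12)
  for (l in seq_along(st2$encoder$layers)) st2$encoder$layers[[l]]$b[] <- 0.5
  for (l in seq_along(st2$projection$layers)) st2$projection$layers[[l]]$b[] <- 0.5
  perm <- c(3, 1, 2)
  st2p <- st2
  st2p$C <- st2$C[perm, ]
  expect_equal(match(prototype_labels(st2, X), perm),
               prototype_labels(st2p, X))
})

test_that("consensus early stopping follows the ARI threshold", {
  S <- c(1, 1, 2, 2, 3, 3)
  chk <- check_early_stop(S, S, tol = 0.9)
  expect_true(chk$stop)
  expect_equal(chk$ari_cur, 1)
  expect_equal(chk$ari_max, 1)

  # tol = 1 never stops, even on perfect agreement (strict inequality)
  expect_false(check_early_stop(S, S, tol = 1)$stop)

  # independent random labelings: ARI near 0, no stop at tol = 0.5
  set.seed(81)
  U <- sample(1:3, 200, replace = TRUE)
  V <- sample(1:3, 200, replace = TRUE)
  chk2 <- check_early_stop(U, V, tol = 0.5, ari_max = 0.2)
  expect_false(chk2$stop)
  expect_equal(chk2$ari_max, max(0.2, chk2$ari_cur))
  expect_lt(abs(chk2$ari_cur), 0.1)

  expect_error(check_early_stop(S, S[-1], 0.5), "equal length")
})

test_that("embedding extraction is deterministic and augmentation-free", {
  fit <- tiny_fit(seed = 7)
  sim <- tiny_problem()
  X <- suppressWarnings(preprocess_counts(sim$counts, n_hvg = 30))
  Z1 <- extract_embeddings(fit$model, X)
  Z2 <- extract_embeddings(fit$model, X)
  expect_identical(Z1, Z2)
  expect_equal(dim(Z1), c(nrow(X), 8L))
  expect_identical(Z1, embed(fit$model, X))
  expect_equal(unname(Z1), unname(fit$embedding))
})

test_that("ablation objectives run and record their own losses", {
  sim <- tiny_problem()
  base_args <- list(
    counts = sim$counts, K = 3, n_hvg = 30,
    dims = network_dims(n_in = 30, hidden = c(32, 16), d = 8, t = 4, K = 3,
                        proj_hidden = 16),
    train = train_config(batch_size = 20, pretrain_epochs = 3,
                         total_epochs = 6, lr = 5e-3, seed = 9),
    metrics = FALSE)
  fi <- suppressWarnings(do.call(scscc, c(base_args, objective = "instance")))
  expect_true(all(is.na(fi$trainlog$L_sw)))
  expect_true(all(fi$trainlog$L_ins > 0))
  fs <- suppressWarnings(do.call(scscc, c(base_args, objective = "swap")))
  expect_true(all(fs$trainlog$L_ins == 0))
  expect_true(all(fs$trainlog$L_sw > 0))
})
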