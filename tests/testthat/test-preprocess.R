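test_that("gene and cell filtering applies the two stated rules", {
  # gene B expressed in exactly 1 of 3 cells -> removed at the min_cells=2 rule
  m <- count_matrix(rbind(c(1, 0), c(2, 3), c(1, 0)),
                    gene_ids = c("A", "B"))
  f <- filter_counts(m)
  expect_equal(dim(f), c(3L, 1L))
  expect_equal(colnames(f), "A")

  # a cell of all zeros is removed
  m2 <- count_matrix(rbind(c(1, 2), c(0, 0), c(3, 4)))
  f2 <- filter_counts(m2)
  expect_equal(nrow(f2), 2L)
  expect_false("cell_2" %in% rownames(f2))

  # dense all-positive matrix passes unchanged
  m3 <- count_matrix(matrix(1:25, 5, 5))
  expect_equal(unname(filter_counts(m3))[, ], unname(m3)[, ])
})

test_that("filtering is a projection and errors on degenerate input", {
  set.seed(11)
  m <- count_matrix(matrix(rbinom(200, 2, 0.2), 20, 10))
  f1 <- filter_counts(m)
  f2 <- filter_counts(f1)
  expect_identical(unname(f1[, ]), unname(f2[, ]))

  allzero_genes <- count_matrix(cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_error(filter_counts(allzero_genes), "gene")
  onecol <- count_matrix(matrix(c(5, 0, 0, 5, 0, 0), 3, 2))
  expect_error(filter_counts(onecol), "cell")
})

test_that("log-normalization follows the median-size-factor formula", {
  # 2 cells x 1 gene, counts 2 and 4: s = (2, 4), s_mid = 3,
  # entries ln(3/2*2 + 1) = ln 4 and ln(3/4*4 + 1) = ln 4
  m <- count_matrix(matrix(c(2, 4), 2, 1))
  ln <- lognormalize(m)
  expect_equal(unname(ln$mat[, 1]), c(log(4), log(4)))
  expect_equal(unname(ln$size_factors$s), c(2, 4))
  expect_equal(ln$size_factors$s_mid, 3)

  # zeros map to zeros; equal totals reduce to ln(y + 1)
  m2 <- count_matrix(rbind(c(0, 3), c(2, 1)))
  ln2 <- lognormalize(m2)
  expect_equal(ln2$mat[1, 1], 0)
  expect_equal(unname(ln2$mat), log1p(unname(m2[, ])), ignore_attr = TRUE)

  # zero-total cell violates the precondition
  bad <- structure(rbind(c(1, 1), c(0, 0)), dimnames = list(NULL, NULL))
  expect_error(lognormalize(bad), "zero total")
})

test_that("log-normalization is monotone within each cell", {
  set.seed(12)
  m <- count_matrix(matrix(rpois(60, 4) + 1, 6, 10))
  ln <- lognormalize(m)$mat
  for (i in 1:6) {
    o <- order(m[i, ])
    expect_true(all(diff(ln[i, o]) >= 0))
    strict <- diff(m[i, o]) > 0
    expect_true(all(diff(ln[i, o])[strict] > 0))
  }
})

test_that("scaling one cell's counts changes only its own transform", {
  m <- count_matrix(rbind(c(2, 4), c(1, 3), c(5, 1)))
  ln <- lognormalize(m)
  # the cell whose total equals the median reduces to ln(y + 1)
  s <- ln$size_factors$s
  i <- which(s == ln$size_factors$s_mid)[1]
  expect_equal(unname(ln$mat[i, ]), log1p(unname(m[i, ])))
})

test_that("HVG selection ranks by dispersion with deterministic ties", {
  set.seed(13)
  X <- matrix(rnorm(100, 5), 10, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  X[, 7] <- X[, 7] * 10  # strictly largest variance/mean
  disp <- apply(X, 2, function(g) {
    mu <- mean(g); (mean(g^2) - mu^2) / mu
  })
  expect_equal(unname(which.max(disp)), 7L)
  sel <- select_hvg(X, 1)
  expect_equal(ncol(sel), 1L)
  expect_equal(unname(sel[, 1]), unname(X[, 7]))

  # ties broken by original column index
  Y <- cbind(a = c(0, 2, 4), b = c(0, 2, 4), c = c(1, 1, 1))
  sel2 <- select_hvg(Y, 1)
  expect_equal(colnames(sel2), "a")

  # n_hvg beyond the gene count keeps everything (with a warning)
  expect_warning(sel3 <- select_hvg(X, 50), "exceeds")
  expect_equal(ncol(sel3), 10L)
  expect_setequal(colnames(sel3), colnames(X))
})

test_that("z-scoring gives population mean 0 / variance 1 and is idempotent", {
  expect_equal(unname(zscore_genes(matrix(c(0, 2), 2, 1))[, 1]), c(-1, 1))

  set.seed(14)
  X <- matrix(rnorm(200, 3, 2), 20, 10)
  Z <- zscore_genes(X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  popvar <- colMeans(Z^2) - colMeans(Z)^2
  expect_lt(max(abs(popvar - 1)), 1e-8)
  expect_lt(max(abs(zscore_genes(Z) - Z)), 1e-10)

  const <- cbind(rnorm(5), rep(2, 5))
  expect_error(zscore_genes(const), "constant")
  expect_warning(dropped <- zscore_genes(const, drop_zero_var = TRUE),
                 "zero-variance")
  expect_equal(ncol(dropped), 1L)
})

test_that("the pipeline composes the four stages in order, deterministically", {
  sim <- simulate_counts(sim_config(m = 200, n_genes = 500, K = 3,
                                    proportions = rep(1 / 3, 3), seed = 21))
  X1 <- suppressWarnings(preprocess_counts(sim$counts, n_hvg = 100))
  X2 <- suppressWarnings(preprocess_counts(sim$counts, n_hvg = 100))
  expect_identical(X1[, ], X2[, ])
  expect_equal(steps_applied(X1), c("filter", "lognormalize", "hvg", "zscore"))
  expect_equal(ncol(X1), 100L)
  expect_lt(max(abs(colMeans(X1))), 1e-10)

  # equals the stages applied manually
  f <- filter_counts(sim$counts)
  ln <- lognormalize(f)
  hv <- select_hvg(ln$mat, 100)
  z <- suppressWarnings(zscore_genes(hv, drop_zero_var = TRUE))
  expect_equal(unname(X1[, ]), unname(z[, ]))
})

test_that("count matrix validation catches malformed input", {
  expect_error(count_matrix(matrix(-1, 2, 2)), "negative")
  expect_error(count_matrix(matrix(0.5, 2, 2)), "non-integer")
  expect_error(count_matrix(matrix(0L, 2, 2), cell_ids = c("a", "a")),
               "duplicate")
})
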