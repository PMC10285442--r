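test_that("perfect and null fits bracket the explained variance", {
  set.seed(1)
  X <- matrix(rnorm(24), 8, 3)
  B <- matrix(rnorm(15), 3, 5)
  Y <- X %*% B
  expect_equal(rda_fit(Y, X)$prop_explained, 1, tolerance = 1e-10)

  # responses orthogonal to the predictors by construction
  Y2 <- matrix(rnorm(40), 8, 5)
  Y2 <- stats::resid(stats::lm(Y2 ~ X))
  expect_lt(rda_fit(Y2, X)$prop_explained, 1e-10)
})

test_that("rda_fit matches an independent brute-force reduced-rank oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    Y <- matrix(rnorm(40), 8, 5)
    X <- matrix(rnorm(24), 8, 3)
    fit <- rda_fit(Y, X)

    # oracle: explicit multivariate regression + full eigendecomposition
    Yc <- scale(Y, scale = FALSE)
    Xc <- scale(X, scale = FALSE)
    Bh <- solve(crossprod(Xc)) %*% crossprod(Xc, Yc)
    Yh <- Xc %*% Bh
    ev <- eigen(crossprod(Yh) / (nrow(Y) - 1), symmetric = TRUE)$values
    ev <- ev[ev > 1e-12]
    expect_equal(unname(fit$eigenvalues), ev, tolerance = 1e-8)
    expect_equal(fit$prop_explained, sum(ev) / (sum(Yc^2) / (nrow(Y) - 1)),
                 tolerance = 1e-8)
  }
})

test_that("rda_fit agrees with vegan as an independent cross-check", {
  skip_if_not_installed("vegan")
  set.seed(2)
  Y <- matrix(rnorm(60), 10, 6)
  X <- matrix(rnorm(30), 10, 3)
  fit <- rda_fit(Y, X)
  v <- vegan::rda(Y ~ X)
  expect_equal(unname(fit$eigenvalues), unname(v$CCA$eig), tolerance = 1e-10)
  expect_equal(fit$prop_explained, v$CCA$tot.chi / v$tot.chi,
               tolerance = 1e-10)
})

test_that("explained proportion is invariant to rotation of Y and scaling of X", {
  set.seed(3)
  Y <- matrix(rnorm(48), 12, 4)
  X <- matrix(rnorm(24), 12, 2)
  base <- rda_fit(Y, X)$prop_explained
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(rda_fit(Y %*% Q, X)$prop_explained, base, tolerance = 1e-10)
  Xs <- sweep(X, 2, c(10, 0.01), "*")
  Xs <- sweep(Xs, 2, c(-5, 3), "+")
  expect_equal(rda_fit(Y, Xs)$prop_explained, base, tolerance = 1e-10)
})

test_that("axis count and ordering invariants hold", {
  set.seed(4)
  Y <- matrix(rnorm(70), 10, 7)
  X <- matrix(rnorm(30), 10, 3)
  fit <- rda_fit(Y, X)
  expect_lte(fit$rank, 3)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_gte(fit$prop_explained, 0); expect_lte(fit$prop_explained, 1)
  expect_equal(dim(rda_scores(fit, display = "sites")), c(10, 2))
})

test_that("sequential term variances sum to the constrained variance", {
  set.seed(5)
  Y <- matrix(rnorm(60), 15, 4)
  X <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  fit <- rda_fit(Y, X)
  tt <- rda_sequential_test(Y, X, n_perm = 99, seed = 1)
  terms <- tt$term != "Residual"
  expect_equal(sum(tt$variance[terms]), sum(fit$eigenvalues),
               tolerance = 1e-10)
  # residual + constrained = total
  expect_equal(sum(tt$variance), fit$total_variance, tolerance = 1e-10)
})

test_that("permutation tests are deterministic and detect a strong effect", {
  set.seed(6)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  Y <- matrix(rnorm(80, sd = 0.3), 20, 4)
  Y[, 1] <- Y[, 1] + 3 * X$a
  t1 <- rda_sequential_test(Y, X, n_perm = 199, seed = 3)
  t2 <- rda_sequential_test(Y, X, n_perm = 199, seed = 3)
  expect_identical(t1$p, t2$p)
  expect_equal(t1$p[1], 1 / 200)     # attainable minimum
  expect_gt(t1$p[2], 0.05)
  t3 <- rda_sequential_test(Y, X, n_perm = 199, seed = 4)
  expect_equal(t3$p[1], 1 / 200)
})

test_that("term order is honoured and validated", {
  set.seed(7)
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  Y <- matrix(rnorm(36), 12, 3)
  tt <- rda_sequential_test(Y, X, term_order = c("b", "a"), n_perm = 99,
                            seed = 1)
  expect_equal(tt$term[1:2], c("b", "a"))
  expect_error(rda_sequential_test(Y, X, term_order = c("a", "z"),
                                   n_perm = 99), "every term")
  expect_error(rda_sequential_test(Y, X, n_perm = 50), "at least 99")
})

test_that("factor terms expand to their contrast degrees of freedom", {
  set.seed(8)
  X <- data.frame(g = factor(rep(c("u", "v", "w"), each = 5)),
                  z = rnorm(15))
  Y <- matrix(rnorm(45), 15, 3)
  tt <- rda_sequential_test(Y, X, n_perm = 99, seed = 2)
  expect_equal(tt$df[tt$term == "g"], 2L)
  expect_equal(tt$df[tt$term == "z"], 1L)
})
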