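sess <- build_session("spider", 4, seed = 1)
dm <- build_design_matrix(sess)

test_that("OLS recovers planted betas exactly on noiseless data", {
  spec <- small_spec(noise_sd = 0)
  cfg <- effect_config(seed = 1)
  v <- simulate_bold(list(id = "T1", spider_trait = 2), sess, spec, cfg,
                     seed = 1, design = build_design_matrix(sess, drift_order = 0))
  fit <- fit_glm(v, dm)
  roi <- spec$true_roi
  lin <- roi[, 1] + (roi[, 2] - 1) * 6 + (roi[, 3] - 1) * 36
  k <- match("tarantula", sess$conditions)
  expect_equal(unname(fit$betas[k, lin]), rep(0.7 + 1, nrow(roi)),
               tolerance = 1e-8)
  out <- setdiff(seq_len(216), lin)
  expect_equal(unname(fit$betas[k, out]), rep(0.5, length(out)),
               tolerance = 1e-8)
  expect_true(all(fit$sigma2 < 1e-16))
})

test_that("a response equal to one regressor is fitted exactly", {
  y <- dm$X[, 1]
  v <- make_series(array(y, c(1, 1, 1, length(y))))
  fit <- fit_glm(v, dm)
  expect_equal(unname(fit$betas[, 1]),
               c(1, rep(0, ncol(dm$X) - 1)), tolerance = 1e-10)
  expect_equal(unname(fit$sigma2), 0, tolerance = 1e-20)
})

test_that("voxelwise OLS agrees with the lm() oracle", {
  set.seed(3)
  nvox <- 5
  arr <- array(rnorm(nvox * sess$n_volumes), c(nvox, 1, 1, sess$n_volumes))
  fit <- fit_glm(make_series(arr), dm)
  for (i in seq_len(nvox)) {
    ref <- stats::lm(arr[i, 1, 1, ] ~ dm$X - 1)
    expect_equal(unname(fit$betas[, i]), unname(stats::coef(ref)),
                 tolerance = 1e-10)
    expect_equal(fit$sigma2[i], summary(ref)$sigma^2, tolerance = 1e-10)
  }
})

test_that("contrast t-maps match a hand-coded formula and are antisymmetric", {
  set.seed(5)
  arr <- array(rnorm(4 * sess$n_volumes), c(4, 1, 1, sess$n_volumes))
  fit <- fit_glm(make_series(arr), dm)
  cw <- rep(0, ncol(dm$X)); cw[1] <- 1; cw[2] <- -1
  tm <- contrast_tmap(fit, cw, name = "c1-c2")
  # independent brute force straight from the definition
  X <- dm$X
  xtxi <- solve(crossprod(X))
  for (i in 1:4) {
    y <- arr[i, 1, 1, ]
    b <- xtxi %*% crossprod(X, y)
    rss <- sum((y - X %*% b)^2)
    s2 <- rss / (length(y) - ncol(X))
    t_ref <- drop(crossprod(cw, b)) / sqrt(s2 * drop(t(cw) %*% xtxi %*% cw))
    expect_equal(tm$tvalues[i, 1, 1], t_ref, tolerance = 1e-10)
  }
  tneg <- contrast_tmap(fit, -cw, name = "c2-c1")
  expect_equal(tneg$tvalues, -tm$tvalues, tolerance = 1e-12)
  expect_error(contrast_tmap(fit, rep(0, ncol(dm$X))), "all zero")
})

test_that("named condition contrasts resolve against the design", {
  set.seed(6)
  arr <- array(rnorm(2 * sess$n_volumes), c(2, 1, 1, sess$n_volumes))
  fit <- fit_glm(make_series(arr), dm)
  t1 <- contrast_tmap(fit, c(tarantula = 1, beetle = -1))
  cw <- rep(0, ncol(dm$X))
  cw[match(c("tarantula", "beetle"), dm$regressor_names)] <- c(1, -1)
  t2 <- contrast_tmap(fit, cw)
  expect_equal(t1$tvalues, t2$tvalues)
})

test_that("planted contrast effect elevates t inside the true region", {
  spec <- small_spec(noise_sd = 1)
  cfg <- effect_config(seed = 1)
  v <- simulate_bold(list(id = "T1", spider_trait = 2.5), sess, spec, cfg,
                     seed = 13, design = build_design_matrix(sess, drift_order = 0))
  tm <- contrast_tmap(fit_glm(v, dm), c(tarantula = 1, beetle = -1))
  roi_mask <- array(FALSE, c(6, 6, 6))
  roi_mask[spec$true_roi] <- TRUE
  expect_gt(mean(tm$tvalues[roi_mask]), mean(tm$tvalues[!roi_mask]) + 2)
})

test_that("group one-sample map matches the direct formula", {
  set.seed(8)
  maps <- lapply(1:6, function(i)
    make_stat_map(array(rnorm(8), c(2, 2, 2)), df = 20))
  g <- group_onesample_tmap(maps, use = "t")
  vals <- sapply(maps, function(m) m$tvalues[1, 1, 1])
  expect_equal(g$tvalues[1, 1, 1],
               mean(vals) / (stats::sd(vals) / sqrt(6)), tolerance = 1e-12)
  expect_equal(g$df, 5L)
  flipped <- lapply(maps, function(m) {
    m$tvalues <- -m$tvalues; m$effect <- -m$effect; m
  })
  gf <- group_onesample_tmap(flipped, use = "t")
  expect_equal(gf$tvalues, -g$tvalues, tolerance = 1e-12)
})

test_that("identical subject maps yield a flagged infinite group t", {
  same <- array(1.5, c(2, 2, 2))
  maps <- lapply(1:4, function(i) make_stat_map(same))
  g <- group_onesample_tmap(maps)
  expect_true(all(is.infinite(g$tvalues) & g$tvalues > 0))
  expect_error(group_onesample_tmap(maps[1]), "at least 2")
})

test_that("first-level t-values are calibrated under the null", {
  # white-noise series (no autocorrelation): the voxelwise two-sided
  # rejection rate at alpha = 0.05 should match alpha to binomial error
  spec <- brain_spec(grid_dims = c(12, 12, 12),
                     baseline_amplitudes = list(outside = 0, inside = NULL),
                     noise_sd = 1, ar1_coef = 0)
  v <- simulate_bold(list(spider_trait = 0), sess, spec, null_config(),
                     seed = 31)
  tm <- contrast_tmap(fit_glm(v, dm), c(tarantula = 1, beetle = -1))
  crit <- stats::qt(0.975, tm$df)
  k <- sum(abs(tm$tvalues) > crit)
  bounds <- stats::qbinom(c(0.0005, 0.9995), 1728, 0.05)
  expect_gte(k, bounds[1]); expect_lte(k, bounds[2])
})
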