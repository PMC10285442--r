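test_that("single-voxel Bonferroni reduces to an uncorrected test", {
  df <- 20L
  t_sig <- stats::qt(0.96, df)   # one-sided p ~0.04 < 0.05
  m <- make_stat_map(array(t_sig, c(1, 1, 1)), df = df)
  roi <- define_roi(m, alpha = 0.05)
  expect_equal(roi$n_voxels, 1L)
  t_ns <- stats::qt(0.94, df)
  roi2 <- define_roi(make_stat_map(array(t_ns, c(1, 1, 1)), df = df))
  expect_equal(roi2$n_voxels, 0L)
})

test_that("non-finite voxels are excluded from ROI candidacy", {
  tv <- array(c(Inf, 10, 0, 1), c(4, 1, 1))
  roi <- define_roi(make_stat_map(tv, df = 30L))
  expect_false(roi$mask[1, 1, 1])
  expect_true(roi$mask[2, 1, 1])
  all_bad <- make_stat_map(array(Inf, c(2, 1, 1)))
  expect_error(define_roi(all_bad), "no valid voxels")
})

test_that("SFI is the mean t inside the region", {
  mask <- array(FALSE, c(3, 3, 1)); mask[1, 1, 1] <- mask[2, 2, 1] <- TRUE
  roi <- structure(list(mask = mask, n_voxels = 2L, alpha = 0.05,
                        method = "bonferroni", source_contrast = "toy"),
                   class = "roi_mask")
  tv <- array(0, c(3, 3, 1)); tv[1, 1, 1] <- 1; tv[2, 2, 1] <- 3
  rec <- compute_sfi(make_stat_map(tv), roi)
  expect_equal(rec$sfi, 2)
  expect_equal(rec$n_roi_voxels, 2L)

  const <- array(4.2, c(3, 3, 1))
  expect_equal(compute_sfi(make_stat_map(const), roi)$sfi, 4.2)

  # invariance to a relabeling of the voxel axes
  rec_t <- compute_sfi(make_stat_map(aperm(tv, c(2, 1, 3))),
                       structure(list(mask = aperm(mask, c(2, 1, 3)),
                                      n_voxels = 2L, alpha = 0.05,
                                      method = "bonferroni",
                                      source_contrast = "toy"),
                                 class = "roi_mask"))
  expect_equal(rec_t$sfi, rec$sfi)

  empty <- structure(list(mask = array(FALSE, c(3, 3, 1)), n_voxels = 0L,
                          alpha = 0.05, method = "bonferroni",
                          source_contrast = "toy"), class = "roi_mask")
  expect_error(compute_sfi(make_stat_map(tv), empty), "empty ROI")
  wrong <- structure(list(mask = array(TRUE, c(2, 2, 1)), n_voxels = 4L,
                          alpha = 0.05, method = "bonferroni",
                          source_contrast = "toy"), class = "roi_mask")
  expect_error(compute_sfi(make_stat_map(tv), wrong), "grids")
})

test_that("a strong planted effect recovers the true region under FWE", {
  cfg <- effect_config(n_phobic = 10, n_control = 2, seed = 5)
  co <- generate_cohort(cfg)
  spec <- small_spec()
  tab <- sfi_pipeline(co, spec = spec, blocks_per_condition = 4)
  roi <- attr(tab, "roi")
  truth <- array(FALSE, c(6, 6, 6)); truth[spec$true_roi] <- TRUE
  hits <- sum(roi$mask & truth)
  false_pos <- sum(roi$mask & !truth)
  expect_gt(hits, nrow(spec$true_roi) / 2)   # majority of planted voxels
  expect_lte(false_pos, 1)                   # FWE keeps false positives rare
})

test_that("max-t permutation thresholding behaves like an FWE procedure", {
  set.seed(9)
  n_sub <- 12
  maps <- lapply(seq_len(n_sub), function(i) {
    eff <- array(rnorm(64), c(4, 4, 4))
    eff[1, 1, 1] <- eff[1, 1, 1] + 3   # one strongly active voxel
    make_stat_map(eff, df = 100L, effect = eff)
  })
  g <- group_onesample_tmap(maps)
  roi <- define_roi(g, method = "max_t_permutation", subject_maps = maps,
                    n_perm = 499, seed = 2)
  expect_true(roi$mask[1, 1, 1])
  expect_lte(roi$n_voxels, 3)
  expect_error(define_roi(g, method = "max_t_permutation"), "subject_maps")
})

test_that("ROI from the fear session is independent of spider-session noise", {
  # null spider-session maps: SFI distribution centred at zero
  set.seed(14)
  mask <- array(FALSE, c(5, 5, 5)); mask[2:3, 2:3, 2:3] <- TRUE
  roi <- structure(list(mask = mask, n_voxels = sum(mask), alpha = 0.05,
                        method = "bonferroni", source_contrast = "toy"),
                   class = "roi_mask")
  sfis <- replicate(60, compute_sfi(
    make_stat_map(array(rnorm(125), c(5, 5, 5))), roi)$sfi)
  se <- stats::sd(sfis) / sqrt(length(sfis))
  expect_lt(abs(mean(sfis)), 4 * se + 0.05)
})

test_that("the pipeline is deterministic and errors without any effect", {
  cfg <- effect_config(n_phobic = 4, n_control = 4, seed = 3)
  co <- generate_cohort(cfg)
  t1 <- sfi_pipeline(co, spec = small_spec(), blocks_per_condition = 4)
  t2 <- sfi_pipeline(co, spec = small_spec(), blocks_per_condition = 4)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  null_co <- generate_cohort(null_config(seed = 3))
  expect_error(
    sfi_pipeline(null_co, spec = null_spec(), blocks_per_condition = 4),
    "empty ROI|no valid voxels")
})

test_that("excluded subjects drop out of both mask and index", {
  cfg <- effect_config(n_phobic = 5, n_control = 3, seed = 6)
  co <- generate_cohort(cfg)
  tab <- sfi_pipeline(co, spec = small_spec(), blocks_per_condition = 4,
                      exclude = "S001")
  expect_false("S001" %in% tab$subject_id)
  expect_equal(nrow(tab), 7)
})
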