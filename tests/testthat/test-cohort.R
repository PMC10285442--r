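test_that("cohort generation is deterministic and respects bounds", {
  cfg <- effect_config(n_phobic = 6, n_control = 6, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(dim(a$spq), c(12, 31))
  expect_equal(dim(a$snaq), c(12, 30))
  expect_equal(dim(a$dsr), c(12, 27))
  expect_equal(dim(a$interview), c(12, 6))
  expect_true(all(a$ratings %in% 1:7))
  expect_true(all(a$dsr %in% 0:4))
  expect_true(all(a$info$bat_steps %in% 0:7))
  expect_true(all(a$info$age >= 18 & a$info$age <= 66))
})

test_that("seed is required and group sizes validated", {
  expect_error(generate_cohort(effect_config(seed = NULL)), "seed")
  expect_error(effect_config(n_phobic = 1, seed = 1), "at least 2")
  expect_error(effect_config(snake_trait_corr = 1.5, seed = 1), "correlations")
  expect_error(effect_config(trait_sd = 0, seed = 1), "positive")
})

test_that("default calibration brackets the published group summaries", {
  co <- generate_cohort(effect_config(seed = 1))
  sc <- score_cohort(co)
  m <- function(col, g) mean(sc[[col]][sc$group == g])

  expect_gt(m("spq", "phobic"), 18); expect_lt(m("spq", "phobic"), 26)
  expect_gte(m("spq", "control"), 0); expect_lt(m("spq", "control"), 5)
  expect_gt(m("spq", "phobic"), m("spq", "control"))
  expect_lt(m("bat", "phobic"), m("bat", "control"))
  expect_gt(m("fs_tarantula", "phobic"), m("fs_tarantula", "control"))
  # snake-fear screening rule holds for everyone
  expect_true(all(sc$snaq <= 17))
  # interview rule: phobics nearly always reach >= 5 yes, controls ~all zero
  expect_gte(mean(sc$interview_class[sc$group == "phobic"] == "phobic"), 0.95)
  expect_true(all(sc$interview_class[sc$group == "control"] == "not_phobic"))
  expect_gte(mean(sc$interview_positive[sc$group == "control"] == 0), 0.95)
})

test_that("null configuration yields no group differences", {
  co <- generate_cohort(null_config(n_phobic = 500, n_control = 500, seed = 9))
  sc <- score_cohort(co)
  d_spq <- diff(tapply(sc$spq, sc$group, mean))
  expect_lt(abs(d_spq), 0.5)
  d_fs <- diff(tapply(sc$fs_tarantula, sc$group, mean))
  expect_lt(abs(d_fs), 0.2)
})

test_that("group differences grow monotonically with trait separation", {
  seps <- c(0, 1.2, 2.5)
  gaps <- sapply(seps, function(s) {
    cfg <- effect_config(trait_means = c(phobic = s, control = 0), seed = 11)
    sc <- score_cohort(generate_cohort(cfg))
    c(spq = unname(diff(rev(tapply(sc$spq, sc$group, mean)))),
      fs = unname(diff(rev(tapply(sc$fs_tarantula, sc$group, mean)))),
      bat = unname(diff(rev(tapply(sc$bat, sc$group, mean)))))
  })
  expect_true(all(diff(gaps["spq", ]) > 0))
  expect_true(all(diff(gaps["fs", ]) > 0))
  expect_true(all(diff(gaps["bat", ]) < 0))
})

test_that("rating model clips to the scale ends", {
  cfg_floor <- effect_config(
    rating_mu = stats::setNames(rep(1, 6), fear_categories()),
    rating_weights = stats::setNames(rep(0, 6), fear_categories()),
    rating_snake_weights = stats::setNames(rep(0, 6), fear_categories()),
    rating_noise_sd = 0, seed = 1)
  subj <- list(spider_trait = 1.3, snake_trait = 0.2)
  expect_true(all(generate_ratings(subj, cfg_floor) == 1))

  cfg_ceil <- effect_config(
    rating_mu = stats::setNames(rep(9, 6), fear_categories()),
    rating_weights = stats::setNames(rep(0, 6), fear_categories()),
    rating_snake_weights = stats::setNames(rep(0, 6), fear_categories()),
    rating_noise_sd = 0, seed = 1)
  expect_true(all(generate_ratings(subj, cfg_ceil) == 7))
  expect_error(generate_ratings(list(), cfg_floor), "spider_trait")
})

test_that("cohort serialization round-trips through plain text", {
  co <- generate_cohort(effect_config(n_phobic = 3, n_control = 3, seed = 2))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  wide <- utils::read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(wide), 6)
  expect_equal(wide$spq, score_cohort(co)$spq)
  long <- utils::read.csv(file.path(dir, "ratings.csv"))
  expect_equal(nrow(long), 6 * 6 * co$config$n_pictures)
  expect_true(all(long$rating %in% 1:7))
})
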