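#' Stimulus categories used throughout the package
#'
#' Six picture categories shown during the scanning sessions and rated
#' afterwards: big spiders (tarantula), small spiders (daddy-long-legs),
#' beetles, leaves, venomous snakes, and lizards.
#'
#' @return Character vector of the six category labels, in canonical order.
#' @export
fear_categories <- function() {
  c("tarantula", "daddy_long_legs", "beetle", "leaves", "snake", "lizard")
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the generative model for a two-group
#' (phobic / control) cohort.  Latent standardized traits -- spider fear,
#' snake fear, and disgust propensity -- drive all observed measures:
#' questionnaire item endorsements through a logistic item-response model,
#' behavioral approach through ordered thresholds, picture fear ratings
#' through linear loadings, and the planted BOLD amplitude through
#' `activation_gain`.
#'
#' The defaults encode the study conditions the package emulates: 30 phobic
#' and 32 control women, a latent-trait separation calibrated so that
#' expected SPQ totals are about 22 (phobic) versus 1.6 (control), weakly
#' correlated snake-fear and disgust traits, and a snake-fear cap keeping
#' simulated SNAQ totals at or below 17.
#'
#' @param n_phobic,n_control Group sizes (each at least 2).
#' @param trait_means Length-2 numeric, latent spider-fear mean for the
#'   phobic and control group (standardized units).
#' @param trait_sd Within-group SD of each latent trait; must be positive.
#' @param snake_trait_corr,disgust_trait_corr Correlation of the snake-fear
#'   (resp. disgust) trait with the spider-fear trait, in \[-1, 1\].
#' @param snake_trait_cap Upper cap applied to the snake-fear trait,
#'   emulating the exclusion of snake-fearful respondents (SNAQ <= 17).
#'   `Inf` disables the cap.
#' @param rating_mu Named numeric (6): per-category base mean of the 1--7
#'   fear rating scale.
#' @param rating_weights Named numeric (6): per-category loading of the
#'   spider-fear trait on ratings.
#' @param rating_snake_weights Named numeric (6): per-category loading of
#'   the snake-fear trait.
#' @param rating_noise_sd SD of the rating residual before rounding/clipping.
#' @param n_pictures Unique pictures per category rated by each subject.
#' @param activation_gain BOLD amplitude (% signal change) added to the
#'   planted spider-responsive region per unit of spider-fear trait.
#' @param bat_noise_sd SD of the latent avoidance noise in the behavioral
#'   approach test.
#' @param age_range Length-2 integer, uniform age range in years.
#' @param seed Integer seed; required by [generate_cohort()].
#'
#' @return An object of class `effect_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
effect_config <- function(n_phobic = 30L,
                          n_control = 32L,
                          trait_means = c(phobic = 2.5, control = 0),
                          trait_sd = 0.5,
                          snake_trait_corr = 0.3,
                          disgust_trait_corr = 0.4,
                          snake_trait_cap = 2,
                          rating_mu = c(tarantula = 2, daddy_long_legs = 1.8,
                                        beetle = 1.8, leaves = 1.2,
                                        snake = 2.5, lizard = 1.6),
                          rating_weights = c(tarantula = 1.7,
                                             daddy_long_legs = 1.0,
                                             beetle = 0, leaves = 0,
                                             snake = 0, lizard = 0),
                          rating_snake_weights = c(tarantula = 0,
                                                   daddy_long_legs = 0,
                                                   beetle = 0, leaves = 0,
                                                   snake = 1.2, lizard = 0.6),
                          rating_noise_sd = 1,
                          n_pictures = 40L,
                          activation_gain = 0.5,
                          bat_noise_sd = 0.8,
                          age_range = c(18L, 66L),
                          seed = NULL) {
  cats <- fear_categories()
  align <- function(x, what) {
    if (is.null(names(x)) && length(x) == length(cats)) names(x) <- cats
    if (!all(cats %in% names(x)))
      stop(sprintf("'%s' must be named by the six stimulus categories", what))
    x[cats]
  }
  cfg <- list(
    n_phobic = as.integer(n_phobic), n_control = as.integer(n_control),
    trait_means = trait_means, trait_sd = trait_sd,
    snake_trait_corr = snake_trait_corr,
    disgust_trait_corr = disgust_trait_corr,
    snake_trait_cap = snake_trait_cap,
    rating_mu = align(rating_mu, "rating_mu"),
    rating_weights = align(rating_weights, "rating_weights"),
    rating_snake_weights = align(rating_snake_weights, "rating_snake_weights"),
    rating_noise_sd = rating_noise_sd,
    n_pictures = as.integer(n_pictures),
    activation_gain = activation_gain,
    bat_noise_sd = bat_noise_sd,
    age_range = age_range,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  if (cfg$n_phobic < 2L || cfg$n_control < 2L)
    stop("group sizes must be at least 2")
  if (length(cfg$trait_means) != 2L)
    stop("'trait_means' must have length 2 (phobic, control)")
  if (!is.finite(cfg$trait_sd) || cfg$trait_sd <= 0)
    stop("'trait_sd' must be positive")
  for (r in c(cfg$snake_trait_corr, cfg$disgust_trait_corr))
    if (abs(r) > 1) stop("trait correlations must lie in [-1, 1]")
  if (cfg$rating_noise_sd < 0) stop("'rating_noise_sd' must be non-negative")
  if (cfg$n_pictures < 1L) stop("'n_pictures' must be positive")
  class(cfg) <- "effect_config"
  cfg
}

# Item-response constants: logistic discrimination and evenly spaced item
# difficulties, calibrated against the published group-mean totals
# (SPQ ~21.7 vs ~1.6; SNAQ overall mean ~2.7 under the cap).
.spq_disc <- 2.2
.spq_diff <- function() seq(0.5, 3.2, length.out = 31L)
.snaq_disc <- 1.5
.snaq_diff <- function() seq(1.2, 4.0, length.out = 30L)
.dsr_loading <- 0.8
.dsr_noise_sd <- 0.8
.dsr_base <- function() {
  b <- seq(0.5, 2.5, length.out = 27L)
  b[c(1L, 6L, 10L)] <- 2.5  # reversed items start high, decrease with trait
  b
}
# BAT step thresholds on the latent avoidance scale, one per step; they
# decrease because later steps (open terrarium, touch) demand lower
# avoidance.  Calibrated to group means ~4.6 (phobic) and ~6.8 (control)
# with a bimodal phobic split around "uncover and look" vs "touch".
.bat_thresholds <- c(5.5, 5.0, 4.5, 3.0, 2.4, 2.0, 1.0)
# steep link so that, per the sampling frame, controls essentially always
# answer no to every question and phobics nearly always reach >= 5 yes
.interview_disc <- 9
.interview_diff <- 1.4

#' Generate a seeded synthetic cohort
#'
#' Draws a phobic/control cohort whose observed measures carry the
#' statistical structure the downstream analyses assume: a latent
#' spider-fear trait separates the groups and monotonically drives SPQ item
#' endorsement, interview answers, picture fear ratings of spider stimuli,
#' and (negatively) behavioral approach; correlated snake-fear and disgust
#' traits drive SNAQ and DS-R.
#'
#' All sampling happens under `config$seed`, so repeated calls with the same
#' configuration return identical cohorts.
#'
#' @param config An [effect_config()]; `config$seed` must be set.
#' @return An object of class `fear_cohort`: a list with
#'   \describe{
#'     \item{info}{data frame: `id`, `group`, `age`, the three latent
#'       traits, and `bat_steps`.}
#'     \item{spq, snaq, interview}{logical response matrices
#'       (n x 31, n x 30, n x 6).}
#'     \item{dsr}{integer response matrix (n x 27, values 0--4).}
#'     \item{ratings}{integer array n x 6 categories x pictures, values 1--7.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cohort <- generate_cohort(effect_config(seed = 1))
#' cohort
#' @export
generate_cohort <- function(config = effect_config(seed = 1)) {
  stopifnot(inherits(config, "effect_config"))
  if (is.null(config$seed)) stop("config$seed is required for reproducibility")
  set.seed(config$seed)

  np <- config$n_phobic; nc <- config$n_control; n <- np + nc
  group <- factor(rep(c("phobic", "control"), c(np, nc)),
                  levels = c("phobic", "control"))
  id <- sprintf("S%03d", seq_len(n))
  age <- as.integer(round(stats::runif(n, config$age_range[1], config$age_range[2])))

  mu <- config$trait_means[as.integer(group)]
  spider <- stats::rnorm(n, mu, config$trait_sd)
  rho_s <- config$snake_trait_corr
  snake <- rho_s * spider +
    sqrt(1 - rho_s^2) * stats::rnorm(n, 0, config$trait_sd)
  snake <- pmin(snake, config$snake_trait_cap)
  rho_d <- config$disgust_trait_corr
  disgust <- rho_d * spider +
    sqrt(1 - rho_d^2) * stats::rnorm(n, 0, config$trait_sd)

  # binary questionnaires: P(fearful-direction answer) is logistic in the
  # trait; observed response flips on reverse-keyed items (default key 1:9)
  draw_binary <- function(trait, disc, diff, reversed) {
    p <- plogis(disc * outer(trait, diff, "-"))
    fearful <- matrix(stats::runif(length(p)) < p, nrow = length(trait))
    fearful[, reversed] <- !fearful[, reversed]
    fearful
  }
  spq <- draw_binary(spider, .spq_disc, .spq_diff(), 1:9)
  snaq <- draw_binary(snake, .snaq_disc, .snaq_diff(), 1:9)
  # enforce the SNAQ <= 17 screening rule: redraw offending subjects' items
  snaq_key_ <- snaq_key()
  for (i in seq_len(n)) {
    tries <- 0L
    while (score_binary_questionnaire(snaq[i, ], snaq_key_)$total > 17L &&
           tries < 50L) {
      snaq[i, ] <- draw_binary(snake[i], .snaq_disc, .snaq_diff(), 1:9)
      tries <- tries + 1L
    }
  }

  # DS-R: ordinal 0-4 responses; reversed items (1, 6, 10) decrease with the
  # disgust trait; catch items (12, 16) get the keyed attention value 0
  base <- .dsr_base()
  sgn <- rep(1, 27L); sgn[c(1L, 6L, 10L)] <- -1
  latent <- outer(disgust, sgn * .dsr_loading) +
    matrix(base, n, 27L, byrow = TRUE) +
    matrix(stats::rnorm(n * 27L, 0, .dsr_noise_sd), n, 27L)
  dsr <- matrix(as.integer(pmin(pmax(round(latent), 0), 4)), n, 27L)
  dsr[, c(12L, 16L)] <- 0L

  avoid <- spider + stats::rnorm(n, 0, config$bat_noise_sd)
  bat_steps <- as.integer(rowSums(outer(avoid, .bat_thresholds, "<")))

  p_int <- plogis(.interview_disc * (spider - .interview_diff))
  interview <- matrix(stats::runif(n * 6L) < rep(p_int, 6L), n, 6L)

  ratings <- .draw_ratings(spider, snake, config)

  info <- data.frame(id = id, group = group, age = age,
                     spider_trait = spider, snake_trait = snake,
                     disgust_trait = disgust, bat_steps = bat_steps,
                     stringsAsFactors = FALSE)
  structure(list(info = info, spq = spq, snaq = snaq, dsr = dsr,
                 interview = interview, ratings = ratings, config = config),
            class = "fear_cohort")
}

# vectorized rating model shared by generate_cohort and generate_ratings
.draw_ratings <- function(spider, snake, config) {
  n <- length(spider); npix <- config$n_pictures
  cats <- fear_categories()
  out <- array(NA_integer_, dim = c(n, length(cats), npix),
               dimnames = list(NULL, cats, NULL))
  for (k in seq_along(cats)) {
    m <- config$rating_mu[k] +
      config$rating_weights[k] * spider +
      config$rating_snake_weights[k] * snake
    eps <- matrix(stats::rnorm(n * npix, 0, config$rating_noise_sd), n, npix)
    out[, k, ] <- as.integer(pmin(pmax(round(m + eps), 1), 7))
  }
  out
}

#' Draw per-stimulus fear ratings for one subject
#'
#' Rating of picture `j` in category `c` is
#' `round(clip(mu_c + w_c * spider_trait + w'_c * snake_trait + eps, 1, 7))`,
#' where spider categories load on the spider-fear trait, snake and lizard
#' categories on the snake-fear trait, and leaves/beetles on neither (by
#' default).
#'
#' @param subject A list (or one-row data frame) with `spider_trait` and
#'   `snake_trait`.
#' @param config An [effect_config()].
#' @return Integer matrix, categories x pictures, values in 1--7.
#' @export
generate_ratings <- function(subject, config = effect_config(seed = 1)) {
  stopifnot(inherits(config, "effect_config"))
  if (is.null(subject$spider_trait) || is.null(subject$snake_trait))
    stop("'subject' must carry spider_trait and snake_trait")
  r <- .draw_ratings(subject$spider_trait[1], subject$snake_trait[1], config)
  matrix(r[1, , ], nrow = length(fear_categories()),
         dimnames = list(fear_categories(), NULL))
}

#' @export
print.fear_cohort <- function(x, ...) {
  tab <- table(x$info$group)
  cat(sprintf("Synthetic spider-fear cohort: %d subjects (%d phobic, %d control)\n",
              nrow(x$info), tab[["phobic"]], tab[["control"]]))
  cat(sprintf("Ratings: %d categories x %d pictures; seed %d\n",
              dim(x$ratings)[2], dim(x$ratings)[3], x$config$seed))
  invisible(x)
}

#' Score a cohort into an analysis table
#'
#' Applies the standard scoring rules to every subject and returns one row
#' per subject with questionnaire totals, BAT score, interview
#' classification, and per-category mean fear scores.
#'
#' @param cohort A `fear_cohort`.
#' @return Data frame with columns `id`, `group`, `age`, `spq`, `snaq`,
#'   `dsr`, `dsr_valid`, `bat`, `interview_positive`,
#'   `interview_class`, and `fs_<category>` mean fear scores.
#' @export
score_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "fear_cohort"))
  n <- nrow(cohort$info)
  kspq <- spq_key(); ksnaq <- snaq_key(); kdsr <- dsr_key()
  spq <- vapply(seq_len(n), function(i)
    score_binary_questionnaire(cohort$spq[i, ], kspq)$total, integer(1))
  snaq <- vapply(seq_len(n), function(i)
    score_binary_questionnaire(cohort$snaq[i, ], ksnaq)$total, integer(1))
  dsr_res <- lapply(seq_len(n), function(i) score_dsr(cohort$dsr[i, ], kdsr))
  pos <- rowSums(cohort$interview)
  fs <- apply(cohort$ratings, c(1, 2), mean)
  colnames(fs) <- paste0("fs_", colnames(fs))
  out <- data.frame(cohort$info[c("id", "group", "age")],
                    spq = spq, snaq = snaq,
                    dsr = vapply(dsr_res, `[[`, integer(1), "total"),
                    dsr_valid = vapply(dsr_res, `[[`, logical(1), "valid"),
                    bat = cohort$info$bat_steps,
                    interview_positive = as.integer(pos),
                    interview_class = vapply(seq_len(n), function(i)
                      classify_interview(cohort$interview[i, ]), character(1)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fs))
}

#' Write a cohort to plain-text files
#'
#' Serializes the scored cohort (wide CSV, one row per subject with item
#' responses in wide columns), the long-format ratings CSV, and a JSON
#' sidecar with the generating configuration.
#'
#' @param cohort A `fear_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fear_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- cbind(score_cohort(cohort),
                as.data.frame(cohort$spq * 1L) |>
                  stats::setNames(paste0("spq_item", 1:31)),
                as.data.frame(cohort$snaq * 1L) |>
                  stats::setNames(paste0("snaq_item", 1:30)),
                as.data.frame(cohort$dsr) |>
                  stats::setNames(paste0("dsr_item", 1:27)))
  f1 <- file.path(dir, "cohort.csv")
  utils::write.csv(wide, f1, row.names = FALSE)
  d <- dim(cohort$ratings)
  long <- data.frame(
    id = rep(cohort$info$id, times = d[2] * d[3]),
    category = rep(rep(colnames(cohort$ratings), each = d[1]), times = d[3]),
    picture = rep(seq_len(d[3]), each = d[1] * d[2]),
    rating = as.vector(cohort$ratings))
  f2 <- file.path(dir, "ratings.csv")
  utils::write.csv(long, f2, row.names = FALSE)
  f3 <- file.path(dir, "config.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(cohort$config), f3, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    f3 <- NULL
  }
  invisible(c(f1, f2, f3))
}
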