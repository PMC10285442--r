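#' Define a data-driven region of interest under FWE control
#'
#' Selects the voxels whose group-level spider>beetle activation survives
#' one-sided family-wise error control at level `alpha`.  Two corrections
#' are offered: Bonferroni (`p < alpha / n_valid_voxels`, exactly
#' reproducible) and a sign-flipping max-t permutation threshold (the
#' closer analogue of the max-statistic FWE used by standard fMRI
#' packages), which requires the per-subject maps.  Testing is one-sided
#' because the quantity of interest is an activation increase.  Voxels
#' with non-finite group t-values (zero-variance sentinels) are excluded
#' from candidacy.
#'
#' @param group_map A [group_onesample_tmap()] `stat_map`.
#' @param alpha Family-wise error level.
#' @param method `"bonferroni"` or `"max_t_permutation"`.
#' @param subject_maps For the permutation method: the list of per-subject
#'   maps the group map was built from.
#' @param use Statistic entering the permuted group test (see
#'   [group_onesample_tmap()]).
#' @param n_perm Number of sign-flip permutations.
#' @param seed Seed for the permutation draw.
#' @return Object of class `roi_mask`: logical array `mask`, `n_voxels`,
#'   `alpha`, `method`, `source_contrast`.
#' @export
define_roi <- function(group_map, alpha = 0.05,
                       method = c("bonferroni", "max_t_permutation"),
                       subject_maps = NULL, use = c("effect", "t"),
                       n_perm = 999L, seed = 1L) {
  stopifnot(inherits(group_map, "stat_map"))
  method <- match.arg(method)
  use <- match.arg(use)
  tv <- group_map$tvalues
  valid <- is.finite(tv)
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("no valid voxels in the group map")
  mask <- array(FALSE, dim(tv))
  if (method == "bonferroni") {
    pv <- stats::pt(tv[valid], df = group_map$df, lower.tail = FALSE)
    mask[valid] <- pv < alpha / n_valid
  } else {
    if (is.null(subject_maps))
      stop("'subject_maps' are required for the max-t permutation method")
    vals <- vapply(subject_maps, function(m)
      as.vector(if (use == "effect") m$effect else m$tvalues),
      numeric(length(tv)))
    n <- ncol(vals)
    set.seed(as.integer(seed))
    vvalid <- vals[as.vector(valid), , drop = FALSE]
    maxt <- vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      fl <- sweep(vvalid, 2, flips, "*")
      m <- rowMeans(fl)
      s <- sqrt(rowSums((fl - m)^2) / (n - 1))
      max(ifelse(s > 0, m / (s / sqrt(n)), -Inf))
    }, numeric(1))
    thr <- stats::quantile(maxt, 1 - alpha, names = FALSE, type = 8)
    mask[valid] <- tv[valid] > thr
  }
  structure(list(mask = mask, n_voxels = sum(mask), alpha = alpha,
                 method = method, source_contrast = group_map$contrast_name),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask (%s, FWE alpha = %g) from '%s': %d voxels\n",
              x$method, x$alpha, x$source_contrast, x$n_voxels))
  invisible(x)
}

#' Compute the Spider Fear Index for one subject
#'
#' The SFI is the arithmetic mean of the subject's first-level
#' spider>beetle t-statistics over a predefined region of interest; the
#' region must come from a session independent of the map being averaged.
#' It is dimensionless and may be negative.  An empty region is an error
#' (the index is undefined without a mask), not a silent zero.
#'
#' @param subject_tmap First-level `stat_map` from the spider session.
#' @param roi A [define_roi()] mask on the same grid.
#' @param statistic Average the t-values (default, the index definition)
#'   or the contrast estimates (`"effect"`, for sensitivity analysis).
#' @return One-row data frame: `subject_id`, `sfi`, `n_roi_voxels`.
#' @export
compute_sfi <- function(subject_tmap, roi, statistic = c("t", "effect")) {
  stopifnot(inherits(subject_tmap, "stat_map"), inherits(roi, "roi_mask"))
  statistic <- match.arg(statistic)
  if (!all(dim(subject_tmap$tvalues) == dim(roi$mask)))
    stop("subject map and ROI are on different grids")
  if (roi$n_voxels == 0L)
    stop("empty ROI: the defining contrast found no significant voxels")
  vals <- if (statistic == "t") subject_tmap$tvalues[roi$mask]
  else subject_tmap$effect[roi$mask]
  data.frame(subject_id = subject_tmap$subject_id,
             sfi = mean(vals), n_roi_voxels = roi$n_voxels,
             stringsAsFactors = FALSE)
}

#' Run the full Spider Fear Index pipeline on a cohort
#'
#' For every subject, two block-design sessions are simulated and fitted
#' voxelwise.  The region of interest is defined from the *fear* session
#' only, by default from the phobic group only (one-sample group test of
#' the spider>beetle contrast, FWE-corrected); the SFI is then the mean
#' first-level t-statistic of the same contrast in the independent
#' *spider* session, inside that region.  Subjects listed in `exclude`
#' are dropped before both the mask definition and the index computation
#' (the hook for data-quality exclusions).
#'
#' @param cohort A [generate_cohort()] object.
#' @param spec A [brain_spec()].
#' @param blocks_per_condition Blocks per category per session.
#' @param alpha,method FWE settings passed to [define_roi()].
#' @param roi_group `"phobic"` (default) or `"all"`: subjects entering the
#'   mask definition.
#' @param group_use Statistic entering the group test (see
#'   [group_onesample_tmap()]).
#' @param statistic Subject-level quantity averaged into the index.
#' @param exclude Character vector of subject ids to drop.
#' @param seed Base seed for session orders and subject noise; defaults to
#'   the cohort's generating seed.
#' @return Object of class `sfi_table`: data frame with `subject_id`,
#'   `group`, `sfi`, `n_roi_voxels`, plus attributes `roi` (the mask),
#'   `group_map`, and `sessions`.
#' @export
sfi_pipeline <- function(cohort, spec = brain_spec(),
                         blocks_per_condition = 8L,
                         alpha = 0.05, method = "bonferroni",
                         roi_group = c("phobic", "all"),
                         group_use = "effect", statistic = "t",
                         exclude = character(0), seed = NULL) {
  stopifnot(inherits(cohort, "fear_cohort"))
  roi_group <- match.arg(roi_group)
  config <- cohort$config
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)

  fear_sess <- build_session("fear", blocks_per_condition, seed = seed + 101L)
  spider_sess <- build_session("spider", blocks_per_condition, seed = seed + 102L)
  fear_X <- build_design_matrix(fear_sess)
  spider_X <- build_design_matrix(spider_sess)
  contrast <- c(tarantula = 1, beetle = -1)

  info <- cohort$info
  keep <- !(info$id %in% exclude)
  first_level <- function(i, sess, dm, seed_off) {
    subj <- info[i, ]
    series <- simulate_bold(subj, sess, spec, config, seed = seed + seed_off + i,
                            design = dm)
    if (spec$smooth_fwhm_mm > 0)
      series <- smooth_volumes(series, spec$smooth_fwhm_mm, spec$voxel_size_mm)
    contrast_tmap(fit_glm(series, dm), contrast, name = "spider>beetle")
  }

  idx <- which(keep)
  fear_maps <- lapply(idx, first_level, sess = fear_sess, dm = fear_X,
                      seed_off = 1000L)
  names(fear_maps) <- info$id[idx]
  roi_idx <- if (roi_group == "phobic") which(keep & info$group == "phobic") else idx
  group_map <- group_onesample_tmap(fear_maps[info$id[roi_idx]], use = group_use,
                                    name = "group:spider>beetle (fear session)")
  roi <- define_roi(group_map, alpha = alpha, method = method,
                    subject_maps = fear_maps[info$id[roi_idx]],
                    seed = seed + 7L)
  if (roi$n_voxels == 0L)
    stop("empty ROI: no voxel survived FWE correction in the fear session")

  spider_maps <- lapply(idx, first_level, sess = spider_sess, dm = spider_X,
                        seed_off = 2000L)
  recs <- do.call(rbind, lapply(spider_maps, compute_sfi, roi = roi,
                                statistic = statistic))
  out <- data.frame(subject_id = info$id[idx], group = info$group[idx],
                    sfi = recs$sfi, n_roi_voxels = recs$n_roi_voxels,
                    stringsAsFactors = FALSE)
  structure(out, roi = roi, group_map = group_map,
            sessions = list(fear = fear_sess, spider = spider_sess),
            class = c("sfi_table", "data.frame"))
}

#' @export
print.sfi_table <- function(x, ...) {
  roi <- attr(x, "roi")
  cat(sprintf("Spider Fear Index table: %d subjects, ROI of %d voxels (%s)\n",
              nrow(x), roi$n_voxels, roi$method))
  means <- tapply(x$sfi, x$group, mean)
  cat(sprintf("mean SFI: phobic %.3f, control %.3f\n",
              means[["phobic"]], means[["control"]]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
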