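#' Fit the voxelwise general linear model
#'
#' Ordinary least squares per voxel against a shared design:
#' `beta = (X'X)^{-1} X'y`, `sigma2 = RSS / df` with
#' `df = n_volumes - rank(X)`.  First-level autocorrelation is not
#' pre-whitened; the residual degrees of freedom are unadjusted (a
#' documented simplification).
#'
#' @param series A [simulate_bold()] `volume_series`.
#' @param design A [build_design_matrix()] object.
#' @return Object of class `glm_fit`: `betas` (regressors x voxels),
#'   `sigma2`, `df`, `xtx_inv`, the grid dimensions, and the design.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(series, "volume_series"), inherits(design, "design_matrix"))
  d <- dim(series$data)
  nt <- d[4]
  X <- design$X
  if (nrow(X) != nt)
    stop(sprintf("design has %d rows but series has %d volumes", nrow(X), nt))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  Y <- t(matrix(series$data, prod(d[1:3]), nt))  # time x voxels
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  df <- nt - qrX$rank
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(resid^2) / df
  R <- qr.R(qrX)
  xtx_inv <- chol2inv(R)[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  structure(list(betas = B, sigma2 = sigma2, df = df, xtx_inv = xtx_inv,
                 grid_dims = d[1:3], design = design,
                 subject_id = series$subject_id),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Voxelwise GLM fit: %d voxels, %d regressors, df = %d\n",
              ncol(x$betas), nrow(x$betas), x$df))
  invisible(x)
}

#' Contrast t-map from a voxelwise GLM fit
#'
#' For contrast weights `c`,
#' `t_v = c'beta_v / sqrt(sigma2_v * c'(X'X)^{-1}c)`.  Voxels with zero
#' residual variance get `t = 0` when the contrast estimate is also zero
#' and `+/-Inf` otherwise; infinite values are treated as invalid by
#' downstream ROI selection.
#'
#' @param fit A [fit_glm()] object.
#' @param contrast Numeric weight vector.  Either full length (one weight
#'   per regressor) or one weight per condition regressor (zero-padded for
#'   intercept/drift).  A named vector like `c(tarantula = 1, beetle = -1)`
#'   is also accepted.
#' @param name Label for the contrast.
#' @return Object of class `stat_map` with `tvalues` and `effect`
#'   (contrast estimates) as 3-D arrays, `df`, and `contrast_name`.
#' @export
contrast_tmap <- function(fit, contrast, name = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$betas)
  rn <- fit$design$regressor_names
  if (!is.null(names(contrast))) {
    cv <- stats::setNames(rep(0, p), rn)
    if (!all(names(contrast) %in% rn)) stop("unknown regressor in contrast names")
    cv[names(contrast)] <- contrast
    contrast <- cv
  } else if (length(contrast) == length(fit$design$condition_cols) &&
             length(contrast) < p) {
    cv <- rep(0, p)
    cv[fit$design$condition_cols] <- contrast
    contrast <- cv
  }
  if (length(contrast) != p)
    stop(sprintf("contrast length %d does not match %d regressors",
                 length(contrast), p))
  if (all(contrast == 0)) stop("contrast vector is all zero")
  eff <- drop(crossprod(contrast, fit$betas))
  cvc <- drop(t(contrast) %*% fit$xtx_inv %*% contrast)
  se <- sqrt(fit$sigma2 * cvc)
  tv <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, sign(eff) * Inf))
  if (is.null(name)) name <- paste(deparse(substitute(contrast)), collapse = "")
  structure(list(tvalues = array(tv, fit$grid_dims),
                 effect = array(eff, fit$grid_dims),
                 df = fit$df, contrast_name = name,
                 subject_id = fit$subject_id),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  fin <- x$tvalues[is.finite(x$tvalues)]
  cat(sprintf("Stat map '%s' (df = %d): t in [%.2f, %.2f], %d voxels\n",
              x$contrast_name, x$df, min(fin), max(fin), length(x$tvalues)))
  invisible(x)
}

#' Group-level one-sample t-map
#'
#' Per voxel, a one-sample t-test of the subject-level contrast statistics
#' against zero, with `df = n_subjects - 1`.  The statistic entering the
#' group test is the subject contrast estimate (`use = "effect"`, the
#' default) or the subject t-value (`use = "t"`).  Voxels where all
#' subjects agree exactly (zero between-subject variance) yield `t = 0`
#' for a zero mean and `+/-Inf` otherwise, and infinite values are
#' excluded from ROI candidacy downstream.
#'
#' @param maps List of per-subject `stat_map`s on identical grids.
#' @param use `"effect"` or `"t"`.
#' @param name Label for the resulting map.
#' @return A `stat_map` (its `effect` field holds the voxel means).
#' @export
group_onesample_tmap <- function(maps, use = c("effect", "t"), name = NULL) {
  use <- match.arg(use)
  if (length(maps) < 2L) stop("at least 2 subject maps are required")
  dims <- dim(maps[[1]]$tvalues)
  vals <- vapply(maps, function(m) {
    stopifnot(inherits(m, "stat_map"))
    if (!all(dim(m$tvalues) == dims)) stop("subject maps are on different grids")
    as.vector(if (use == "effect") m$effect else m$tvalues)
  }, numeric(prod(dims)))
  n <- ncol(vals)
  m <- rowMeans(vals)
  s <- sqrt(rowSums((vals - m)^2) / (n - 1))
  tv <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
  if (is.null(name))
    name <- paste0("group:", maps[[1]]$contrast_name)
  structure(list(tvalues = array(tv, dims), effect = array(m, dims),
                 df = n - 1L, contrast_name = name, subject_id = NA_character_),
            class = "stat_map")
}
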