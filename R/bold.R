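#' Specification of the simulated brain
#'
#' Describes the voxel grid, the ground-truth spider-responsive region, the
#' per-condition response amplitudes, and the noise model used by
#' [simulate_bold()].  The default grid is deliberately small (12 x 12 x 12
#' voxels of 3 mm) so that a full two-session, 61-subject experiment runs
#' in minutes.
#'
#' @param grid_dims Integer length-3, voxels per axis.
#' @param voxel_size_mm Isotropic voxel size.
#' @param true_roi Ground-truth responsive region: either a logical array
#'   of `grid_dims`, or an integer matrix of voxel coordinates (rows =
#'   voxels, columns = x, y, z).  Default: the central 3 x 3 x 3 cube.
#' @param baseline_amplitudes List with elements `outside` and `inside`:
#'   percent-signal-change response per condition.  Each may be a single
#'   number (all conditions) or a named vector; `inside` entries override
#'   `outside` for voxels in the true region.  The default gives every
#'   condition a 0.5 visual response everywhere and the spider condition an
#'   extra 0.2 baseline inside the region.
#' @param roi_condition Condition whose amplitude scales with the
#'   subject's spider-fear trait inside the region.
#' @param noise_sd Marginal SD of the AR(1) voxel noise.
#' @param ar1_coef Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param smooth_fwhm_mm Spatial smoothing applied by the pipeline (0 =
#'   none, the default; 8 mm mirrors conventional preprocessing).
#' @return Object of class `brain_spec`.
#' @export
brain_spec <- function(grid_dims = c(12L, 12L, 12L), voxel_size_mm = 3,
                       true_roi = NULL,
                       baseline_amplitudes = list(outside = 0.5,
                                                  inside = c(tarantula = 0.7)),
                       roi_condition = "tarantula",
                       noise_sd = 1, ar1_coef = 0.3,
                       smooth_fwhm_mm = 0) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L))
  if (is.null(true_roi)) {
    mid <- pmax(1L, grid_dims %/% 2L)
    rng <- function(m, d) max(1L, m - 1L):min(d, m + 1L)
    true_roi <- as.matrix(expand.grid(rng(mid[1], grid_dims[1]),
                                      rng(mid[2], grid_dims[2]),
                                      rng(mid[3], grid_dims[3])))
  }
  if (is.array(true_roi) && is.logical(true_roi)) {
    stopifnot(all(dim(true_roi) == grid_dims))
    true_roi <- which(true_roi, arr.ind = TRUE)
  }
  true_roi <- unname(as.matrix(true_roi))
  if (nrow(true_roi) == 0L) stop("'true_roi' must be non-empty")
  if (ncol(true_roi) != 3L) stop("'true_roi' must have 3 coordinate columns")
  if (any(true_roi < 1L) || any(sweep(true_roi, 2, grid_dims, ">")))
    stop("'true_roi' voxels fall outside the grid")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("'ar1_coef' must lie in [0, 1)")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (smooth_fwhm_mm < 0) stop("'smooth_fwhm_mm' must be non-negative")
  structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                 true_roi = true_roi,
                 baseline_amplitudes = baseline_amplitudes,
                 roi_condition = roi_condition,
                 noise_sd = noise_sd, ar1_coef = ar1_coef,
                 smooth_fwhm_mm = smooth_fwhm_mm),
            class = "brain_spec")
}

.roi_linear_index <- function(spec) {
  d <- spec$grid_dims
  r <- spec$true_roi
  r[, 1] + (r[, 2] - 1L) * d[1] + (r[, 3] - 1L) * d[1] * d[2]
}

# per-condition amplitude vectors inside/outside the true region
.condition_betas <- function(spec, conds) {
  resolve <- function(x, base) {
    if (is.null(x)) return(base)
    if (is.null(names(x))) return(rep(x[1], length(conds)))
    hit <- conds %in% names(x)
    base[hit] <- x[conds[hit]]
    base
  }
  outside <- resolve(spec$baseline_amplitudes$outside, rep(0, length(conds)))
  inside <- resolve(spec$baseline_amplitudes$inside, outside)
  list(outside = stats::setNames(outside, conds),
       inside = stats::setNames(inside, conds))
}

#' Simulate a 4-D BOLD series for one subject
#'
#' The signal at voxel `v` and volume `t` is the design-matrix linear
#' combination `sum_c beta[v, c] * X[t, c]` over condition regressors plus
#' stationary AR(1) Gaussian noise.  For voxels in the ground-truth region
#' the amplitude of the spider condition is
#' `inside_baseline + activation_gain * spider_trait`; all other betas sit
#' at their baselines.  The series is bitwise reproducible for a fixed
#' `seed`.
#'
#' @param subject List or one-row data frame with `spider_trait` (and
#'   optionally `id`).
#' @param session A [build_session()] design.
#' @param spec A [brain_spec()].
#' @param config An [effect_config()]; supplies `activation_gain`.
#' @param seed Integer seed for the noise.
#' @param design Optional precomputed [build_design_matrix()] for
#'   `session` (saves recomputation across subjects).
#' @return Object of class `volume_series`: list with `data`
#'   (x, y, z, time array), `tr_s`, and `subject_id`.
#' @export
simulate_bold <- function(subject, session, spec = brain_spec(),
                          config = effect_config(seed = 1), seed = 1L,
                          design = NULL) {
  stopifnot(inherits(session, "session_design"), inherits(spec, "brain_spec"))
  if (is.null(design)) design <- build_design_matrix(session, drift_order = 0L)
  conds <- session$conditions
  Xc <- design$X[, design$condition_cols, drop = FALSE]
  amp <- .condition_betas(spec, conds)
  d <- spec$grid_dims
  nv <- prod(d)
  nt <- session$n_volumes

  B <- matrix(rep(amp$outside, each = nv), nv, length(conds))
  roi <- .roi_linear_index(spec)
  B[roi, ] <- matrix(rep(amp$inside, each = length(roi)),
                     length(roi), length(conds))
  k <- match(spec$roi_condition, conds)
  if (is.na(k)) stop("spec$roi_condition not among session conditions")
  B[roi, k] <- B[roi, k] + config$activation_gain * subject$spider_trait[1]

  signal <- B %*% t(Xc)  # voxels x time

  set.seed(as.integer(seed))
  phi <- spec$ar1_coef
  sd <- spec$noise_sd
  E <- matrix(0, nv, nt)
  if (sd > 0) {
    E[, 1] <- stats::rnorm(nv, 0, sd)
    innov_sd <- sd * sqrt(1 - phi^2)
    W <- matrix(stats::rnorm(nv * (nt - 1), 0, innov_sd), nv, nt - 1)
    for (t in 2:nt) E[, t] <- phi * E[, t - 1] + W[, t - 1]
  }
  structure(list(data = array(signal + E, dim = c(d, nt)),
                 tr_s = session$tr_s,
                 subject_id = if (!is.null(subject$id)) subject$id[1] else NA_character_),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD series %s: %d x %d x %d voxels, %d volumes (TR %.2g s)\n",
              if (is.na(x$subject_id)) "" else x$subject_id,
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

# 1-D Gaussian convolution matrix with mirrored (edge-duplicating)
# boundaries; rows and columns both sum to 1, so constants and total mass
# are preserved exactly.
.gauss_conv_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- stats::dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      if (j < 1L) j <- 1L - j  # reflect with edge duplication: 0 -> 1, -1 -> 2
      if (j > n) j <- 2L * n - j + 1L
      j <- min(max(j, 1L), n)
      K[i, j] <- K[i, j] + w[o + r + 1L]
    }
  }
  K
}

#' Spatially smooth a volume series
#'
#' Per-volume separable 3-D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, mirrored at the grid
#' boundaries (which preserves total mass and leaves constant volumes
#' unchanged).  `fwhm_mm = 0` is the identity.
#'
#' @param series A `volume_series`.
#' @param fwhm_mm Full width at half maximum of the kernel, millimetres.
#' @param voxel_size_mm Voxel edge length used to convert to voxel units.
#' @return A smoothed `volume_series`.
#' @export
smooth_volumes <- function(series, fwhm_mm, voxel_size_mm = 3) {
  stopifnot(inherits(series, "volume_series"))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be non-negative")
  if (fwhm_mm == 0) return(series)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(series$data)
  x <- series$data
  for (ax in 1:3) {
    K <- .gauss_conv_matrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:4, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, dp[1], prod(dp[-1]))
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  series$data <- x
  series
}

#' Export a 3-D map or 4-D series to NIfTI-1
#'
#' Thin convenience wrapper around the `RNifti` package (optional
#' dependency).
#'
#' @param x A `volume_series`, `stat_map`, `roi_mask`, or plain array.
#' @param file Output path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, file, voxel_size_mm = 3) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("package 'RNifti' is required for NIfTI export")
  arr <- if (inherits(x, "volume_series")) x$data
  else if (inherits(x, "stat_map")) x$tvalues
  else if (inherits(x, "roi_mask")) x$mask * 1
  else x
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_size_mm, min(3, length(dim(arr)))))
  RNifti::writeNifti(img, file)
  invisible(file)
}
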