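#' Redundancy analysis (constrained ordination)
#'
#' RDA extracts the axes of the response matrix `Y` that are linear
#' combinations of the explanatory variables `X`: the columns of `Y` are
#' centred (optionally standardized), regressed on `X` by least squares,
#' and the fitted values are eigen-decomposed.  The constrained axes are
#' the principal axes of the fitted responses; the proportion of variance
#' explained is the ratio of the fitted to the total sum of squares.
#'
#' Scores follow the conventional triplot scalings: with the fitted SVD
#' `Yhat = U D V'` and eigenvalues `lambda_k = d_k^2 / (n - 1)`,
#' scaling 1 (distance) uses site scores `U D` and response loadings `V`;
#' scaling 2 (correlation) uses `U D^{1/2}` and `V D^{1/2}`.  Site scores
#' are the fitted-value ("lc") coordinates; `wa_scores` give the raw
#' response projections.  Biplot arrows are the correlations of the
#' explanatory variables with the lc site scores.
#'
#' @param Y Numeric response matrix (respondents x responses), no missing
#'   values.
#' @param X Explanatory variables: numeric matrix or data frame (factors
#'   are expanded to contrasts).
#' @param standardize Scale the columns of `Y` to unit variance before
#'   analysis.
#' @return Object of class `rda_fit`: `eigenvalues`, `prop_explained`,
#'   `constrained_axes` (response loadings `V`), `site_scores` (lc, raw
#'   scaling), `wa_scores`, `biplot_scores`, `total_variance`, `rank`, and
#'   the SVD components.
#' @seealso [rda_sequential_test()] for permutation tests of the terms.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(40), 8, 5)
#' X <- matrix(rnorm(24), 8, 3)
#' fit <- rda_fit(Y, X)
#' fit$prop_explained
#' @export
rda_fit <- function(Y, X, standardize = FALSE) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("'Y' must not contain missing values")
  if (is.data.frame(X)) X <- stats::model.matrix(~., X)[, -1, drop = FALSE]
  X <- as.matrix(X)
  if (anyNA(X)) stop("'X' must not contain missing values")
  n <- nrow(Y)
  if (nrow(X) != n) stop("'Y' and 'X' must have the same number of rows")
  Yc <- scale(Y, center = TRUE, scale = standardize)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc))
    warning(sprintf("rank-deficient X: %d of %d columns independent; redundant directions dropped",
                    qx$rank, ncol(Xc)))
  if (n <= qx$rank) stop("more predictors than free observations")
  Yhat <- qr.fitted(qx, Yc)
  sv <- svd(Yhat)
  tol <- max(dim(Yhat)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > max(tol, 1e-12))
  r <- min(r, qx$rank, ncol(Yc), n - 1L)
  if (r == 0L) {
    return(structure(list(eigenvalues = numeric(0), prop_explained = 0,
                          constrained_axes = NULL, site_scores = NULL,
                          wa_scores = NULL, biplot_scores = NULL,
                          total_variance = sum(Yc^2) / (n - 1), rank = 0L,
                          n = n, svd = NULL, standardize = standardize),
                     class = "rda_fit"))
  }
  d <- sv$d[seq_len(r)]
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  eig <- d^2 / (n - 1)
  total <- sum(Yc^2) / (n - 1)
  lc <- U %*% diag(d, r)
  axis_names <- paste0("RDA", seq_len(r))
  dimnames(lc) <- list(rownames(Y), axis_names)
  dimnames(V) <- list(colnames(Y), axis_names)
  wa <- Yc %*% V
  bip <- suppressWarnings(stats::cor(Xc, lc))
  bip[is.na(bip)] <- 0
  structure(list(eigenvalues = stats::setNames(eig, axis_names),
                 prop_explained = sum(eig) / total,
                 constrained_axes = V,
                 site_scores = lc, wa_scores = wa, biplot_scores = bip,
                 total_variance = total, rank = r, n = n,
                 svd = list(u = U, d = d, v = V),
                 standardize = standardize),
            class = "rda_fit")
}

#' Triplot scores of a redundancy analysis
#'
#' @param x An `rda_fit`.
#' @param choices Axes to return.
#' @param display `"sites"`, `"responses"`, or `"biplot"`.
#' @param scaling 1 (distance) or 2 (correlation); see [rda_fit()].
#' @return Numeric matrix of scores.
#' @export
rda_scores <- function(x, choices = 1:2,
                       display = c("sites", "responses", "biplot"),
                       scaling = 2) {
  display <- match.arg(display)
  choices <- choices[choices <= x$rank]
  d <- x$svd$d[choices]
  out <- switch(display,
    sites = if (scaling == 1) x$site_scores[, choices, drop = FALSE]
            else x$svd$u[, choices, drop = FALSE] %*% diag(sqrt(d), length(d)),
    responses = if (scaling == 1) x$svd$v[, choices, drop = FALSE]
                else x$svd$v[, choices, drop = FALSE] %*% diag(sqrt(d), length(d)),
    biplot = x$biplot_scores[, choices, drop = FALSE])
  out
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis\n")
  cat(sprintf("total variance %.4g; constrained %.4g (%.2f%%) on %d axes\n",
              x$total_variance, x$total_variance * x$prop_explained,
              100 * x$prop_explained, x$rank))
  cat("eigenvalues:\n")
  print(signif(x$eigenvalues, 4))
  invisible(x)
}

#' @export
summary.rda_fit <- function(object, ...) {
  print(object)
  cat("\nproportion per axis:\n")
  print(signif(object$eigenvalues / object$total_variance, 4))
  invisible(object)
}

# all hat matrices for cumulative term designs (intercept always included)
.cumulative_hats <- function(X_terms, n) {
  hats <- vector("list", length(X_terms) + 1L)
  ranks <- integer(length(X_terms) + 1L)
  hats[[1]] <- matrix(1 / n, n, n)
  ranks[1] <- 1L
  acc <- matrix(1, n, 1)
  for (k in seq_along(X_terms)) {
    acc <- cbind(acc, X_terms[[k]])
    qx <- qr(acc)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[k + 1L]] <- tcrossprod(Q)
    ranks[k + 1L] <- qx$rank
  }
  list(hats = hats, ranks = ranks)
}

#' Sequential (Type I) permutation tests for RDA terms
#'
#' Terms are added in the given order; each term's pseudo-F is the
#' variance it adds per degree of freedom over the residual variance of
#' the full model:
#' `F_k = (SS_k / df_k) / (SS_res / df_res)`.
#' Significance comes from a seeded permutation null.  The default scheme
#' permutes the residuals of the reduced model (the model with the terms
#' preceding `k`), i.e. `Y* = fitted_{k-1} + P residuals_{k-1}`; free
#' permutation of the response rows is available as an alternative.  The
#' reported p-value is `(1 + #[F* >= F]) / (1 + n_perm)`.
#'
#' @param Y Response matrix as in [rda_fit()].
#' @param X Data frame of explanatory variables; each column is one term.
#' @param term_order Optional character vector ordering the terms.
#' @param n_perm Number of permutations (at least 99).
#' @param seed Integer seed.
#' @param scheme `"reduced"` (reduced-model residual permutation, default)
#'   or `"free"` (permute response rows).
#' @param standardize Passed to the response centring as in [rda_fit()].
#' @return Object of class `rda_anova`: data frame with one row per term
#'   (`df`, `variance`, `F`, `p`) plus a residual row.
#' @export
rda_sequential_test <- function(Y, X, term_order = NULL, n_perm = 1999L,
                                seed = 1L, scheme = c("reduced", "free"),
                                standardize = FALSE) {
  scheme <- match.arg(scheme)
  if (n_perm < 99L) stop("'n_perm' must be at least 99")
  Y <- as.matrix(Y)
  if (!is.data.frame(X)) X <- as.data.frame(X)
  terms <- names(X)
  if (!is.null(term_order)) {
    if (!setequal(term_order, terms)) stop("'term_order' must name every term in X")
    terms <- term_order
  }
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = standardize)
  # sufficient reduction: traces of Y' A Y are invariant to replacing Y by
  # its left singular factor U D, which caps the column count at n
  svy <- svd(Yc, nv = 0)
  Ys <- svy$u %*% diag(svy$d, length(svy$d))

  X_terms <- lapply(terms, function(tm) {
    v <- X[[tm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) stats::model.matrix(~v)[, -1, drop = FALSE]
    else matrix(as.numeric(v), ncol = 1)
  })
  ch <- .cumulative_hats(X_terms, n)
  K <- length(terms)
  H_full <- ch$hats[[K + 1L]]
  df_res <- n - ch$ranks[K + 1L]
  if (df_res <= 0) stop("no residual degrees of freedom")
  R_full <- diag(n) - H_full
  ss <- function(A, Ymat) sum((A %*% Ymat) * Ymat)
  SS_res <- ss(R_full, Ys)

  set.seed(as.integer(seed))
  out <- data.frame(term = terms, df = NA_integer_, variance = NA_real_,
                    F = NA_real_, p = NA_real_)
  for (k in seq_len(K)) {
    Dk <- ch$hats[[k + 1L]] - ch$hats[[k]]
    df_k <- ch$ranks[k + 1L] - ch$ranks[k]
    if (df_k == 0L) stop(sprintf("term '%s' adds no independent information", terms[k]))
    SS_k <- ss(Dk, Ys)
    F_obs <- (SS_k / df_k) / (SS_res / df_res)
    H_red <- ch$hats[[k]]
    fit_red <- H_red %*% Ys
    res_red <- Ys - fit_red
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      Yp <- if (scheme == "reduced") fit_red + res_red[perm, , drop = FALSE]
            else Ys[perm, , drop = FALSE]
      F_b <- (ss(Dk, Yp) / df_k) / (ss(R_full, Yp) / df_res)
      if (F_b >= F_obs - 1e-12) exceed <- exceed + 1L
    }
    out$df[k] <- df_k
    out$variance[k] <- SS_k / (n - 1)
    out$F[k] <- F_obs
    out$p[k] <- (1 + exceed) / (1 + n_perm)
  }
  out <- rbind(out, data.frame(term = "Residual", df = df_res,
                               variance = SS_res / (n - 1),
                               F = NA_real_, p = NA_real_))
  structure(out, n_perm = n_perm, scheme = scheme,
            class = c("rda_anova", "data.frame"))
}

#' @export
print.rda_anova <- function(x, ...) {
  cat(sprintf("Sequential permutation tests (%d permutations, %s scheme)\n",
              attr(x, "n_perm"), attr(x, "scheme")))
  df <- as.data.frame(x)
  df$variance <- signif(df$variance, 4)
  df$F <- signif(df$F, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
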