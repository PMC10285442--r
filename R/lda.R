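#' Two-group linear discriminant classification
#'
#' Discriminant function analysis for two groups: a linear discriminant
#' with pooled within-group covariance assigns each subject to the group
#' with the larger discriminant score
#' `delta_g(x) = x'S^{-1}m_g - m_g'S^{-1}m_g / 2 + log(pi_g)`.
#' The confusion matrix is resubstitution (apparent) classification by
#' default; leave-one-out cross-validation is available.  Each variable's
#' strength as a discriminator is reported as its one-way ANOVA F
#' statistic (between over within group variance), the usual ranking of a
#' stepwise discriminant analysis.
#'
#' If the pooled covariance is numerically singular, a documented ridge
#' fallback (`S + eps * mean(diag(S)) * I`) is applied with a warning.
#'
#' @param features Numeric matrix or data frame (subjects x variables).
#' @param labels Factor (or vector) with exactly two levels; at least two
#'   subjects per group.
#' @param method `"resubstitution"` (default) or `"cv"` (leave-one-out).
#' @param prior `"proportions"` (group frequencies, default) or `"equal"`.
#' @return Object of class `lda_fit`: `confusion` (true x predicted
#'   counts), `percent_correct` (per group and `total`), `variable_tests`
#'   (per-variable F and p), `coefficients` (discriminant direction),
#'   `means`, and `predicted`.
#' @export
lda_classify <- function(features, labels,
                         method = c("resubstitution", "cv"),
                         prior = c("proportions", "equal")) {
  method <- match.arg(method)
  prior <- match.arg(prior)
  X <- as.matrix(as.data.frame(features))
  if (!is.numeric(X)) stop("'features' must be numeric")
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("at least 2 subjects per group are required")
  if (nrow(X) != length(g)) stop("features and labels disagree in length")

  fit_rule <- function(Xtr, gtr) {
    lev <- levels(gtr)
    n1 <- sum(gtr == lev[1]); n2 <- sum(gtr == lev[2])
    m1 <- colMeans(Xtr[gtr == lev[1], , drop = FALSE])
    m2 <- colMeans(Xtr[gtr == lev[2], , drop = FALSE])
    S <- ((n1 - 1) * stats::cov(Xtr[gtr == lev[1], , drop = FALSE]) +
          (n2 - 1) * stats::cov(Xtr[gtr == lev[2], , drop = FALSE])) /
      (n1 + n2 - 2)
    Sinv <- tryCatch(solve(S), error = function(e) {
      warning("singular pooled covariance; ridge regularization applied")
      solve(S + 1e-6 * mean(diag(S)) * diag(ncol(S)))
    })
    lp <- if (prior == "proportions") log(c(n1, n2) / (n1 + n2)) else c(0, 0)
    list(m = rbind(m1, m2), Sinv = Sinv, logprior = lp, lev = lev)
  }
  predict_rule <- function(rule, Xte) {
    sc <- sapply(1:2, function(k) {
      mk <- rule$m[k, ]
      drop(Xte %*% rule$Sinv %*% mk) -
        0.5 * drop(t(mk) %*% rule$Sinv %*% mk) + rule$logprior[k]
    })
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
    factor(rule$lev[max.col(sc, ties.method = "first")], levels = rule$lev)
  }

  rule <- fit_rule(X, g)
  predicted <- if (method == "resubstitution") {
    predict_rule(rule, X)
  } else {
    pr <- vapply(seq_len(nrow(X)), function(i) {
      r <- fit_rule(X[-i, , drop = FALSE], g[-i])
      as.character(predict_rule(r, X[i, , drop = FALSE]))
    }, character(1))
    factor(pr, levels = levels(g))
  }

  confusion <- table(true = g, predicted = predicted)
  per_group <- 100 * diag(confusion) / rowSums(confusion)
  pct <- c(per_group, total = 100 * sum(diag(confusion)) / length(g))

  n <- length(g); k <- 2L
  vt <- apply(X, 2, function(v) {
    gm <- tapply(v, g, mean)
    ssb <- sum(tapply(v, g, length) * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    F <- (ssb / (k - 1)) / (ssw / (n - k))
    c(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
  })
  variable_tests <- data.frame(variable = colnames(X),
                               F = vt["F", ], p = vt["p", ],
                               row.names = NULL)
  variable_tests <- variable_tests[order(-variable_tests$F), ]

  structure(list(confusion = confusion, percent_correct = pct,
                 variable_tests = variable_tests,
                 coefficients = drop(rule$Sinv %*% (rule$m[1, ] - rule$m[2, ])),
                 means = rule$m, predicted = predicted,
                 method = method, prior = prior),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("Linear discriminant classification (%s, %s priors)\n",
              x$method, x$prior))
  print(x$confusion)
  cat(sprintf("percent correct: %s; total %.1f%%\n",
              paste(sprintf("%s %.1f%%",
                            names(x$percent_correct)[-length(x$percent_correct)],
                            x$percent_correct[-length(x$percent_correct)]),
                    collapse = ", "),
              x$percent_correct[["total"]]))
  cat("discriminating variables (one-way F):\n")
  vt <- x$variable_tests
  vt$F <- signif(vt$F, 5); vt$p <- signif(vt$p, 3)
  print(vt, row.names = FALSE)
  invisible(x)
}
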