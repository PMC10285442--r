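#' AIC-based linear-model reduction
#'
#' Fits a Gaussian linear model of `response` on the candidate predictors
#' and reduces it by the Akaike Information Criterion,
#' `AIC = n * log(RSS / n) + 2k` with `k` the number of fitted
#' coefficients (the additive Gaussian constant is dropped, as in
#' `stats::extractAIC`).  The default strategy is backward elimination:
#' repeatedly drop the term whose removal lowers the AIC most, until no
#' removal helps.  Exhaustive search over all predictor subsets is
#' available for up to 12 candidates.
#'
#' @param response Numeric response vector.
#' @param candidate_predictors Data frame (or matrix) of candidate terms;
#'   factors allowed.
#' @param strategy `"backward"` or `"exhaustive"`.
#' @return Object of class `aic_selection`: `selected_terms`, `aic`,
#'   `aic_full`, `r_squared`, `term_tests` (marginal F-test per retained
#'   term), and the final `stats::lm` fit as `model`.
#' @export
lm_aic_select <- function(response, candidate_predictors,
                          strategy = c("backward", "exhaustive")) {
  strategy <- match.arg(strategy)
  X <- as.data.frame(candidate_predictors)
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(X) != n) stop("response and predictors disagree in length")
  terms <- names(X)
  if (n <= ncol(stats::model.matrix(~., X)))
    stop("too few observations for the full model")
  dat <- cbind(.y = y, X)

  fit_terms <- function(tms) {
    f <- if (length(tms)) stats::reformulate(tms, response = ".y")
         else .y ~ 1
    stats::lm(f, data = dat)
  }
  # RSS floored at a relative tolerance so exact fits compare by parameter
  # count instead of log(0)
  tss <- sum((y - mean(y))^2)
  aic_of <- function(fit) {
    rss <- max(sum(stats::residuals(fit)^2), 1e-12 * tss, 1e-300)
    n * log(rss / n) + 2 * length(stats::coef(fit))
  }

  full <- fit_terms(terms)
  if (any(is.na(stats::coef(full)))) stop("singular full-model fit")
  aic_full <- aic_of(full)

  if (strategy == "backward") {
    current <- terms
    best_fit <- full
    best_aic <- aic_full
    repeat {
      if (!length(current)) break
      cand <- lapply(current, function(tm) fit_terms(setdiff(current, tm)))
      aics <- vapply(cand, aic_of, numeric(1))
      if (min(aics) < best_aic - 1e-10) {
        drop_i <- which.min(aics)
        current <- setdiff(current, current[drop_i])
        best_fit <- cand[[drop_i]]
        best_aic <- aics[drop_i]
      } else break
    }
  } else {
    if (length(terms) > 12L) stop("exhaustive search limited to 12 candidates")
    best_aic <- Inf; best_fit <- NULL; current <- NULL
    for (mask in 0:(2^length(terms) - 1)) {
      tms <- terms[bitwAnd(mask, 2^(seq_along(terms) - 1)) > 0]
      fit <- fit_terms(tms)
      a <- aic_of(fit)
      if (a < best_aic - 1e-10) {
        best_aic <- a; best_fit <- fit; current <- tms
      }
    }
  }

  tt <- NULL
  if (length(current)) {
    d1 <- suppressWarnings(stats::drop1(best_fit, test = "F"))
    keep <- rownames(d1) != "<none>"
    tt <- data.frame(term = rownames(d1)[keep],
                     df = d1$Df[keep],
                     F = d1$`F value`[keep],
                     p = d1$`Pr(>F)`[keep],
                     row.names = NULL)
  }
  structure(list(selected_terms = current, aic = best_aic,
                 aic_full = aic_full,
                 r_squared = suppressWarnings(summary(best_fit)$r.squared),
                 term_tests = tt, model = best_fit, strategy = strategy),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  cat(sprintf("AIC model reduction (%s): AIC %.2f (full %.2f), R^2 = %.4f\n",
              x$strategy, x$aic, x$aic_full, x$r_squared))
  if (length(x$selected_terms)) {
    cat("selected terms:", paste(x$selected_terms, collapse = ", "), "\n")
    if (!is.null(x$term_tests)) {
      tt <- x$term_tests
      tt$F <- signif(tt$F, 4); tt$p <- signif(tt$p, 3)
      print(tt, row.names = FALSE)
    }
  } else cat("selected model: intercept only\n")
  invisible(x)
}
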