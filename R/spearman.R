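# all permutations of 1..n as an n! x n matrix (n <= 8 kept small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Ranks both vectors (average ranks for ties) and returns the Pearson
#' correlation of the ranks.  For n of 8 or fewer the two-sided p-value is
#' exact, from full enumeration of all permutations of one variable;
#' otherwise it uses the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n at least 4, neither
#'   constant.
#' @return An object of class `htest` with `estimate` (rho), `p.value`,
#'   and for the approximate case the t statistic.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))$estimate
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("at least 4 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  dn <- paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  if (n <= 8L) {
    P <- .permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    null_rs <- (matrix(ryc[P], nrow(P), n) %*% rxc) / denom
    p <- mean(abs(null_rs) >= abs(rs) - 1e-12)
    return(structure(list(estimate = c(rho = rs), p.value = p,
                          method = "Spearman rank correlation (exact permutation)",
                          alternative = "two.sided", data.name = dn),
                     class = "htest"))
  }
  tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(estimate = c(rho = rs), p.value = min(p, 1),
                 statistic = c(t = tstat), parameter = c(df = n - 2),
                 method = "Spearman rank correlation (t approximation)",
                 alternative = "two.sided", data.name = dn),
            class = "htest")
}
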