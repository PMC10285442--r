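#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak, 1) - ratio * g(t; undershoot, 1)` with `g` the gamma
#' density, rescaled to unit peak height.  The defaults (response peak
#' around 5--6 s, undershoot around 15 s, undershoot ratio 1/6) follow the
#' canonical HRF used by standard fMRI analysis software.
#'
#' @param t Time in seconds (vector); values before 0 return 0.
#' @param peak Shape of the response gamma (seconds scale).
#' @param undershoot Shape of the undershoot gamma.
#' @param ratio Relative amplitude of the undershoot.
#' @return Numeric vector of HRF values, maximum 1.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  tt <- seq(0, 50, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak, rate = 1) -
                ratio * stats::dgamma(tt, shape = undershoot, rate = 1))
  h / hmax
}

.session_conditions <- function(session_kind) {
  switch(session_kind,
         spider = c("tarantula", "daddy_long_legs", "beetle", "leaves"),
         fear = c("tarantula", "beetle", "snake", "lizard"),
         stop(sprintf("unknown session kind '%s'", session_kind)))
}

# Eulerian circuit on the complete directed graph over `conds` including
# self-loops, each edge with multiplicity m (Hierholzer, seeded edge order).
# The resulting block sequence is circularly carryover-balanced: every
# ordered pair of conditions (repeats included) is adjacent exactly m times.
.balanced_sequence <- function(conds, m) {
  k <- length(conds)
  adj <- lapply(seq_len(k), function(i) sample(rep(seq_len(k), m)))
  ptr <- rep(1L, k)
  stack <- sample(k, 1L)
  circuit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (ptr[v] <= length(adj[[v]])) {
      u <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      stack <- c(stack, u)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  circuit <- rev(circuit)
  conds[circuit[-length(circuit)]]  # drop repeated endpoint
}

#' Build one block-design scanning session
#'
#' A session presents four stimulus categories in blocks of 10 pictures,
#' 1.5 s per picture (matching the repetition time), so each block spans
#' 15 s.  The "spider" session shows tarantulas, daddy-long-legs spiders,
#' beetles, and leaves; the "fear" session shows tarantulas, beetles,
#' snakes, and lizards.  With the default 8 blocks per condition a session
#' lasts 8 minutes and acquires 320 volumes.
#'
#' Block order is pseudorandom but carryover-balanced: every ordered pair
#' of conditions follows one another equally often.  Counting adjacencies
#' circularly (last block wraps to the first) and including same-condition
#' transitions, exact balance exists precisely when `blocks_per_condition`
#' is a multiple of 4; it is achieved by a seeded Eulerian-circuit
#' construction.  For other block counts `balance = "auto"` falls back to a
#' seeded shuffle, while `balance = "carryover"` raises an error.
#'
#' @param session_kind `"spider"` or `"fear"`.
#' @param blocks_per_condition Blocks per category (default 8).
#' @param seed Integer seed for the pseudorandom order.
#' @param tr_s Repetition time in seconds.
#' @param pictures_per_block,stimulus_duration_s Block composition.
#' @param balance `"auto"`, `"carryover"`, or `"none"`.
#' @return Object of class `session_design`.
#' @examples
#' s <- build_session("fear", blocks_per_condition = 8, seed = 3)
#' s$n_volumes  # 320
#' @export
build_session <- function(session_kind = c("spider", "fear"),
                          blocks_per_condition = 8L, seed = 1L,
                          tr_s = 1.5, pictures_per_block = 10L,
                          stimulus_duration_s = 1.5,
                          balance = c("auto", "carryover", "none")) {
  session_kind <- match.arg(session_kind)
  balance <- match.arg(balance)
  b <- as.integer(blocks_per_condition)
  if (b < 1L) stop("'blocks_per_condition' must be at least 1")
  conds <- .session_conditions(session_kind)
  set.seed(as.integer(seed))
  balanced <- b %% 4L == 0L
  if (balance == "carryover" && !balanced)
    stop("carryover balance impossible: blocks_per_condition must be a multiple of 4")
  seq_blocks <- if (balanced && balance != "none") {
    .balanced_sequence(conds, b %/% 4L)
  } else {
    sample(rep(conds, b))
  }
  block_s <- pictures_per_block * stimulus_duration_s
  total_s <- length(seq_blocks) * block_s
  n_vol <- total_s / tr_s
  if (abs(n_vol - round(n_vol)) > 1e-9)
    stop("session duration is not a whole number of volumes")
  structure(list(session_kind = session_kind, conditions = conds,
                 block_sequence = seq_blocks,
                 pictures_per_block = as.integer(pictures_per_block),
                 stimulus_duration_s = stimulus_duration_s,
                 tr_s = tr_s, n_volumes = as.integer(round(n_vol)),
                 session_duration_s = total_s,
                 carryover_balanced = balanced && balance != "none"),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("Block-design session '%s': %d blocks (%d/condition), %d volumes, %.0f s\n",
              x$session_kind, length(x$block_sequence),
              length(x$block_sequence) %/% length(x$conditions),
              x$n_volumes, x$session_duration_s))
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Count ordered condition adjacencies of a session
#'
#' @param session A `session_design`.
#' @param circular Wrap the last block to the first (the balance guarantee
#'   of [build_session()] is circular).
#' @return Integer matrix of adjacency counts, `from` x `to`.
#' @export
count_adjacencies <- function(session, circular = TRUE) {
  s <- session$block_sequence
  from <- s
  to <- c(s[-1], if (circular) s[1])
  if (!circular) from <- s[-length(s)]
  table(factor(from, session$conditions), factor(to, session$conditions))
}

#' Export a session as an events table
#'
#' @param session A `session_design`.
#' @param file Optional path; when given, written as tab-separated text
#'   (onset, duration, trial_type).
#' @return Data frame with one row per block.
#' @export
session_events <- function(session, file = NULL) {
  block_s <- session$pictures_per_block * session$stimulus_duration_s
  ev <- data.frame(
    onset = (seq_along(session$block_sequence) - 1) * block_s,
    duration = block_s,
    trial_type = session$block_sequence)
  if (!is.null(file))
    utils::write.table(ev, file, sep = "\t", quote = FALSE, row.names = FALSE)
  ev
}

#' Build the GLM design matrix for a session
#'
#' Each condition's regressor is its stimulus boxcar (1 at volumes
#' acquired during that condition's blocks) convolved with the canonical
#' double-gamma HRF sampled at the repetition time, truncated to the
#' session length.  An intercept column and optional Legendre-polynomial
#' drift columns are appended.
#'
#' @param session A `session_design`.
#' @param hrf_params List with `peak`, `undershoot`, `ratio` passed to
#'   [hrf_double_gamma()].
#' @param drift_order Highest Legendre polynomial order for drift (0 for
#'   none; default 1, a linear trend).
#' @return Object of class `design_matrix`: list with the `n_volumes x
#'   n_regressors` matrix `X`, `regressor_names`, `condition_cols` (column
#'   indices of the condition regressors), `boxcars` (pre-convolution
#'   indicator matrix), and `hrf_params`.
#' @export
build_design_matrix <- function(session,
                                hrf_params = list(peak = 6, undershoot = 16,
                                                  ratio = 1 / 6),
                                drift_order = 1L) {
  stopifnot(inherits(session, "session_design"))
  n <- session$n_volumes
  conds <- session$conditions
  block_vols <- session$pictures_per_block * session$stimulus_duration_s / session$tr_s
  if (block_vols < 1) stop("degenerate design: blocks shorter than one volume")
  box <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  for (j in seq_along(session$block_sequence)) {
    rows <- ((j - 1) * block_vols + 1):(j * block_vols)
    box[rows, session$block_sequence[j]] <- 1
  }
  if (any(colSums(box) == 0)) stop("degenerate design: all-zero condition regressor")
  h <- hrf_double_gamma(seq(0, 32, by = session$tr_s),
                        peak = hrf_params$peak,
                        undershoot = hrf_params$undershoot,
                        ratio = hrf_params$ratio)
  conv <- apply(box, 2, function(b) {
    stats::convolve(b, rev(h), type = "open")[seq_len(n)]
  })
  X <- cbind(conv, `(Intercept)` = rep(1, n))
  if (drift_order >= 1L) {
    tt <- seq(-1, 1, length.out = n)
    # Legendre polynomials by Gram-Schmidt on monomials
    P <- stats::poly(tt, degree = drift_order, raw = FALSE)
    drift <- scale(P, center = FALSE, scale = apply(abs(P), 2, max))
    colnames(drift) <- paste0("drift", seq_len(drift_order))
    X <- cbind(X, drift)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, regressor_names = colnames(X),
                 condition_cols = seq_along(conds),
                 boxcars = box, hrf_params = hrf_params,
                 tr_s = session$tr_s),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("GLM design matrix: %d volumes x %d regressors\n",
              nrow(x$X), ncol(x$X)))
  cat("regressors:", paste(x$regressor_names, collapse = ", "), "\n")
  invisible(x)
}
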