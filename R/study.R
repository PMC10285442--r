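#' Run the complete simulated study
#'
#' End-to-end pipeline: generate the cohort, score every instrument, run
#' the two-session fMRI simulation and Spider Fear Index computation, then
#' the downstream analyses — redundancy analysis of the picture fear
#' ratings with sequential permutation tests, AIC reduction of the linear
#' model for the SFI, discriminant classification of the groups, and the
#' Spearman correlations among SFI, SPQ, BAT and fear scores.
#'
#' One phobic subject is excluded before analysis by default
#' (`exclude_phobic = 1`), emulating a data-quality exclusion and yielding
#' the 29 + 32 analysis sample the default configuration targets.
#'
#' @param config An [effect_config()] with a seed.
#' @param spec A [brain_spec()].
#' @param blocks_per_condition Blocks per category per session.
#' @param n_perm Permutations for the sequential RDA tests.
#' @param exclude_phobic Number of phobic subjects dropped (from the top
#'   of the roster) before analysis.
#' @param rda_responses `"pictures"` (per-picture rating matrix,
#'   categories x pictures columns) or `"categories"` (6 mean-score
#'   columns, faster).
#' @param run_fmri Set `FALSE` to skip the fMRI arm (no SFI; RDA and the
#'   linear model then omit it).
#' @return Object of class `fear_study` with components `cohort`,
#'   `scores`, `sfi` (an [sfi_pipeline()] table), `data` (the merged
#'   analysis table), `rda`, `rda_test`, `selection`, `lda`, and
#'   `correlations`.
#' @examples
#' \donttest{
#' study <- run_study(effect_config(seed = 1), n_perm = 199)
#' print(study)
#' }
#' @export
run_study <- function(config = effect_config(seed = 1),
                      spec = brain_spec(),
                      blocks_per_condition = 8L,
                      n_perm = 1999L,
                      exclude_phobic = 1L,
                      rda_responses = c("pictures", "categories"),
                      run_fmri = TRUE) {
  rda_responses <- match.arg(rda_responses)
  cohort <- generate_cohort(config)
  scores <- score_cohort(cohort)
  phobic_ids <- scores$id[scores$group == "phobic"]
  exclude <- utils::head(phobic_ids, exclude_phobic)

  sfi_tab <- NULL
  if (run_fmri) {
    sfi_tab <- sfi_pipeline(cohort, spec = spec,
                            blocks_per_condition = blocks_per_condition,
                            exclude = exclude)
    dat <- merge(scores, as.data.frame(sfi_tab)[c("subject_id", "sfi")],
                 by.x = "id", by.y = "subject_id")
  } else {
    dat <- scores[!(scores$id %in% exclude), ]
  }
  dat <- dat[order(match(dat$id, scores$id)), ]
  rownames(dat) <- NULL

  fs_cols <- paste0("fs_", fear_categories())
  Y <- if (rda_responses == "pictures") {
    keep <- match(dat$id, cohort$info$id)
    r <- cohort$ratings[keep, , , drop = FALSE]
    m <- matrix(r, nrow = length(keep))
    colnames(m) <- as.vector(outer(colnames(cohort$ratings),
                                   seq_len(dim(r)[3]),
                                   function(a, b) paste0(a, "_p", b)))
    m
  } else as.matrix(dat[fs_cols])

  expl <- data.frame(group = dat$group, spq = dat$spq, snaq = dat$snaq,
                     dsr = dat$dsr, bat = dat$bat, age = dat$age)
  if (run_fmri) expl <- cbind(expl[1], sfi = dat$sfi, expl[-1])
  rda <- rda_fit(Y, expl)
  rda_test <- rda_sequential_test(Y, expl, n_perm = n_perm,
                                  seed = config$seed + 7L)

  selection <- NULL
  if (run_fmri) {
    cand <- data.frame(bat = dat$bat, spq = dat$spq, snaq = dat$snaq,
                       dsr = dat$dsr, dat[fs_cols],
                       group = dat$group, age = dat$age)
    selection <- lm_aic_select(dat$sfi, cand)
  }

  lda <- lda_classify(dat[c("fs_tarantula", "fs_snake",
                            "fs_daddy_long_legs", "snaq")], dat$group)

  dat$fs_spider <- rowMeans(dat[c("fs_tarantula", "fs_daddy_long_legs")])
  pairs <- list(c("spq", "bat"), c("spq", "fs_spider"),
                c("bat", "fs_spider"))
  if (run_fmri) pairs <- c(list(c("sfi", "bat"), c("sfi", "fs_spider"),
                                c("sfi", "spq")), pairs)
  correlations <- do.call(rbind, lapply(pairs, function(p) {
    ct <- spearman_cor(dat[[p[1]]], dat[[p[2]]])
    data.frame(x = p[1], y = p[2], rho = unname(ct$estimate),
               p = ct$p.value)
  }))

  structure(list(cohort = cohort, scores = scores, sfi = sfi_tab,
                 data = dat, rda = rda, rda_test = rda_test,
                 selection = selection, lda = lda,
                 correlations = correlations,
                 config = config, excluded = exclude),
            class = "fear_study")
}

#' @export
print.fear_study <- function(x, ...) {
  tab <- table(x$data$group)
  cat(sprintf("Simulated spider-fear study: %d analysed subjects (%d phobic, %d control)\n",
              nrow(x$data), tab[["phobic"]], tab[["control"]]))
  if (!is.null(x$sfi)) {
    means <- tapply(x$data$sfi, x$data$group, mean)
    cat(sprintf("SFI (ROI of %d voxels): phobic mean %.3f, control mean %.3f\n",
                attr(x$sfi, "roi")$n_voxels, means[["phobic"]], means[["control"]]))
  }
  cat(sprintf("RDA: %d constrained axes explain %.2f%% of rating variance\n",
              x$rda$rank, 100 * x$rda$prop_explained))
  cat(sprintf("LDA: %.1f%% correctly classified\n",
              x$lda$percent_correct[["total"]]))
  cat("Spearman correlations:\n")
  cc <- x$correlations
  cc$rho <- signif(cc$rho, 3); cc$p <- signif(cc$p, 3)
  print(cc, row.names = FALSE)
  invisible(x)
}
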