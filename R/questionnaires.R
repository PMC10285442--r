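#' Scoring key for a questionnaire
#'
#' @param n_items Number of items.
#' @param reversed_items 1-based indices of reverse-scored items.
#' @param catch_items 1-based indices of attention-check items (excluded
#'   from the total; DS-R only). Must be disjoint from `reversed_items`.
#' @param item_scale `"binary"` (true/false) or `"likert0to4"`.
#' @param catch_key Expected responses to the catch items (recycled); a
#'   subject is flagged invalid when any catch response differs.
#' @param subscales Optional named list mapping subscale names to item
#'   indices (scored items only).
#' @return An object of class `scoring_key`.
#' @export
scoring_key <- function(n_items, reversed_items = integer(0),
                        catch_items = integer(0),
                        item_scale = c("binary", "likert0to4"),
                        catch_key = 0L, subscales = NULL) {
  item_scale <- match.arg(item_scale)
  n_items <- as.integer(n_items)
  reversed_items <- as.integer(reversed_items)
  catch_items <- as.integer(catch_items)
  if (any(reversed_items < 1L | reversed_items > n_items))
    stop("'reversed_items' out of range")
  if (any(catch_items < 1L | catch_items > n_items))
    stop("'catch_items' out of range")
  if (length(intersect(reversed_items, catch_items)))
    stop("catch items must be disjoint from scored reversed items")
  structure(list(n_items = n_items, reversed_items = reversed_items,
                 catch_items = catch_items, item_scale = item_scale,
                 catch_key = as.integer(catch_key), subscales = subscales),
            class = "scoring_key")
}

#' Default scoring keys
#'
#' `spq_key()` and `snaq_key()` score the 31-item Spider Questionnaire and
#' the 30-item Snake Questionnaire: one point per fearful-direction answer,
#' nine items reverse-scored.  The identity of the nine reversed items is
#' not published, so the default key reverses items 1--9; the key is a
#' configuration input precisely so that a published key can be dropped in.
#' `dsr_key()` scores the Disgust Scale -- Revised: 25 disgust-elicitor
#' items on a 0--4 scale (items 1, 6, 10 reverse-scored) plus two catch
#' items (12 and 16).  The default subscale map assigns elicitors to the
#' three factors (core, animal reminder, contamination) in blocks, as a
#' documented stand-in for the unpublished assignment.
#'
#' @return A [scoring_key()].
#' @name default_keys
NULL

#' @rdname default_keys
#' @export
spq_key <- function() scoring_key(31L, reversed_items = 1:9)

#' @rdname default_keys
#' @export
snaq_key <- function() scoring_key(30L, reversed_items = 1:9)

#' @rdname default_keys
#' @export
dsr_key <- function() {
  scored <- setdiff(1:27, c(12L, 16L))
  scoring_key(27L, reversed_items = c(1L, 6L, 10L),
              catch_items = c(12L, 16L), item_scale = "likert0to4",
              catch_key = 0L,
              subscales = list(core = scored[1:12],
                               animal_reminder = scored[13:20],
                               contamination = scored[21:25]))
}

#' Score a binary true/false questionnaire
#'
#' Each fearful-direction answer contributes one point: a point for `TRUE`
#' on a normally keyed item, and for `FALSE` on a reverse-scored item
#' (response XOR reversed).
#'
#' @param responses Logical vector of length `key$n_items`.
#' @param key A [scoring_key()] with `item_scale = "binary"`.
#' @return List (class `score_result`) with integer `total` in
#'   `[0, n_items]` and `valid = TRUE`.
#' @examples
#' score_binary_questionnaire(rep(TRUE, 31), spq_key())$total  # 22: 9 reversed
#' @export
score_binary_questionnaire <- function(responses, key) {
  stopifnot(inherits(key, "scoring_key"), key$item_scale == "binary")
  responses <- as.logical(responses)
  if (length(responses) != key$n_items)
    stop(sprintf("expected %d responses, got %d", key$n_items, length(responses)))
  if (anyNA(responses)) stop("missing responses are not supported")
  scored <- responses
  scored[key$reversed_items] <- !scored[key$reversed_items]
  structure(list(total = as.integer(sum(scored)), valid = TRUE,
                 subscale_totals = NULL),
            class = "score_result")
}

#' Score the Disgust Scale -- Revised
#'
#' Sums the 25 elicitor items (0--4 each; reverse-scored items contribute
#' `4 - x`), excluding the catch items, for a total in 0--100.  The result
#' is flagged invalid when a catch response deviates from the keyed
#' attention value, but the total is still reported so the exclusion
#' decision stays with the caller.
#'
#' @param responses Integer vector of length 27 with values in 0--4.
#' @param key A [scoring_key()], typically [dsr_key()].
#' @return `score_result` with `total`, `valid`, and `subscale_totals`.
#' @export
score_dsr <- function(responses, key = dsr_key()) {
  stopifnot(inherits(key, "scoring_key"), key$item_scale == "likert0to4")
  responses <- as.integer(responses)
  if (length(responses) != key$n_items)
    stop(sprintf("expected %d responses, got %d", key$n_items, length(responses)))
  if (anyNA(responses) || any(responses < 0L | responses > 4L))
    stop("responses must be integers in 0..4")
  contrib <- responses
  contrib[key$reversed_items] <- 4L - contrib[key$reversed_items]
  scored <- setdiff(seq_len(key$n_items), key$catch_items)
  total <- sum(contrib[scored])
  valid <- TRUE
  if (length(key$catch_items)) {
    expected <- rep_len(key$catch_key, length(key$catch_items))
    valid <- all(responses[key$catch_items] == expected)
  }
  sub <- NULL
  if (!is.null(key$subscales))
    sub <- vapply(key$subscales, function(ix) sum(contrib[ix]), integer(1))
  structure(list(total = as.integer(total), valid = valid,
                 subscale_totals = sub),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("total = %d%s\n", x$total,
              if (x$valid) "" else "  [catch check FAILED]"))
  if (!is.null(x$subscale_totals)) {
    cat("subscales:\n")
    print(x$subscale_totals)
  }
  invisible(x)
}

#' Score a behavioral approach test
#'
#' The graded approach toward a live tarantula has seven ordered steps
#' (walk closer x3, uncover and look, open the terrarium, touch with a
#' pencil, touch with a finger); the score is the number of completed
#' steps.  A later step cannot be completed without the earlier ones, so
#' the outcomes must form a prefix.  Score 0 (no step completed) is
#' permitted for a refusal to approach at all.
#'
#' @param steps_completed Logical vector of length 7, `TRUE` for each
#'   completed step in order.
#' @return Integer score in 0--7 (7 = touched the animal with a finger).
#' @export
score_bat <- function(steps_completed) {
  steps_completed <- as.logical(steps_completed)
  if (length(steps_completed) != 7L || anyNA(steps_completed))
    stop("'steps_completed' must be 7 non-missing step outcomes")
  k <- sum(steps_completed)
  if (!all(steps_completed == (seq_len(7L) <= k)))
    stop("step outcomes must form a prefix: a later step requires all earlier ones")
  as.integer(k)
}

#' Classify a structured clinical interview
#'
#' Six questions probe whether fear of spiders impairs everyday life;
#' a respondent is assigned to the phobic category when at least five of
#' the six answers imply high fear.
#'
#' @param answers Logical vector of length 6.
#' @return `"phobic"` or `"not_phobic"`.
#' @export
classify_interview <- function(answers) {
  answers <- as.logical(answers)
  if (length(answers) != 6L || anyNA(answers))
    stop("'answers' must be 6 non-missing booleans")
  if (sum(answers) >= 5L) "phobic" else "not_phobic"
}
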