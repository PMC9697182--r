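# Crowd-rating aggregation with known-answer quality control, AQ
# questionnaire scoring with the partial-completion scaling rule, and
# per-child style summaries.

#' Filter raters by known-answer accuracy
#'
#' Each rater also guessed the object category of the presented (black) part
#' of every drawing they rated. All records of a rater are kept only if the
#' rater guessed correctly in strictly more than `threshold` of their
#' ratings; a rater at exactly the threshold is removed.
#'
#' @param records Rating tibble (`rater_id`, `drawing_id`, `s1`..`s7`,
#'   `guess`).
#' @param stimulus_truth Tibble mapping `drawing_id` to the true `category`.
#' @param threshold Accuracy threshold (default 0.7).
#' @return The records of surviving raters.
#' @export
qc_filter_raters <- function(records, stimulus_truth, threshold = 0.7) {
  truth <- stimulus_truth$category[match(records$drawing_id, stimulus_truth$drawing_id)]
  if (anyNA(truth)) {
    stop("stimulus_truth is missing drawings: ",
      paste(utils::head(unique(records$drawing_id[is.na(truth)]), 3L),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  acc <- tapply(records$guess == truth, records$rater_id, mean)
  keep <- names(acc)[acc > threshold]
  records[records$rater_id %in% keep, , drop = FALSE]
}

#' Aggregate ratings into per-drawing style scores
#'
#' Statement scores are averaged within rater and then across raters (each
#' rater weighs equally): the completion score is the rater-mean of
#' `mean(s1, s2)`, the scribbling score of `mean(s3, s4)`; tracing (`s5`),
#' coloring (`s6`) and relatedness (`s7`) are rater means of single
#' statements. Drawings in `empty_drawings` (nothing drawn) are assigned 0
#' on every score regardless of any records. Non-empty drawings without
#' surviving records get `NA` scores with a message.
#'
#' @param records QC-filtered rating tibble.
#' @param empty_drawings Character vector of drawing ids where nothing was
#'   drawn.
#' @param all_drawings Optional character vector of all drawing ids that
#'   should appear in the table (defaults to the union of rated and empty
#'   ids).
#' @return A tibble with `drawing_id`, `completion`, `scribbling`,
#'   `tracing`, `coloring`, `relatedness`, `n_raters_used`.
#' @export
aggregate_drawing_scores <- function(records, empty_drawings = character(),
                                     all_drawings = NULL) {
  per_rater <- dplyr::mutate(records,
    completion = (.data$s1 + .data$s2) / 2,
    scribbling = (.data$s3 + .data$s4) / 2,
    tracing = .data$s5, coloring = .data$s6, relatedness = .data$s7
  )
  agg <- dplyr::summarise(
    dplyr::group_by(per_rater, .data$drawing_id),
    dplyr::across(dplyr::all_of(c(RATED_STYLES, "relatedness")), mean),
    n_raters_used = dplyr::n(),
    .groups = "drop"
  )
  if (is.null(all_drawings)) {
    all_drawings <- union(agg$drawing_id, empty_drawings)
  }
  out <- dplyr::left_join(
    tibble::tibble(drawing_id = all_drawings), agg,
    by = "drawing_id"
  )
  is_empty <- out$drawing_id %in% empty_drawings
  for (col in c(RATED_STYLES, "relatedness")) {
    out[[col]][is_empty] <- 0
  }
  out$n_raters_used[is_empty] <- 0L
  out$n_raters_used[is.na(out$n_raters_used)] <- 0L
  unrated <- !is_empty & is.na(out$completion)
  if (any(unrated)) {
    message(
      sum(unrated), " drawing(s) have no surviving ratings and are left NA: ",
      paste(utils::head(out$drawing_id[unrated], 3L), collapse = ", "), "..."
    )
  }
  out
}

#' Score AQ questionnaire sheets
#'
#' Items are coded 1 (more autistic-like behavior), 0, or `NA` (missing). A
#' sheet is scored only if at least 40 of the 50 items are answered; the raw
#' sum is then scaled by `50 / n_answered` to be equivalent to a fully
#' filled questionnaire. Scores of at least 32 are flagged as conventionally
#' indicating strong autistic traits; the flag is informational and never
#' used as a filter.
#'
#' @param answers Tibble with `child_id` and items `item_1`..`item_50`.
#' @param min_answered Minimum answered items for a valid score.
#' @return A tibble with `child_id`, `n_answered`, `raw_sum`,
#'   `scaled_score` (`NA` when too few items were answered), `above_cutoff`.
#' @export
compute_aq <- function(answers, min_answered = 40L) {
  item_cols <- paste0("item_", 1:50)
  missing_cols <- setdiff(item_cols, names(answers))
  if (length(missing_cols) > 0L) {
    stop("answers is missing item columns: ",
      paste(utils::head(missing_cols, 3L), collapse = ", "),
      call. = FALSE
    )
  }
  items <- as.matrix(answers[, item_cols])
  if (!all(items %in% c(0L, 1L, NA))) {
    stop("AQ items must be 0, 1 or NA", call. = FALSE)
  }
  n_answered <- rowSums(!is.na(items))
  raw_sum <- rowSums(items, na.rm = TRUE)
  scaled <- ifelse(n_answered >= min_answered,
    raw_sum * 50 / n_answered, NA_real_
  )
  tibble::tibble(
    child_id = answers$child_id,
    n_answered = as.integer(n_answered),
    raw_sum = as.integer(raw_sum),
    scaled_score = scaled,
    above_cutoff = !is.na(scaled) & scaled >= 32
  )
}

#' Dominant drawing style per child
#'
#' The style whose average score, over all scored drawings of the child, is
#' maximal among completion, scribbling, tracing and coloring. Exact ties
#' are broken in that fixed order, with a message.
#'
#' @param score_table Aggregated score tibble
#'   ([aggregate_drawing_scores()]).
#' @param drawing_children Tibble mapping `drawing_id` to `child_id`.
#' @return A tibble with `child_id`, the per-child mean style scores, and
#'   `dominant_style` (`NA` if the child has no scored drawing).
#' @export
dominant_style <- function(score_table, drawing_children) {
  df <- dplyr::inner_join(score_table, drawing_children[, c("drawing_id", "child_id")],
    by = "drawing_id"
  )
  means <- dplyr::summarise(
    dplyr::group_by(df, .data$child_id),
    dplyr::across(dplyr::all_of(RATED_STYLES), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  m <- as.matrix(means[, RATED_STYLES])
  pick <- apply(m, 1L, function(v) {
    if (all(is.nan(v))) {
      return(NA_character_)
    }
    best <- which(v == max(v, na.rm = TRUE))
    if (length(best) > 1L) {
      message(
        "tie between styles (",
        paste(RATED_STYLES[best], collapse = ", "),
        "); broken by fixed order"
      )
    }
    RATED_STYLES[best[1L]]
  })
  means$dominant_style <- pick
  means
}
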