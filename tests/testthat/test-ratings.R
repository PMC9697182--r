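fake_records <- function(rater_id, drawing_id, guess, s = 50) {
  tibble::tibble(
    rater_id = rater_id, drawing_id = drawing_id,
    s1 = s, s2 = s, s3 = s, s4 = s, s5 = s, s6 = s, s7 = s,
    guess = guess
  )
}

test_that("rater QC keeps strictly-above-threshold raters only", {
  truth <- tibble::tibble(drawing_id = paste0("d", 1:10), category = "face")
  perfect <- fake_records("good", paste0("d", 1:10), rep("face", 10))
  exactly70 <- fake_records(
    "border", paste0("d", 1:10),
    c(rep("face", 7), rep("car", 3))
  )
  poor <- fake_records("bad", paste0("d", 1:10), rep("house", 10))
  records <- dplyr::bind_rows(perfect, exactly70, poor)
  kept <- qc_filter_raters(records, truth, threshold = 0.7)
  expect_setequal(unique(kept$rater_id), "good")
  # exactly 70% accuracy is removed: the rule is strictly more-than
  expect_false("border" %in% kept$rater_id)
})

test_that("raising the QC threshold never increases surviving records", {
  set.seed(20)
  b <- simulate_cohort(12, seed = 20)
  truth <- b$drawings[, c("drawing_id", "category")]
  counts <- vapply(c(0.5, 0.7, 0.9), function(th) {
    nrow(qc_filter_raters(b$ratings, truth, th))
  }, numeric(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("inaccurate raters are removed more often than accurate ones", {
  set.seed(21)
  drawing <- simulate_drawing(
    make_agent("complete", alpha = 1), render_stimulus("face", "outline")
  )
  removal_rate <- function(q) {
    removed <- vapply(1:100, function(i) {
      raters <- tibble::tibble(
        rater_id = sprintf("r%d", 1:2),
        known_answer_accuracy = q, noise_sd = 5
      )
      recs <- dplyr::bind_rows(lapply(1:10, function(k) {
        r <- simulate_ratings(drawing, raters)
        r$drawing_id <- paste0(r$drawing_id, "_", k)
        r
      }))
      truth <- tibble::tibble(
        drawing_id = unique(recs$drawing_id), category = "face"
      )
      kept <- qc_filter_raters(recs, truth)
      2L - length(unique(kept$rater_id))
    }, integer(1))
    mean(removed) / 2
  }
  expect_gt(removal_rate(0.5), removal_rate(0.9))
})

test_that("score aggregation averages statements then raters", {
  rec <- tibble::tibble(
    rater_id = c("r1", "r2"), drawing_id = "d1",
    s1 = c(80, 30), s2 = c(60, 50), # completion means 70 and 40 -> 55
    s3 = c(0, 20), s4 = c(10, 30), # scribbling means 5 and 25 -> 15
    s5 = c(10, 20), s6 = c(0, 40), s7 = c(50, 70),
    guess = "face"
  )
  out <- aggregate_drawing_scores(rec)
  expect_equal(out$completion, 55)
  expect_equal(out$scribbling, 15)
  expect_equal(out$tracing, 15)
  expect_equal(out$coloring, 20)
  expect_equal(out$relatedness, 60)
  expect_equal(out$n_raters_used, 2L)
  # single rater with s1 = 80, s2 = 60 -> completion 70
  single <- aggregate_drawing_scores(rec[1, ])
  expect_equal(single$completion, 70)
})

test_that("empty drawings are zero-scored even when ratings exist", {
  rec <- fake_records(c("r1", "r2"), "d_empty", "face", s = 90)
  out <- aggregate_drawing_scores(rec, empty_drawings = "d_empty")
  expect_equal(out$completion, 0)
  expect_equal(out$scribbling, 0)
  expect_equal(out$relatedness, 0)
  expect_equal(out$n_raters_used, 0L)
})

test_that("unrated non-empty drawings stay NA and are reported", {
  rec <- fake_records("r1", "d1", "face")
  expect_message(
    out <- aggregate_drawing_scores(rec, all_drawings = c("d1", "d2")),
    "no surviving ratings"
  )
  expect_true(is.na(out$completion[out$drawing_id == "d2"]))
  expect_equal(out$n_raters_used[out$drawing_id == "d2"], 0L)
})

test_that("aggregation is invariant to rater order and stays in range", {
  set.seed(22)
  b <- simulate_cohort(6, seed = 22)
  recs <- b$ratings
  a <- aggregate_drawing_scores(recs)
  b2 <- aggregate_drawing_scores(recs[sample.int(nrow(recs)), ])
  expect_equal(
    dplyr::arrange(a, .data$drawing_id),
    dplyr::arrange(b2, .data$drawing_id)
  )
  vals <- as.matrix(a[, c("completion", "scribbling", "tracing", "coloring", "relatedness")])
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("AQ scaling follows the minimum-40 rule exactly", {
  sheet <- function(child, n_answered, n_ones) {
    ans <- c(rep(1L, n_ones), rep(0L, n_answered - n_ones),
             rep(NA_integer_, 50L - n_answered))
    dplyr::bind_cols(
      tibble::tibble(child_id = child),
      tibble::as_tibble(as.list(stats::setNames(ans, paste0("item_", 1:50))))
    )
  }
  out <- compute_aq(dplyr::bind_rows(
    sheet("full", 50L, 18L),
    sheet("forty", 40L, 20L),
    sheet("thirtynine", 39L, 20L)
  ))
  expect_equal(out$scaled_score[out$child_id == "full"], 18)
  expect_equal(out$scaled_score[out$child_id == "forty"], 25)
  expect_true(is.na(out$scaled_score[out$child_id == "thirtynine"]))
  expect_equal(out$n_answered, c(50L, 40L, 39L))
  # identity whenever all 50 items are answered
  expect_equal(
    out$scaled_score[out$child_id == "full"],
    out$raw_sum[out$child_id == "full"]
  )
  expect_false(any(out$above_cutoff))
  high <- compute_aq(sheet("high", 50L, 40L))
  expect_true(high$above_cutoff)
  bad <- sheet("bad", 50L, 10L)
  bad$item_3 <- 2L
  expect_error(compute_aq(bad), "0, 1 or NA")
})

test_that("dominant style takes the per-child argmax with a fixed tie-break", {
  scores <- tibble::tibble(
    drawing_id = c("d1", "d2", "d3"),
    completion = c(80, 0, 40),
    scribbling = c(0, 80, 40),
    tracing = c(0, 0, 10),
    coloring = c(0, 0, 0),
    relatedness = 0, n_raters_used = 5L
  )
  map <- tibble::tibble(
    drawing_id = c("d1", "d2", "d3"),
    child_id = c("only_completes", "only_completes", "tied")
  )
  expect_message(out <- dominant_style(scores, map), "tie")
  expect_equal(
    out$dominant_style[out$child_id == "only_completes"], "completion"
  )
  # exact completion/scribbling tie resolves to completion
  expect_equal(out$dominant_style[out$child_id == "tied"], "completion")
})

test_that("zero-noise cohorts recover the modal true style per child", {
  p <- cohort_params()
  rp <- rater_params(noise_sd = 0, accuracy_shape1 = 200, accuracy_shape2 = 1)
  b <- simulate_cohort(100, p, rp, seed = 30)
  truth <- b$drawings[, c("drawing_id", "category")]
  kept <- qc_filter_raters(b$ratings, truth)
  scores <- suppressMessages(aggregate_drawing_scores(
    kept, empty_drawing_ids(b$drawings), b$drawings$drawing_id
  ))
  dom <- suppressMessages(dominant_style(scores, b$drawings))
  style_map <- c(
    complete = "completion", scribble = "scribbling",
    trace = "tracing", color = "coloring"
  )
  priority <- c("completion", "scribbling", "tracing", "coloring")
  modal <- vapply(split(b$drawings$true_style, b$drawings$child_id), function(st) {
    st <- style_map[st[st %in% names(style_map)]]
    if (length(st) == 0L) {
      return(NA_character_)
    }
    counts <- table(factor(st, levels = priority))
    # count ties resolved by the same fixed priority the scorer uses
    priority[which.max(counts)]
  }, character(1))
  cmp <- tibble::tibble(
    child_id = names(modal), modal = unname(modal)
  )
  cmp <- dplyr::inner_join(cmp, dom, by = "child_id")
  cmp <- cmp[!is.na(cmp$modal), ]
  expect_gte(mean(cmp$dominant_style == cmp$modal), 0.95)
})
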