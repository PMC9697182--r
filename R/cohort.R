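# Synthetic cohort: child agents with age-dependent drawing-style mixtures
# and a stimulus-adaptation probability alpha, adult completers, noisy crowd
# raters, and questionnaire sheets. The generator supplies ground truth
# (true_style, alpha) so that every downstream stage can be tested by
# parameter recovery.

#' Cohort generator parameters
#'
#' Parameters of the synthetic child cohort. Style mixtures follow a logistic
#' age trend on a softmax scale: the completion logit increases and the
#' scribbling logit decreases with age (in months, centered at
#' `age_center`), reproducing the qualitative developmental trend that
#' children scribble less and complete more as they grow older. The
#' stimulus-adaptation probability `alpha` is drawn from a Beta distribution
#' whose mean follows its own logistic age trend.
#'
#' @param age_range Admissible age range in months (default 25-99, the
#'   age span of the emulated cohort).
#' @param age_center,age_scale Centering/scaling (months) applied to age
#'   before the logistic trends.
#' @param complete_intercept,complete_slope Logit intercept/slope (per scaled
#'   age unit) of the completion style weight.
#' @param scribble_intercept,scribble_slope Logit intercept/slope of the
#'   scribbling style weight (the slope is subtracted, so positive values
#'   mean less scribbling with age).
#' @param trace_logit,color_logit,none_logit,off_target_logit Constant logits
#'   of the remaining styles.
#' @param alpha_intercept,alpha_slope Logistic trend of the mean of `alpha`.
#' @param alpha_concentration Beta concentration (a+b) of the alpha draw.
#' @param stroke_jitter_sd Point jitter (unit canvas) applied to completion
#'   strokes; tracing uses three times this value.
#' @param adult_jitter_sd Point jitter for adult completions; larger than the
#'   child completion jitter because adults drew freehand, without tracing
#'   aids, and repeated stimuli up to twice.
#' @param aq_shape1,aq_shape2 Beta parameters of the latent questionnaire
#'   propensity (mean ~0.3, matching typical totals between 10 and 20).
#' @param aq_missing_prob Per-item probability that a questionnaire item is
#'   left unanswered.
#' @param adult_second_prob Probability that an adult draws a second time on
#'   a stimulus.
#' @return A named list of class `cohort_params`.
#' @export
cohort_params <- function(age_range = c(25L, 99L),
                          age_center = 55, age_scale = 16,
                          complete_intercept = 0.5, complete_slope = 3.0,
                          scribble_intercept = 0.3, scribble_slope = 2.2,
                          trace_logit = -1.2, color_logit = -1.0,
                          none_logit = -2.4, off_target_logit = -1.8,
                          alpha_intercept = 1.5, alpha_slope = 2.8,
                          alpha_concentration = 12,
                          stroke_jitter_sd = 0.008,
                          adult_jitter_sd = 0.012,
                          aq_shape1 = 3, aq_shape2 = 7,
                          aq_missing_prob = 0.03,
                          adult_second_prob = 0.8) {
  structure(as.list(environment()), class = "cohort_params")
}

#' Crowd-rater parameters
#'
#' @param n_raters Size of the rater pool.
#' @param raters_per_drawing Number of independent ratings per drawing.
#' @param accuracy_shape1,accuracy_shape2 Beta parameters of each rater's
#'   known-answer accuracy (defaults give mostly accurate raters with a tail
#'   of careless ones).
#' @param noise_sd Gaussian noise (0-100 scale) added to each statement
#'   score before clipping.
#' @return A named list of class `rater_params`.
#' @export
rater_params <- function(n_raters = 40L, raters_per_drawing = 5L,
                         accuracy_shape1 = 9, accuracy_shape2 = 1.2,
                         noise_sd = 10) {
  structure(as.list(environment()), class = "rater_params")
}

style_weights_at_age <- function(age_months, params) {
  z <- (age_months - params$age_center) / params$age_scale
  logits <- c(
    none = params$none_logit,
    scribble = params$scribble_intercept - params$scribble_slope * z,
    trace = params$trace_logit,
    color = params$color_logit,
    complete = params$complete_intercept + params$complete_slope * z,
    off_target = params$off_target_logit
  )
  w <- exp(logits - max(logits))
  w / sum(w)
}

alpha_mean_at_age <- function(age_months, params) {
  z <- (age_months - params$age_center) / params$age_scale
  stats::plogis(params$alpha_intercept + params$alpha_slope * z)
}

#' Sample a synthetic child agent
#'
#' Draws one child of the given age from the cohort distribution: a style
#' mixture following the logistic age trends of `params`, a
#' stimulus-adaptation probability `alpha` from a Beta distribution with
#' age-dependent mean, a fixed off-target motif, and a latent questionnaire
#' propensity. Uses the current RNG state.
#'
#' @param age_months Integer age in months, within `params$age_range`.
#' @param params A [cohort_params()] list.
#' @param child_id Identifier; generated ids use this as-is.
#' @return A list of class `child_agent` with fields `child_id`,
#'   `age_months`, `alpha`, `style_weights`, `motif_seed`, `aq_propensity`.
#' @export
sample_child <- function(age_months, params = cohort_params(),
                         child_id = "child") {
  age_months <- as.integer(age_months)
  if (is.na(age_months) || age_months < params$age_range[1] ||
    age_months > params$age_range[2]) {
    stop(
      "age_months must lie in [", params$age_range[1], ", ",
      params$age_range[2], "], got ", age_months,
      call. = FALSE
    )
  }
  m <- alpha_mean_at_age(age_months, params)
  k <- params$alpha_concentration
  alpha <- stats::rbeta(1L, m * k, (1 - m) * k)
  structure(
    list(
      child_id = child_id,
      age_months = age_months,
      alpha = alpha,
      style_weights = style_weights_at_age(age_months, params),
      motif_seed = sample.int(10000L, 1L),
      aq_propensity = stats::rbeta(1L, params$aq_shape1, params$aq_shape2)
    ),
    class = "child_agent"
  )
}

# Deterministic off-target motif: a small star polygon whose vertex count and
# orientation are fixed by the agent's motif seed. Placement is fixed, so the
# motif is identical across stimuli.
motif_strokes <- function(motif_seed) {
  k <- 5L + (motif_seed %% 3L)
  rot <- (motif_seed %% 7L) / 7 * 2 * pi
  t <- seq(0, 2 * pi, length.out = 2L * k + 1L) + rot
  r <- rep(c(0.12, 0.05), k)[seq_len(2L * k)]
  r <- c(r, r[1])
  list(motif = cbind(x = 0.70 + r * cos(t), y = 0.70 + r * sin(t)))
}

jitter_strokes <- function(strokes, sd) {
  lapply(strokes, function(s) s + matrix(stats::rnorm(length(s), 0, sd), ncol = 2L))
}

scribble_strokes <- function(bbox) {
  n <- sample(5:30, 1L)
  lapply(seq_len(n), function(i) {
    start <- c(
      stats::runif(1L, bbox["xmin"], bbox["xmax"]),
      stats::runif(1L, bbox["ymin"], bbox["ymax"])
    )
    steps <- matrix(stats::rnorm(2L * sample(4:9, 1L), 0, 0.025), ncol = 2L)
    pts <- rbind(start, sweep(apply(steps, 2L, cumsum), 2L, start, "+"))
    colnames(pts) <- c("x", "y")
    pmin(pmax(pts, 0.02), 0.98)
  })
}

hatch_strokes <- function(bbox, spacing = 0.02) {
  ys <- seq(bbox["ymin"] + spacing / 2, bbox["ymax"] - spacing / 2, by = spacing)
  lapply(ys, function(y) seg_pts(bbox["xmin"], y, bbox["xmax"], y))
}

#' Simulate one drawing of an agent on a stimulus
#'
#' Samples a drawing style from the agent's mixture, then, with probability
#' `alpha`, produces strokes conditioned on the presented stimulus
#' (completion adds the complementary template strokes, tracing re-draws the
#' presented strokes with jitter, coloring hatches the dominant enclosed
#' presented region, scribbling stays inside the stimulus bounding box);
#' with probability `1 - alpha` the agent draws its fixed off-target motif
#' regardless of the stimulus. Style `none` yields an empty produced layer.
#' Uses the current RNG state.
#'
#' @param agent A [sample_child()] agent (or an adult agent).
#' @param stimulus A [render_stimulus()] stimulus.
#' @param params A [cohort_params()] list (stroke jitter).
#' @param drawing_id Identifier for the drawing.
#' @return A one-row [tibble::tibble] with the drawing metadata, ground
#'   truth (`true_style`, `adapted`, `alpha`) and list-columns `presented`
#'   and `produced` holding the stroke lists.
#' @export
simulate_drawing <- function(agent, stimulus, params = cohort_params(),
                             drawing_id = paste0(agent$child_id, "_", stimulus$label)) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  style <- sample(DRAW_STYLES, 1L, prob = agent$style_weights)
  adapted <- stats::runif(1L) < agent$alpha
  produced <- list()
  if (style != "none") {
    if (style == "off_target" || !adapted) {
      produced <- motif_strokes(agent$motif_seed)
      adapted <- FALSE
    } else {
      produced <- switch(style,
        complete = jitter_strokes(complement_strokes(stimulus), params$stroke_jitter_sd),
        trace = jitter_strokes(stimulus$strokes, 3 * params$stroke_jitter_sd),
        color = hatch_strokes(fill_region_bbox(stimulus)),
        scribble = scribble_strokes(strokes_bbox(stimulus$strokes))
      )
    }
  } else {
    adapted <- FALSE
  }
  tibble::tibble(
    drawing_id = drawing_id,
    child_id = agent$child_id,
    age_months = agent$age_months,
    category = stimulus$category,
    condition = stimulus$condition,
    stimulus_label = stimulus$label,
    true_style = style,
    adapted = adapted,
    alpha = agent$alpha,
    presented = list(stimulus$strokes),
    produced = list(produced)
  )
}

# Style-conditional statement means on the 0-100 scale. Statements s1/s2
# probe completion, s3/s4 scribbling, s5 tracing, s6 coloring, s7 whether the
# produced part relates to the presented part.
statement_means <- function(true_style, adapted, high = 85, low = 10) {
  m <- rep(low, 7L)
  idx <- switch(true_style,
    complete = 1:2, scribble = 3:4, trace = 5L, color = 6L,
    integer(0)
  )
  m[idx] <- high
  m[7L] <- if (adapted && true_style %in% c("complete", "trace", "color")) {
    high
  } else if (adapted) 25 else low
  if (true_style == "none") m <- rep(2, 7L)
  m
}

#' Simulate crowd ratings for one drawing
#'
#' Each rater scores the seven statements at their style-conditional means
#' plus Gaussian noise, clipped to `[0, 100]`, and answers the known-answer
#' category question correctly with their personal accuracy, otherwise
#' uniformly over the wrong options (including "I do not know"). Uses the
#' current RNG state.
#'
#' @param drawing A one-row drawing tibble from [simulate_drawing()].
#' @param raters A tibble of raters (`rater_id`, `known_answer_accuracy`,
#'   `noise_sd`), e.g. rows of the pool built by [simulate_cohort()].
#' @return A tibble with one row per rater: `rater_id`, `drawing_id`,
#'   `s1`..`s7`, `guess`.
#' @export
simulate_ratings <- function(drawing, raters) {
  stopifnot(nrow(raters) >= 1L)
  m <- statement_means(drawing$true_style, drawing$adapted)
  n <- nrow(raters)
  scores <- matrix(
    pmin(pmax(
      rep(m, each = n) + stats::rnorm(7L * n, 0, rep(raters$noise_sd, 7L)),
      0
    ), 100),
    nrow = n
  )
  colnames(scores) <- paste0("s", 1:7)
  correct <- stats::runif(n) < raters$known_answer_accuracy
  wrong <- setdiff(GUESS_OPTIONS, drawing$category)
  guess <- ifelse(correct, drawing$category,
    wrong[sample.int(length(wrong), n, replace = TRUE)]
  )
  dplyr::bind_cols(
    tibble::tibble(rater_id = raters$rater_id, drawing_id = drawing$drawing_id),
    tibble::as_tibble(scores),
    tibble::tibble(guess = guess)
  )
}

simulate_aq_sheet <- function(agent, params) {
  ans <- stats::rbinom(50L, 1L, agent$aq_propensity)
  ans[stats::runif(50L) < params$aq_missing_prob] <- NA_integer_
  out <- tibble::as_tibble(as.list(stats::setNames(ans, paste0("item_", 1:50))))
  dplyr::bind_cols(tibble::tibble(child_id = agent$child_id), out)
}

#' Simulate a full study cohort
#'
#' Generates the complete synthetic study: `n_children` child agents with
#' ages uniform over the cohort age range, assigned round-robin to the four
#' prepared drawing sets; six drawings per child; five adult reference
#' drawers who always complete (alpha = 1) and draw on every stimulus once,
#' plus a second time with probability `params$adult_second_prob`; a crowd
#' of noisy raters scoring every child drawing; and one 50-item
#' questionnaire sheet per child with item-level missingness.
#'
#' @param n_children Number of children (>= 1).
#' @param params A [cohort_params()] list.
#' @param rparams A [rater_params()] list.
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_adults Number of adult reference drawers.
#' @return A list of class `cohort_bundle` with tibbles `children`,
#'   `drawings`, `adult_drawings`, `raters`, `ratings`, `aq`, plus
#'   `drawing_sets` and the parameter lists.
#' @export
simulate_cohort <- function(n_children, params = cohort_params(),
                            rparams = rater_params(), seed = 1L,
                            n_adults = 5L) {
  stopifnot(n_children >= 1L)
  withr::local_seed(as.integer(seed))
  sets <- build_drawing_sets(seed = sample.int(.Machine$integer.max, 1L))

  ages <- sample(seq(params$age_range[1], params$age_range[2]), n_children,
    replace = TRUE
  )
  children_agents <- lapply(seq_len(n_children), function(i) {
    sample_child(ages[i], params, child_id = sprintf("c%03d", i))
  })
  children <- dplyr::bind_rows(lapply(seq_len(n_children), function(i) {
    a <- children_agents[[i]]
    tibble::tibble(
      child_id = a$child_id, age_months = a$age_months, alpha = a$alpha,
      aq_propensity = a$aq_propensity,
      drawing_set = ((i - 1L) %% 4L) + 1L
    )
  }))

  drawings <- dplyr::bind_rows(lapply(seq_len(n_children), function(i) {
    a <- children_agents[[i]]
    set <- sets[[((i - 1L) %% 4L) + 1L]]
    dplyr::bind_rows(lapply(set, function(st) {
      simulate_drawing(a, st, params,
        drawing_id = paste0(a$child_id, "_", st$label)
      )
    }))
  }))

  stimuli <- all_stimuli()
  adult_params <- params
  adult_params$stroke_jitter_sd <- params$adult_jitter_sd
  adult_drawings <- dplyr::bind_rows(lapply(seq_len(n_adults), function(j) {
    agent <- structure(
      list(
        child_id = sprintf("adult%02d", j), age_months = NA_integer_,
        alpha = 1, style_weights = stats::setNames(
          as.numeric(DRAW_STYLES == "complete"), DRAW_STYLES
        ),
        motif_seed = j, aq_propensity = NA_real_
      ),
      class = "child_agent"
    )
    dplyr::bind_rows(lapply(stimuli, function(st) {
      reps <- 1L + (stats::runif(1L) < params$adult_second_prob)
      dplyr::bind_rows(lapply(seq_len(reps), function(r) {
        simulate_drawing(agent, st, adult_params,
          drawing_id = sprintf("%s_%s_r%d", agent$child_id, st$label, r)
        )
      }))
    }))
  }))

  raters <- tibble::tibble(
    rater_id = sprintf("r%03d", seq_len(rparams$n_raters)),
    known_answer_accuracy = stats::rbeta(
      rparams$n_raters, rparams$accuracy_shape1, rparams$accuracy_shape2
    ),
    noise_sd = rparams$noise_sd
  )
  k <- min(rparams$raters_per_drawing, nrow(raters))
  ratings <- dplyr::bind_rows(lapply(seq_len(nrow(drawings)), function(i) {
    simulate_ratings(drawings[i, ], raters[sample.int(nrow(raters), k), ])
  }))

  aq <- dplyr::bind_rows(lapply(children_agents, simulate_aq_sheet, params = params))

  structure(
    list(
      children = children, drawings = drawings,
      adult_drawings = adult_drawings,
      raters = raters, ratings = ratings, aq = aq,
      drawing_sets = lapply(sets, names),
      params = params, rater_params = rparams, seed = as.integer(seed)
    ),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(
    "<cohort_bundle> ", nrow(x$children), " children, ",
    nrow(x$drawings), " drawings, ", nrow(x$adult_drawings),
    " adult drawings, ", nrow(x$ratings), " ratings (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Drawings with an empty produced layer
#'
#' @param drawings A drawings tibble from [simulate_cohort()].
#' @return Character vector of `drawing_id`s where nothing was drawn.
#' @export
empty_drawing_ids <- function(drawings) {
  drawings$drawing_id[vapply(drawings$produced, length, integer(1)) == 0L]
}
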