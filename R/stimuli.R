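# Stimulus construction: 4 object categories x 3 presentation conditions.
# Strokes are polylines (n x 2 matrices) on a unit canvas, origin bottom-left.

circle_pts <- function(cx, cy, r, n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(x = cx + r * cos(t), y = cy + r * sin(t))
}

# closed rectangle polyline
rect_closed <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

seg_pts <- function(x0, y0, x1, y1) cbind(x = c(x0, x1), y = c(y0, y1))

arc_pts <- function(cx, cy, r, from, to, n = 16L) {
  t <- seq(from, to, length.out = n)
  cbind(x = cx + r * cos(t), y = cy + r * sin(t))
}

# A part is a named shape (relative to its center) plus a canonical position.
make_part <- function(name, shape, center) {
  list(name = name, shape = shape, center = center)
}

place_part <- function(part, center) {
  sweep(part$shape, 2L, center, "+")
}

# Hand-authored templates. Only the categorical / conditional structure is
# analytically relevant; shapes are schematic.
stimulus_templates <- function() {
  list(
    face = list(
      outline = list(face_outline = circle_pts(0.5, 0.5, 0.38)),
      parts = list(
        make_part("left_eye", circle_pts(0, 0, 0.05), c(0.38, 0.62)),
        make_part("right_eye", circle_pts(0, 0, 0.05), c(0.62, 0.62)),
        make_part("nose", seg_pts(0, 0.05, 0, -0.05), c(0.50, 0.50)),
        make_part("mouth", arc_pts(0, 0.05, 0.12, -2.6, -0.54), c(0.50, 0.36))
      )
    ),
    house = list(
      outline = list(
        house_body = rect_closed(0.20, 0.15, 0.80, 0.60),
        house_roof = cbind(x = c(0.20, 0.50, 0.80), y = c(0.60, 0.85, 0.60))
      ),
      parts = list(
        make_part("door", rect_closed(-0.065, -0.115, 0.065, 0.115), c(0.515, 0.265)),
        make_part("left_window", rect_closed(-0.06, -0.05, 0.06, 0.05), c(0.34, 0.47)),
        make_part("right_window", rect_closed(-0.06, -0.05, 0.06, 0.05), c(0.68, 0.47))
      )
    ),
    car = list(
      outline = list(
        car_body = cbind(
          x = c(0.10, 0.90, 0.90, 0.72, 0.62, 0.36, 0.26, 0.10, 0.10),
          y = c(0.30, 0.30, 0.45, 0.45, 0.62, 0.62, 0.45, 0.45, 0.30)
        )
      ),
      parts = list(
        make_part("front_wheel", circle_pts(0, 0, 0.07), c(0.30, 0.28)),
        make_part("rear_wheel", circle_pts(0, 0, 0.07), c(0.70, 0.28)),
        make_part("window", rect_closed(-0.09, -0.055, 0.09, 0.055), c(0.49, 0.52))
      )
    ),
    human = list(
      outline = list(
        head = circle_pts(0.50, 0.80, 0.10),
        torso = seg_pts(0.50, 0.70, 0.50, 0.40),
        arms = seg_pts(0.32, 0.58, 0.68, 0.58),
        left_leg = seg_pts(0.50, 0.40, 0.38, 0.14),
        right_leg = seg_pts(0.50, 0.40, 0.62, 0.14)
      ),
      parts = list(
        make_part("left_eye", circle_pts(0, 0, 0.022), c(0.465, 0.825)),
        make_part("right_eye", circle_pts(0, 0, 0.022), c(0.535, 0.825)),
        make_part("mouth", arc_pts(0, 0.02, 0.045, -2.6, -0.54), c(0.50, 0.77)),
        make_part("left_hand", circle_pts(0, 0, 0.03), c(0.30, 0.58)),
        make_part("right_hand", circle_pts(0, 0, 0.03), c(0.70, 0.58))
      )
    )
  )
}

part_strokes <- function(parts, centers) {
  out <- lapply(seq_along(parts), function(i) place_part(parts[[i]], centers[[i]]))
  names(out) <- vapply(parts, `[[`, character(1), "name")
  out
}

#' Construct one presented stimulus
#'
#' Builds the stroke template for one of the 12 stimuli of the completion
#' task: an object category (`face`, `house`, `car`, `human`) crossed with a
#' presentation condition. In the `outline` condition only the object outline
#' is shown; in the `inner` condition only the inner features (eyes, wheels,
#' windows, ...) at their canonical positions; in the `scrambled` condition
#' the same inner features at cyclically permuted positions, so that the
#' canonical completion is not available.
#'
#' @param category One of `"face"`, `"house"`, `"car"`, `"human"`.
#' @param condition One of `"outline"`, `"inner"`, `"scrambled"`.
#' @param scramble_seed Integer selecting the cyclic shift used for the
#'   scrambled condition (ignored otherwise). Any value yields a non-identity
#'   permutation; the default `0` gives a shift of one position.
#' @return An object of class `stimulus_spec`: a list with `category`,
#'   `condition`, `label`, `strokes` (named list of x,y polyline matrices on
#'   the unit canvas), the canonical `outline` and `parts` templates, and
#'   `scramble_permutation`.
#' @examples
#' s <- render_stimulus("face", "outline")
#' names(s$strokes)
#' @export
render_stimulus <- function(category, condition, scramble_seed = 0L) {
  if (!is.character(category) || length(category) != 1L || !category %in% DRAW_CATEGORIES) {
    stop("unknown stimulus category: ", paste(category, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.character(condition) || length(condition) != 1L || !condition %in% DRAW_CONDITIONS) {
    stop("unknown presentation condition: ", paste(condition, collapse = ", "),
      call. = FALSE
    )
  }
  tmpl <- stimulus_templates()[[category]]
  np <- length(tmpl$parts)
  canonical_centers <- lapply(tmpl$parts, `[[`, "center")
  perm <- seq_len(np)
  if (condition == "scrambled") {
    shift <- 1L + (as.integer(scramble_seed) %% (np - 1L))
    perm <- c((shift + 1L):np, seq_len(shift)) # cyclic, never identity
  }
  strokes <- switch(condition,
    outline = tmpl$outline,
    inner = part_strokes(tmpl$parts, canonical_centers),
    scrambled = part_strokes(tmpl$parts, canonical_centers[perm])
  )
  structure(
    list(
      category = category,
      condition = condition,
      label = paste(category, condition, sep = "_"),
      strokes = strokes,
      outline = tmpl$outline,
      parts = tmpl$parts,
      scramble_permutation = perm
    ),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(
    "<stimulus_spec> ", x$label, ": ", length(x$strokes), " strokes (",
    paste(names(x$strokes), collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' All 12 stimuli of the task
#'
#' @param scramble_seed Passed to [render_stimulus()] for the scrambled
#'   condition.
#' @return A list of 12 `stimulus_spec` objects named by their
#'   `category_condition` label.
#' @export
all_stimuli <- function(scramble_seed = 0L) {
  grid <- expand.grid(
    condition = DRAW_CONDITIONS, category = DRAW_CATEGORIES,
    stringsAsFactors = FALSE
  )
  out <- Map(render_stimulus, grid$category, grid$condition,
    MoreArgs = list(scramble_seed = scramble_seed)
  )
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

# Strokes a completing drawer would add: the complement of the presented part
# within the full object template.
complement_strokes <- function(stimulus) {
  if (stimulus$condition == "outline") {
    part_strokes(stimulus$parts, lapply(stimulus$parts, `[[`, "center"))
  } else {
    stimulus$outline
  }
}

# The closed region a coloring drawer would fill: the dominant closed shape
# among the presented strokes (outline body, or the largest presented part).
fill_region_bbox <- function(stimulus) {
  strokes <- stimulus$strokes
  areas <- vapply(strokes, function(s) {
    diff(range(s[, 1])) * diff(range(s[, 2]))
  }, numeric(1))
  s <- strokes[[which.max(areas)]]
  c(
    xmin = min(s[, 1]), xmax = max(s[, 1]),
    ymin = min(s[, 2]), ymax = max(s[, 2])
  )
}

strokes_bbox <- function(strokes) {
  pts <- do.call(rbind, strokes)
  c(
    xmin = min(pts[, 1]), xmax = max(pts[, 1]),
    ymin = min(pts[, 2]), ymax = max(pts[, 2])
  )
}

#' Build the four prepared drawing sets
#'
#' Each participant is assigned to one of four prepared sets of six stimuli.
#' Every set contains exactly two stimuli of each presentation condition and
#' never more than two stimuli of the same object category. Across the four
#' sets every one of the 12 stimuli appears exactly twice.
#'
#' @param seed Integer seed; the construction is deterministic given the
#'   seed.
#' @param scramble_seed Passed to [render_stimulus()].
#' @return A list of 4 lists, each containing 6 `stimulus_spec` objects.
#' @export
build_drawing_sets <- function(seed = 1L, scramble_seed = 0L) {
  stimuli <- all_stimuli(scramble_seed = scramble_seed)
  labels <- names(stimuli)
  meta <- tibble::tibble(
    label = labels,
    category = vapply(stimuli, `[[`, character(1), "category"),
    condition = vapply(stimuli, `[[`, character(1), "condition")
  )
  ok <- function(sets) {
    all(vapply(sets, function(ls) {
      m <- meta[match(ls, meta$label), ]
      all(table(m$condition)[DRAW_CONDITIONS] == 2L) &&
        max(table(m$category)) <= 2L
    }, logical(1)))
  }
  withr::with_seed(as.integer(seed), {
    repeat {
      # two balanced random covers of the 12 stimuli -> 4 sets of 6
      sets <- c(split_cover(meta), split_cover(meta))
      if (ok(sets)) break
    }
  })
  lapply(sets, function(ls) stimuli[ls])
}

# Split the 12 stimuli into 2 sets of 6 with 2 per condition each.
split_cover <- function(meta) {
  pick <- unlist(lapply(split(meta$label, meta$condition), function(ls) {
    sample(ls, 2L)
  }), use.names = FALSE)
  list(pick, setdiff(meta$label, pick))
}
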