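# Representational dissimilarity: the Pearson correlation distance between
# layer activations, RDMs over stimuli (group level) and per child, the
# per-child RDM score, and the style-vs-adult distance analysis.

#' Pearson correlation distance
#'
#' The dissimilarity between two feature vectors,
#' `d = 1 - cov(x, y) / sqrt(var(x) * var(y))`, lying in `[0, 2]`:
#' 0 for perfectly correlated, 1 for uncorrelated, 2 for perfectly
#' anticorrelated vectors. Population (divide-by-n) moments are used; the
#' ratio is identical under the sample convention. If either vector is
#' constant the correlation is undefined; the distance is then totalized
#' with a warning: 0 when both are constant and equal, 2 otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single numeric distance in `[0, 2]`.
#' @examples
#' pearson_distance(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop(
      "feature vectors differ in length (", length(x), " vs ", length(y), ")",
      call. = FALSE
    )
  }
  if (length(x) < 2L) stop("feature vectors must have length >= 2", call. = FALSE)
  xm <- x - mean(x)
  ym <- y - mean(y)
  vx <- sum(xm * xm)
  vy <- sum(ym * ym)
  if (vx == 0 || vy == 0) {
    warning("constant feature vector: Pearson distance undefined, totalized",
      call. = FALSE
    )
    if (vx == 0 && vy == 0 && isTRUE(all.equal(x[1], y[1]))) {
      return(0)
    }
    return(2)
  }
  1 - sum(xm * ym) / sqrt(vx * vy)
}

new_rdm <- function(matrix, labels, layer, produced_only) {
  dimnames(matrix) <- list(labels, labels)
  structure(
    list(
      matrix = matrix, labels = labels, layer = layer,
      produced_only = produced_only
    ),
    class = "rdm"
  )
}

rdm_from_vectors <- function(vectors, labels, layer, produced_only) {
  n <- length(vectors)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- pearson_distance(vectors[[i]], vectors[[j]])
    }
  }
  new_rdm(m, labels, layer, produced_only)
}

#' @export
print.rdm <- function(x, ...) {
  cat(
    "<rdm> ", nrow(x$matrix), " x ", ncol(x$matrix), " (layer ", x$layer,
    if (isTRUE(x$produced_only)) ", produced-only" else ", full drawings",
    "), score ", format(rdm_score(x), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Restrict an RDM to a subset of labels
#'
#' @param rdm An `rdm`.
#' @param labels Labels to keep, in the order given.
#' @return The sub-RDM.
#' @export
subset_rdm <- function(rdm, labels) {
  missing <- setdiff(labels, rdm$labels)
  if (length(missing) > 0L) {
    stop("labels not in RDM: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(labels, rdm$labels)
  new_rdm(rdm$matrix[idx, idx, drop = FALSE], labels, rdm$layer, rdm$produced_only)
}

# Internal validity check used by tests and IO.
check_rdm <- function(rdm, tol = 1e-9) {
  m <- rdm$matrix
  all(is.finite(m)) &&
    max(abs(m - t(m))) <= tol &&
    max(abs(diag(m))) <= tol &&
    min(m) >= -tol && max(m) <= 2 + tol
}

#' Group-level RDM over stimuli
#'
#' For each stimulus label, averages the feature vectors of all drawings on
#' that stimulus, then computes the pairwise Pearson distances between the
#' averaged vectors. With all 12 stimuli present this yields the 12 x 12
#' dissimilarity matrix whose block structure reflects how distinctly a
#' group adapted its drawings to different stimuli. Produced-only features
#' are the intended input, so that the presented strokes do not contribute.
#'
#' @param features A feature tibble ([compute_drawing_features()]) with
#'   columns `stimulus_label`, `layer` and `feature`; a single layer only.
#' @param labels Stimulus label order for the matrix (default: sorted by
#'   category then condition so category blocks are contiguous).
#' @return An [`rdm`][pearson_distance] object.
#' @export
group_rdm <- function(features, labels = NULL) {
  stopifnot(nrow(features) > 0L)
  layer <- unique(features$layer)
  if (length(layer) != 1L) {
    stop("features must contain a single layer, got: ",
      paste(layer, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(labels)) {
    grid <- expand.grid(
      condition = DRAW_CONDITIONS, category = DRAW_CATEGORIES,
      stringsAsFactors = FALSE
    )
    labels <- intersect(
      paste(grid$category, grid$condition, sep = "_"),
      unique(features$stimulus_label)
    )
  }
  missing <- setdiff(labels, unique(features$stimulus_label))
  if (length(missing) > 0L) {
    stop("no feature vectors for stimulus label(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  means <- lapply(labels, function(lb) {
    vs <- features$feature[features$stimulus_label == lb]
    rowMeans(do.call(cbind, vs))
  })
  rdm_from_vectors(means, labels, layer, produced_only = TRUE)
}

#' Per-child RDM
#'
#' Computes the RDM of one child over the six stimuli the child drew on,
#' from produced-only features (the presented part is removed before feature
#' extraction). Children with fewer than `n_required` drawings are excluded.
#'
#' @param drawings The drawings of one child (a drawings tibble subset).
#' @param backbone A `drawing_backbone`.
#' @param layer Analysis layer (default `fc7`, the highest layer).
#' @param n_required Number of distinct stimuli required (default 6).
#' @param canvas,width Rendering parameters.
#' @return An `rdm`, or `NULL` (with a message) if the child is excluded.
#' @export
child_rdm <- function(drawings, backbone, layer = "fc7", n_required = 6L,
                      canvas = 224L, width = 2) {
  if (length(unique(drawings$child_id)) != 1L) {
    stop("child_rdm() expects the drawings of exactly one child", call. = FALSE)
  }
  if (length(unique(drawings$stimulus_label)) < n_required) {
    message(
      "child ", drawings$child_id[1], " excluded: saw ",
      length(unique(drawings$stimulus_label)), " < ", n_required, " stimuli"
    )
    return(NULL)
  }
  feats <- compute_drawing_features(drawings, backbone,
    layers = layer,
    produced_only = TRUE, canvas = canvas, width = width
  )
  rdm_from_vectors(feats$feature, feats$stimulus_label, layer,
    produced_only = TRUE
  )
}

#' Per-child RDMs and scores for a cohort
#'
#' @param bundle A `cohort_bundle`, or a drawings tibble.
#' @param backbone A `drawing_backbone`.
#' @inheritParams child_rdm
#' @param features Optional precomputed produced-only feature tibble for the
#'   drawings (single layer); avoids re-rendering.
#' @return A tibble with `child_id`, list-column `rdm` and `rdm_score`.
#' @export
child_rdms <- function(bundle, backbone = NULL, layer = "fc7",
                       n_required = 6L, canvas = 224L, width = 2,
                       features = NULL) {
  drawings <- if (inherits(bundle, "cohort_bundle")) bundle$drawings else bundle
  if (is.null(features)) {
    features <- compute_drawing_features(drawings, backbone,
      layers = layer,
      produced_only = TRUE, canvas = canvas, width = width
    )
  }
  features <- features[features$layer == layer, ]
  split_feats <- split(features, features$child_id)
  rows <- lapply(names(split_feats), function(cid) {
    f <- split_feats[[cid]]
    if (length(unique(f$stimulus_label)) < n_required) {
      message(
        "child ", cid, " excluded: saw ",
        length(unique(f$stimulus_label)), " < ", n_required, " stimuli"
      )
      return(NULL)
    }
    r <- rdm_from_vectors(f$feature, f$stimulus_label, layer, TRUE)
    tibble::tibble(child_id = cid, rdm = list(r), rdm_score = rdm_score(r))
  })
  dplyr::bind_rows(rows)
}

#' RDM score: mean off-diagonal dissimilarity
#'
#' The mean of the strictly off-diagonal entries of an RDM. For a per-child
#' RDM, a high score means the child drew differently on different stimuli
#' (stimulus-adaptive, bottom-up-driven drawing); a low score means the
#' child drew similarly everywhere (repetitive, prior-driven drawing).
#'
#' @param rdm An `rdm` object or a square numeric matrix, n >= 2.
#' @return A single numeric score.
#' @export
rdm_score <- function(rdm) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else rdm
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < 2L) stop("rdm_score() needs an RDM of size >= 2", call. = FALSE)
  mean(m[row(m) != col(m)])
}

#' Category block contrast of an RDM
#'
#' Mean between-category off-diagonal distance minus mean within-category
#' off-diagonal distance: a scalar summary of the near-diagonal category
#' clustering visible in group RDMs of stimulus-adaptive drawers. Positive
#' values mean drawings on same-category stimuli are more similar than
#' drawings on different-category stimuli.
#'
#' @param rdm An `rdm` whose labels encode the category (or pass
#'   `categories`).
#' @param categories Category of each label; defaults to the part of the
#'   label before the first underscore.
#' @return A single numeric contrast.
#' @export
block_contrast <- function(rdm, categories = NULL) {
  m <- rdm$matrix
  if (is.null(categories)) categories <- sub("_.*$", "", rdm$labels)
  if (length(unique(categories)) < 2L) {
    stop("block_contrast() needs at least two categories", call. = FALSE)
  }
  same <- outer(categories, categories, "==") & row(m) != col(m)
  diff <- outer(categories, categories, "!=")
  if (!any(same)) {
    stop("no within-category pairs available", call. = FALSE)
  }
  mean(m[diff]) - mean(m[same])
}

#' Select style sets from aggregated scores
#'
#' For each of the four rated drawing styles, collects the drawings whose
#' average style score strictly exceeds the cutoff (the rating scale runs
#' 0-100; the default cutoff of 70 corresponds to "clearly shows this
#' style", with 60 and 80 as robustness variants).
#'
#' @param score_table An aggregated score tibble
#'   ([aggregate_drawing_scores()]).
#' @param cutoff Strict threshold on the 0-100 scale.
#' @return A tibble with `style`, `cutoff`, `n`, and list-column
#'   `drawing_ids`; empty styles are kept with `n = 0` and a message.
#' @export
select_style_sets <- function(score_table, cutoff = 70) {
  rows <- lapply(RATED_STYLES, function(st) {
    ids <- score_table$drawing_id[
      !is.na(score_table[[st]]) & score_table[[st]] > cutoff
    ]
    if (length(ids) == 0L) {
      message("style set '", st, "' is empty at cutoff ", cutoff)
    }
    tibble::tibble(
      style = st, cutoff = cutoff, n = length(ids),
      drawing_ids = list(ids)
    )
  })
  dplyr::bind_rows(rows)
}

#' Distance of a style set to adult drawings
#'
#' For every child drawing in each style set, computes the mean Pearson
#' distance between its features and the features of all adult drawings on
#' the same presented stimulus, then summarizes per style. Full drawings
#' (presented + produced, recolored) are the intended input, since both
#' participants drew on the identical presented part.
#'
#' @param style_sets Output of [select_style_sets()].
#' @param child_features,adult_features Single-layer feature tibbles
#'   ([compute_drawing_features()] with `produced_only = FALSE`).
#' @return A tibble with one row per style: `style`, `layer`, `n`, `mean`,
#'   `sd` and list-column `per_drawing_distances`. Child drawings on a
#'   stimulus without any adult drawing are skipped with a message.
#' @export
style_vs_adult_distances <- function(style_sets, child_features, adult_features) {
  layer <- unique(c(child_features$layer, adult_features$layer))
  stopifnot(length(layer) == 1L)
  adult_by_stim <- split(adult_features$feature, adult_features$stimulus_label)
  rows <- lapply(seq_len(nrow(style_sets)), function(i) {
    ids <- style_sets$drawing_ids[[i]]
    sel <- child_features[child_features$drawing_id %in% ids, ]
    dists <- vapply(seq_len(nrow(sel)), function(j) {
      adults <- adult_by_stim[[sel$stimulus_label[j]]]
      if (is.null(adults)) {
        message(
          "drawing ", sel$drawing_id[j],
          " skipped: no adult drawing on ", sel$stimulus_label[j]
        )
        return(NA_real_)
      }
      mean(vapply(adults, pearson_distance, numeric(1), y = sel$feature[[j]]))
    }, numeric(1))
    dists <- dists[!is.na(dists)]
    tibble::tibble(
      style = style_sets$style[i], layer = layer,
      n = length(dists),
      mean = if (length(dists) > 0L) mean(dists) else NA_real_,
      sd = if (length(dists) > 1L) stats::sd(dists) else NA_real_,
      per_drawing_distances = list(dists)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write / read an RDM as CSV with a JSON sidecar
#'
#' The CSV holds the labeled matrix; the sidecar (`<path>.json`) records the
#' layer, whether produced-only features were used, and an optional backbone
#' id.
#'
#' @param rdm An `rdm` object.
#' @param path CSV path.
#' @param backbone_id Optional backbone identifier for the sidecar.
#' @return `path`, invisibly (`write_rdm`); an `rdm` (`read_rdm`).
#' @export
write_rdm <- function(rdm, path, backbone_id = NULL) {
  df <- tibble::as_tibble(rdm$matrix)
  df <- dplyr::bind_cols(tibble::tibble(label = rdm$labels), df)
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(
      layer = rdm$layer, produced_only = rdm$produced_only,
      backbone_id = backbone_id, labels = rdm$labels
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1L])
  new_rdm(
    unname(m), df$label, meta$layer,
    isTRUE(meta$produced_only)
  )
}

#' Tidy an RDM into a long tibble
#'
#' @param x An `rdm`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `distance`.
#' @method tidy rdm
#' @export
tidy.rdm <- function(x, ...) {
  grid <- expand.grid(
    row = x$labels, col = x$labels,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    row = grid$row, col = grid$col,
    distance = as.vector(x$matrix)
  )
}

#' Heatmap of an RDM
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdm
#' @export
autoplot.rdm <- function(object, ...) {
  df <- tidy.rdm(object)
  df$row <- factor(df$row, levels = object$labels)
  df$col <- factor(df$col, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2), name = "distance") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0("RDM (", object$layer, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Style-distance profile across layers
#'
#' Mean distance of each style set to adult drawings, per analysis layer.
#'
#' @param summaries A tibble binding [style_vs_adult_distances()] results
#'   over layers.
#' @return A ggplot object.
#' @export
plot_style_distances <- function(summaries) {
  summaries$layer <- factor(summaries$layer, levels = ANALYSIS_LAYERS)
  ggplot2::ggplot(
    summaries,
    ggplot2::aes(
      x = .data$layer, y = .data$mean,
      color = .data$style, group = .data$style
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "backbone layer", y = "mean distance to adult drawings",
      color = "style"
    ) +
    ggplot2::theme_minimal()
}
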