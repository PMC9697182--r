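# End-to-end orchestration: synthetic cohort -> ratings -> features ->
# style sets and adult comparison -> group and per-child RDMs -> statistics.
# All outputs are plain CSV/JSON (plus PNG drawings), deterministic under a
# fixed config and seed.

#' Pipeline configuration
#'
#' @param n_children Number of simulated children.
#' @param seed Master seed; per-stage seeds are derived at fixed offsets.
#' @param backbone `"test"` (seed-deterministic weights) or `"vgg19"`
#'   (requires `weights_path`).
#' @param weights_path Local VGG19 weights RDS (only for
#'   `backbone = "vgg19"`).
#' @param layer Analysis layer for RDMs and the RDM score.
#' @param style_layers Layers at which the style-vs-adult distances are
#'   computed.
#' @param cutoff Style-set rating cutoff.
#' @param n_perm Sign-flip permutations for the group-vs-adult comparison.
#' @param canvas,width Rendering canvas (px) and stroke width (px).
#' @param write_pngs Write every drawing as a PNG.
#' @param reuse_cache Reuse `cache.rds` from a previous run in the same
#'   output directory (skips simulation and feature extraction).
#' @param cohort,raters [cohort_params()] / [rater_params()] lists.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_children = 24L, seed = 1L,
                            backbone = c("test", "vgg19"),
                            weights_path = NULL,
                            layer = "fc7", style_layers = "fc7",
                            cutoff = 70, n_perm = 1000L,
                            canvas = 224L, width = 2,
                            write_pngs = FALSE, reuse_cache = FALSE,
                            cohort = cohort_params(),
                            raters = rater_params()) {
  backbone <- match.arg(backbone)
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

strokeless <- function(drawings) {
  dplyr::select(drawings, -dplyr::any_of(c("presented", "produced")))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, aggregates crowd ratings with quality control, scores
#' the questionnaires, extracts backbone features, selects style sets and
#' compares them to adult drawings, builds group RDMs per age group plus the
#' adult RDM with permutation comparisons, builds per-child RDMs and scores,
#' runs the mixed-model likelihood-ratio tests, correlates the RDM score
#' with the completion score, and writes every result as CSV/JSON into
#' `out_dir` together with a run manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  cache_path <- file.path(out_dir, "cache.rds")

  backbone <- run_stage("backbone", {
    if (config$backbone == "test") {
      make_test_backbone(seed = seed + 1000L)
    } else {
      load_pretrained_backbone("vgg19-imagenet", config$weights_path)
    }
  })

  layers_needed <- unique(c(config$layer, config$style_layers))
  if (config$reuse_cache && file.exists(cache_path)) {
    cache <- readRDS(cache_path)
    bundle <- cache$bundle
    feats_produced <- cache$feats_produced
    feats_full <- cache$feats_full
    adult_produced <- cache$adult_produced
    adult_full <- cache$adult_full
  } else {
    bundle <- run_stage(
      "simulate",
      simulate_cohort(config$n_children, config$cohort, config$raters,
        seed = seed
      )
    )
    feats_produced <- run_stage(
      "features",
      compute_drawing_features(bundle$drawings, backbone,
        layers = config$layer,
        produced_only = TRUE, canvas = config$canvas, width = config$width
      )
    )
    feats_full <- run_stage(
      "features",
      compute_drawing_features(bundle$drawings, backbone,
        layers = layers_needed,
        produced_only = FALSE, canvas = config$canvas, width = config$width
      )
    )
    adult_produced <- run_stage(
      "features",
      compute_drawing_features(bundle$adult_drawings, backbone,
        layers = config$layer,
        produced_only = TRUE, canvas = config$canvas, width = config$width
      )
    )
    adult_full <- run_stage(
      "features",
      compute_drawing_features(bundle$adult_drawings, backbone,
        layers = layers_needed,
        produced_only = FALSE, canvas = config$canvas, width = config$width
      )
    )
    saveRDS(
      list(
        bundle = bundle, feats_produced = feats_produced,
        feats_full = feats_full, adult_produced = adult_produced,
        adult_full = adult_full
      ),
      cache_path
    )
  }

  run_stage("write-cohort", {
    readr::write_csv(
      assign_age_groups(bundle$children),
      file.path(out_dir, "children.csv")
    )
    readr::write_csv(
      strokeless(bundle$drawings),
      file.path(out_dir, "drawings.csv")
    )
    readr::write_csv(
      strokeless(bundle$adult_drawings),
      file.path(out_dir, "adult_drawings.csv")
    )
    readr::write_csv(bundle$ratings, file.path(out_dir, "ratings.csv"))
    readr::write_csv(bundle$aq, file.path(out_dir, "aq_sheets.csv"))
    if (config$write_pngs) {
      png_dir <- file.path(out_dir, "drawings")
      dir.create(png_dir, showWarnings = FALSE)
      all_dr <- dplyr::bind_rows(bundle$drawings, bundle$adult_drawings)
      for (i in seq_len(nrow(all_dr))) {
        write_drawing_png(
          rasterize(all_dr[i, ], config$canvas, config$width),
          file.path(png_dir, paste0(all_dr$drawing_id[i], ".png"))
        )
      }
    }
  })

  scores <- run_stage("rate", {
    truth <- strokeless(bundle$drawings)[, c("drawing_id", "category")]
    kept <- qc_filter_raters(bundle$ratings, truth)
    aggregate_drawing_scores(kept,
      empty_drawings = empty_drawing_ids(bundle$drawings),
      all_drawings = bundle$drawings$drawing_id
    )
  })
  readr::write_csv(scores, file.path(out_dir, "score_table.csv"))

  aq_scores <- run_stage("rate", compute_aq(bundle$aq))
  readr::write_csv(aq_scores, file.path(out_dir, "aq_scores.csv"))

  style_sets <- run_stage("styles", select_style_sets(scores, config$cutoff))
  readr::write_csv(
    tidyr::unnest(style_sets, "drawing_ids"),
    file.path(out_dir, "style_sets.csv")
  )
  style_distances <- run_stage("styles", {
    dplyr::bind_rows(lapply(config$style_layers, function(ly) {
      style_vs_adult_distances(
        style_sets,
        feats_full[feats_full$layer == ly, ],
        adult_full[adult_full$layer == ly, ]
      )
    }))
  })
  readr::write_csv(
    dplyr::select(style_distances, -"per_drawing_distances"),
    file.path(out_dir, "style_distances.csv")
  )

  rdm_results <- run_stage("rdm", {
    children <- assign_age_groups(bundle$children)
    drmeta <- strokeless(bundle$drawings)
    drmeta$age_group <- children$age_group[match(drmeta$child_id, children$child_id)]
    adult_rdm <- group_rdm(adult_produced)
    group_rdms <- lapply(1:4, function(g) {
      ids <- drmeta$drawing_id[drmeta$age_group == g]
      feats <- feats_produced[feats_produced$drawing_id %in% ids, ]
      if (nrow(feats) == 0L) {
        message("age group ", g, " has no drawings; RDM skipped")
        return(NULL)
      }
      group_rdm(feats)
    })
    names(group_rdms) <- paste0("age_group_", 1:4)
    for (g in 1:4) {
      if (!is.null(group_rdms[[g]])) {
        write_rdm(
          group_rdms[[g]],
          file.path(out_dir, sprintf("rdm_age_group_%d.csv", g)),
          backbone_id = backbone$spec$backbone_id
        )
      }
    }
    write_rdm(adult_rdm, file.path(out_dir, "rdm_adults.csv"),
      backbone_id = backbone$spec$backbone_id
    )
    comparisons <- dplyr::bind_rows(lapply(1:4, function(g) {
      gr <- group_rdms[[g]]
      if (is.null(gr) || length(gr$labels) < 2L) {
        return(tibble::tibble(
          age_group = g, block_contrast = NA_real_, statistic = NA_real_,
          p = NA_real_, n_pairs = 0L, n_perm = as.integer(config$n_perm)
        ))
      }
      common <- intersect(gr$labels, adult_rdm$labels)
      res <- compare_group_to_adult_rdm(
        subset_rdm(gr, common), subset_rdm(adult_rdm, common),
        n_perm = config$n_perm, seed = seed + 2000L + g
      )
      dplyr::bind_cols(
        tibble::tibble(age_group = g, block_contrast = block_contrast(gr)),
        res
      )
    }))
    comparisons$adult_block_contrast <- block_contrast(adult_rdm)
    # no multiplicity correction across the four groups; flagged here
    comparisons$p_adjusted <- NA_real_
    readr::write_csv(comparisons, file.path(out_dir, "group_comparisons.csv"))
    list(
      adult_rdm = adult_rdm, group_rdms = group_rdms,
      comparisons = comparisons
    )
  })

  per_child <- run_stage("rdm", {
    pc <- child_rdms(bundle,
      backbone = backbone, layer = config$layer,
      features = feats_produced
    )
    dom <- dominant_style(scores, strokeless(bundle$drawings))
    pc <- dplyr::left_join(pc, dom, by = "child_id")
    pc <- dplyr::left_join(pc, assign_age_groups(bundle$children),
      by = "child_id"
    )
    pc
  })
  readr::write_csv(
    dplyr::select(per_child, -"rdm"),
    file.path(out_dir, "per_child_scores.csv")
  )

  stats_results <- run_stage("stats", {
    drmeta <- strokeless(bundle$drawings)
    df <- dplyr::left_join(scores, drmeta, by = "drawing_id")
    df <- dplyr::left_join(df,
      aq_scores[, c("child_id", "scaled_score")],
      by = "child_id"
    )
    lrts <- dplyr::bind_rows(
      dplyr::mutate(
        lrt_fixed_effect(df, "completion",
          test_term = "age_months",
          random_terms = c("child_id", "category", "condition")
        ),
        response = "completion"
      ),
      dplyr::mutate(
        lrt_fixed_effect(df, "scribbling",
          test_term = "age_months",
          random_terms = c("child_id", "category", "condition")
        ),
        response = "scribbling"
      ),
      dplyr::mutate(
        lrt_fixed_effect(df, "completion",
          fixed_terms = "age_months", test_term = "scaled_score",
          random_terms = c("child_id", "category", "condition")
        ),
        response = "completion"
      )
    )
    readr::write_csv(lrts, file.path(out_dir, "lrt_table.csv"))
    corr <- correlate_rdm_completion(per_child)
    readr::write_csv(corr, file.path(out_dir, "rdm_completion_correlation.csv"))
    list(lrts = lrts, correlation = corr)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("drawrsa")),
    seed = seed,
    backbone = backbone$spec$backbone_id,
    layer = config$layer,
    cutoff = config$cutoff,
    n_children = config$n_children,
    n_perm = config$n_perm,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE
  )

  invisible(list(
    bundle = bundle, scores = scores, aq_scores = aq_scores,
    style_sets = style_sets, style_distances = style_distances,
    rdms = rdm_results, per_child = per_child, stats = stats_results,
    manifest = manifest
  ))
}
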