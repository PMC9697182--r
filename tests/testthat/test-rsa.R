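test_that("pearson_distance matches the brute-force correlation oracle", {
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 4)),
    oracle_distance(c(1, 2, 3), c(1, 2, 4)),
    tolerance = 1e-12
  )
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 4)), 0.01801949,
    tolerance = 1e-6
  )
  set.seed(10)
  for (i in 1:50) {
    x <- rnorm(20)
    y <- rnorm(20)
    expect_equal(pearson_distance(x, y), oracle_distance(x, y),
      tolerance = 1e-12
    )
  }
})

test_that("distance identities and affine invariance hold", {
  set.seed(11)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, -x), 2)
  expect_equal(pearson_distance(2.5 * x + 3, y), pearson_distance(x, y),
    tolerance = 1e-12
  )
  expect_equal(pearson_distance(-x, y), 2 - pearson_distance(x, y),
    tolerance = 1e-12
  )
  expect_equal(pearson_distance(x, y), pearson_distance(y, x))
})

test_that("degenerate vectors are rejected or totalized as documented", {
  expect_error(pearson_distance(1:3, 1:4), "length")
  expect_error(pearson_distance(numeric(1), numeric(1)), "length >= 2")
  expect_warning(d <- pearson_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(d, 2)
  expect_warning(d0 <- pearson_distance(c(2, 2), c(2, 2)), "constant")
  expect_equal(d0, 0)
  expect_warning(d2 <- pearson_distance(c(2, 2), c(3, 3)), "constant")
  expect_equal(d2, 2)
})

test_that("group RDMs average within label then take pairwise distances", {
  # hand-built oracle case: 3 labels, 2 vectors each
  feats <- tibble::tibble(
    drawing_id = paste0("d", 1:6),
    stimulus_label = rep(c("face_outline", "car_inner", "house_inner"), each = 2),
    child_id = "c1",
    layer = "fc7",
    feature = list(
      c(1, 2, 3), c(3, 2, 1), # face: mean (2,2,2) -> constant!
      c(1, 0, 0), c(0, 1, 0),
      c(5, 1, 2), c(1, 1, 4)
    )
  )
  expect_warning(rdm <- group_rdm(feats), "constant")
  means <- list(
    face_outline = c(2, 2, 2), car_inner = c(0.5, 0.5, 0),
    house_inner = c(3, 1, 3)
  )
  expect_equal(
    rdm$matrix["car_inner", "house_inner"],
    oracle_distance(means$car_inner, means$house_inner),
    tolerance = 1e-12
  )
  expect_equal(rdm$matrix["face_outline", "car_inner"], 2) # constant mean
  expect_true(drawrsa:::check_rdm(rdm))
})

test_that("a shared identical vector gives an all-zero RDM", {
  feats <- tibble::tibble(
    drawing_id = paste0("d", 1:2),
    stimulus_label = c("face_outline", "car_inner"),
    child_id = "c1", layer = "fc7",
    feature = list(c(1, 5, 2), c(1, 5, 2))
  )
  rdm <- group_rdm(feats)
  expect_equal(dim(rdm$matrix), c(2L, 2L))
  expect_equal(max(abs(rdm$matrix)), 0)
})

test_that("group RDMs name the missing label when a stimulus has no features", {
  feats <- tibble::tibble(
    drawing_id = "d1", stimulus_label = "face_outline",
    child_id = "c1", layer = "fc7", feature = list(c(1, 2, 3))
  )
  expect_error(
    group_rdm(feats, labels = c("face_outline", "car_inner")),
    "car_inner"
  )
})

test_that("rdm_score is the mean off-diagonal entry", {
  m <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_equal(rdm_score(m), 0.3)
  expect_equal(rdm_score(matrix(0, 3, 3)), 0)
  m3 <- matrix(0, 3, 3)
  m3[lower.tri(m3)] <- c(0.2, 0.4, 0.6)
  m3 <- m3 + t(m3)
  expect_equal(rdm_score(m3), 0.4)
  expect_error(rdm_score(matrix(0, 1, 1)), "size >= 2")
})

test_that("children who saw fewer than six stimuli are excluded", {
  b <- simulate_cohort(2, seed = 8)
  bb <- make_test_backbone(2)
  partial <- b$drawings[b$drawings$child_id == "c001", ][1:4, ]
  expect_message(
    expect_null(child_rdm(partial, bb)),
    "excluded"
  )
  full <- b$drawings[b$drawings$child_id == "c001", ]
  rdm <- child_rdm(full, bb)
  expect_equal(dim(rdm$matrix), c(6L, 6L))
  expect_true(drawrsa:::check_rdm(rdm))
})

test_that("a child repeating identical strokes scores near zero", {
  agent <- make_agent("complete", alpha = 0) # always the fixed motif
  set.seed(4)
  sets <- build_drawing_sets(1)
  drawings <- dplyr::bind_rows(lapply(sets[[1]], function(st) {
    simulate_drawing(agent, st)
  }))
  bb <- make_test_backbone(2)
  rdm <- child_rdm(drawings, bb)
  expect_lt(rdm_score(rdm), 1e-8)
})

test_that("stimulus-adaptive completers outscore motif repeaters", {
  bb <- make_test_backbone(1001)
  sets <- build_drawing_sets(1)
  set.seed(12)
  wins <- vapply(1:8, function(i) {
    adaptive <- make_agent("complete", alpha = 1, motif_seed = i, child_id = "a")
    repeater <- make_agent("complete", alpha = 0, motif_seed = i, child_id = "r")
    d_a <- dplyr::bind_rows(lapply(sets[[1 + i %% 4]], simulate_drawing, agent = adaptive))
    d_r <- dplyr::bind_rows(lapply(sets[[1 + i %% 4]], simulate_drawing, agent = repeater))
    rdm_score(child_rdm(d_a, bb)) > rdm_score(child_rdm(d_r, bb))
  }, logical(1))
  expect_true(all(wins))
})

test_that("block contrast is between minus within category distance", {
  labels <- c("face_outline", "face_inner", "car_outline", "car_inner")
  m <- matrix(0.5, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.1
  m[3, 4] <- m[4, 3] <- 0.1
  diag(m) <- 0
  rdm <- drawrsa:::new_rdm(m, labels, "fc7", TRUE)
  expect_equal(block_contrast(rdm), 0.4)
  expect_error(
    block_contrast(drawrsa:::new_rdm(m, rep("face", 4), "fc7", TRUE)),
    "two categories"
  )
})

test_that("label-permuted RDMs have expected contrast near zero", {
  set.seed(13)
  v <- lapply(1:12, function(i) rnorm(40))
  labels <- names(all_stimuli())
  rdm <- drawrsa:::rdm_from_vectors(v, labels, "fc7", TRUE)
  perms <- replicate(400, {
    block_contrast(rdm, categories = sample(sub("_.*$", "", labels)))
  })
  se <- stats::sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms)), 4 * se + 1e-3)
})

test_that("group block contrast increases with the cohort adaptation level", {
  bb <- make_test_backbone(1001)
  contrast_at <- function(alpha_logit, seed) {
    p <- cohort_params(
      alpha_intercept = alpha_logit, alpha_slope = 0,
      alpha_concentration = 400
    )
    b <- simulate_cohort(36, p, seed = seed)
    feats <- compute_drawing_features(b$drawings, bb, "fc7", TRUE)
    block_contrast(group_rdm(feats))
  }
  c0 <- contrast_at(-50, 31) # alpha ~ 0
  c5 <- contrast_at(0, 31) # alpha ~ 0.5
  c1 <- contrast_at(50, 31) # alpha ~ 1
  expect_lt(c0, c5)
  expect_lt(c5, c1)
})

test_that("style sets apply the strict cutoff and report empties", {
  scores <- tibble::tibble(
    drawing_id = c("a", "b", "c", "d"),
    completion = c(70, 70.01, 90, NA),
    scribbling = c(10, 20, 0, 50),
    tracing = c(0, 0, 0, 0),
    coloring = c(80, 0, 0, 0),
    relatedness = 0, n_raters_used = 5L
  )
  expect_message(sets <- select_style_sets(scores, 70), "tracing")
  expect_setequal(
    sets$drawing_ids[[which(sets$style == "completion")]],
    c("b", "c")
  )
  expect_equal(sets$n[sets$style == "tracing"], 0L)
  expect_setequal(sets$drawing_ids[[which(sets$style == "coloring")]], "a")
  all_in <- select_style_sets(scores, 0)
  expect_setequal(
    all_in$drawing_ids[[which(all_in$style == "scribbling")]],
    c("a", "b", "d")
  )
})

test_that("style-vs-adult distances use same-stimulus pairs only", {
  feats <- function(ids, labels, vecs) {
    tibble::tibble(
      drawing_id = ids, stimulus_label = labels, child_id = ids,
      layer = "fc7", feature = vecs
    )
  }
  child <- feats(
    c("k1", "k2"), c("face_outline", "car_inner"),
    list(c(1, 2, 3), c(3, 1, 2))
  )
  adult <- feats(
    c("a1", "a2"), c("face_outline", "face_outline"),
    list(c(1, 2, 3), c(2, 4, 6))
  )
  sets <- tibble::tibble(
    style = "completion", cutoff = 70, n = 2L,
    drawing_ids = list(c("k1", "k2"))
  )
  expect_message(
    out <- style_vs_adult_distances(sets, child, adult),
    "skipped"
  )
  # k1 is an exact duplicate (and a scaled copy) of the adult drawings
  expect_equal(out$mean, 0)
  expect_equal(out$n, 1L)
})

test_that("RDM CSV round trip preserves matrix and metadata", {
  set.seed(14)
  v <- lapply(1:4, function(i) rnorm(10))
  rdm <- drawrsa:::rdm_from_vectors(
    v, c("face_outline", "face_inner", "car_outline", "car_inner"), "pool3", TRUE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_rdm(rdm, path, backbone_id = "test-cnn")
  back <- read_rdm(path)
  expect_equal(back$matrix, rdm$matrix, tolerance = 1e-12)
  expect_identical(back$labels, rdm$labels)
  expect_identical(back$layer, "pool3")
  expect_true(back$produced_only)
})

test_that("tidy and autoplot expose the RDM in long form", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  rdm <- drawrsa:::new_rdm(m, c("a", "b"), "fc7", TRUE)
  td <- tidy(rdm)
  expect_equal(nrow(td), 4L)
  expect_equal(td$distance[td$row == "a" & td$col == "b"], 0.5)
  expect_s3_class(autoplot(rdm), "ggplot")
})
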