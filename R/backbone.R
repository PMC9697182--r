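# Pluggable convolutional feature extractor. Every backbone exposes the same
# seven analysis layers (pool1..pool5 after each conv/pool block, fc6/fc7
# after the two fully connected layers), so the analysis pipeline is
# independent of the concrete network. A small seed-deterministic test
# backbone makes the whole pipeline runnable without pretrained weights.

#' Backbone specification
#'
#' @param backbone_id Identifier string.
#' @param channel_means Per-channel means subtracted during preprocessing
#'   (0-255 scale), in `channel_order`.
#' @param channel_order Channel permutation applied before mean subtraction
#'   (`c(1, 2, 3)` keeps RGB; `c(3, 2, 1)` converts to BGR).
#' @param input_size Spatial input size.
#' @return A list of class `backbone_spec` with the fixed layer taxonomy.
#' @export
backbone_spec <- function(backbone_id, channel_means, channel_order = c(1L, 2L, 3L),
                          input_size = c(224L, 224L, 3L)) {
  structure(
    list(
      backbone_id = backbone_id,
      layer_names = ANALYSIS_LAYERS,
      input_size = input_size,
      channel_means = channel_means,
      channel_order = channel_order
    ),
    class = "backbone_spec"
  )
}

#' Spec of the deterministic test backbone
#'
#' Channel means sit near the white background level of rendered drawings,
#' so inputs are roughly centered.
#'
#' @return A `backbone_spec`.
#' @export
test_backbone_spec <- function() {
  backbone_spec("test-cnn", channel_means = c(245, 245, 245))
}

# x: H x W x Cin array; w: 3 x 3 x Cin x Cout array; zero "same" padding.
conv3x3 <- function(x, w, bias = NULL) {
  d <- dim(x)
  h <- d[1]
  wd <- d[2]
  cin <- d[3]
  cout <- dim(w)[4]
  xp <- array(0, dim = c(h + 2L, wd + 2L, cin))
  xp[2:(h + 1L), 2:(wd + 1L), ] <- x
  out <- matrix(0, h * wd, cout)
  for (di in 0:2) {
    for (dj in 0:2) {
      slab <- xp[(1:h) + di, (1:wd) + dj, , drop = FALSE]
      dim(slab) <- c(h * wd, cin)
      wk <- matrix(w[di + 1L, dj + 1L, , ], cin, cout)
      out <- out + slab %*% wk
    }
  }
  if (!is.null(bias)) out <- sweep(out, 2L, bias, "+")
  array(out, dim = c(h, wd, cout))
}

# 2 x 2 max pooling, stride 2 (even H, W).
maxpool2 <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  pmax(
    x[io, jo, , drop = FALSE], x[io + 1L, jo, , drop = FALSE],
    x[io, jo + 1L, , drop = FALSE], x[io + 1L, jo + 1L, , drop = FALSE]
  )
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Build the deterministic test backbone
#'
#' A narrow VGG-style network: five conv(3x3)+ReLU+maxpool(2x2) blocks with
#' 4, 8, 8, 16, 16 channels, followed by two fully connected layers of 128
#' units with ReLU. Weights are random (He-scaled Gaussians) but fully
#' determined by `seed`, so features are reproducible without any download.
#' Random convolutional features preserve enough image geometry to support
#' relative dissimilarity comparisons at desk scale.
#'
#' @param seed Integer seed fixing the weights.
#' @return An object of class `drawing_backbone` exposing the seven analysis
#'   layers via [extract_features()].
#' @export
make_test_backbone <- function(seed = 1L) {
  channels <- c(3L, 4L, 8L, 8L, 16L, 16L)
  fc_units <- 128L
  withr::with_seed(as.integer(seed), {
    convs <- lapply(1:5, function(b) {
      cin <- channels[b]
      cout <- channels[b + 1L]
      array(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
        dim = c(3L, 3L, cin, cout)
      )
    })
    flat <- 7L * 7L * channels[6L]
    fc6 <- matrix(stats::rnorm(flat * fc_units, 0, sqrt(2 / flat)), flat, fc_units)
    fc7 <- matrix(stats::rnorm(fc_units^2, 0, sqrt(2 / fc_units)), fc_units, fc_units)
  })
  structure(
    list(
      spec = test_backbone_spec(),
      blocks = lapply(convs, function(w) list(list(w = w, b = NULL))),
      fc6 = fc6, fc6_bias = NULL, fc7 = fc7, fc7_bias = NULL,
      seed = as.integer(seed)
    ),
    class = "drawing_backbone"
  )
}

#' @export
print.drawing_backbone <- function(x, ...) {
  cat(
    "<drawing_backbone> ", x$spec$backbone_id, ", layers: ",
    paste(x$spec$layer_names, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

# Forward pass collecting the requested analysis layers (post-activation).
forward_backbone <- function(backbone, input, layers) {
  unknown <- setdiff(layers, backbone$spec$layer_names)
  if (length(unknown) > 0L) {
    stop("unknown backbone layer(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  d <- dim(input)
  if (!identical(as.integer(d), as.integer(backbone$spec$input_size))) {
    stop(
      "input shape (", paste(d, collapse = "x"),
      ") does not match backbone input size (",
      paste(backbone$spec$input_size, collapse = "x"), ")",
      call. = FALSE
    )
  }
  out <- list()
  x <- unclass(input)
  pool_layers <- paste0("pool", 1:5)
  last_pool <- max(c(0L, which(pool_layers %in% layers)))
  need_fc <- any(c("fc6", "fc7") %in% layers)
  for (b in 1:5) {
    if (!need_fc && b > last_pool) break
    for (cv in backbone$blocks[[b]]) {
      x <- relu(conv3x3(x, cv$w, cv$b))
    }
    x <- maxpool2(x)
    lname <- pool_layers[b]
    if (lname %in% layers) out[[lname]] <- as.numeric(x)
  }
  if (need_fc) {
    v <- as.numeric(x) %*% backbone$fc6
    if (!is.null(backbone$fc6_bias)) v <- v + backbone$fc6_bias
    v <- relu(as.numeric(v))
    if ("fc6" %in% layers) out[["fc6"]] <- v
    if ("fc7" %in% layers) {
      v7 <- v %*% backbone$fc7
      if (!is.null(backbone$fc7_bias)) v7 <- v7 + backbone$fc7_bias
      out[["fc7"]] <- relu(as.numeric(v7))
    }
  }
  out[layers]
}

#' Extract features of one preprocessed image
#'
#' Runs the backbone forward and returns the flattened post-activation
#' values of the named analysis layer. Deterministic for fixed weights.
#'
#' @param backbone A `drawing_backbone`.
#' @param input A `backbone_input` array from [preprocess_for_backbone()].
#' @param layer One of `pool1`..`pool5`, `fc6`, `fc7`.
#' @return A numeric feature vector.
#' @export
extract_features <- function(backbone, input, layer = "fc7") {
  stopifnot(length(layer) == 1L)
  forward_backbone(backbone, input, layer)[[1L]]
}

#' Load a pretrained VGG19 backbone
#'
#' Builds the full VGG19 feature extractor (16 convolutions, 5 poolings, two
#' 4096-unit fully connected layers) from a local weights file, exposing the
#' same seven analysis layers as the test backbone. The weights file is an
#' RDS list with elements `convs` (sixteen 3x3xCinxCout arrays),
#' `conv_biases`, `fc6`, `fc6_bias`, `fc7`, `fc7_bias`, as exported from any
#' framework's pretrained model. No download is attempted.
#'
#' @param name Backbone name; only `"vgg19-imagenet"` is recognized.
#' @param weights_path Path to the local weights RDS file.
#' @return A `drawing_backbone` of class `c("vgg19_backbone",
#'   "drawing_backbone")`.
#' @export
load_pretrained_backbone <- function(name = "vgg19-imagenet", weights_path = NULL) {
  if (!identical(name, "vgg19-imagenet")) {
    stop("unknown pretrained backbone: ", name, call. = FALSE)
  }
  if (is.null(weights_path) || !file.exists(weights_path)) {
    stop(
      "pretrained VGG19 weights not available locally. ",
      "For fully offline use, run the pipeline with make_test_backbone() ",
      "instead, or point weights_path at an exported weights RDS file.",
      call. = FALSE
    )
  }
  w <- readRDS(weights_path)
  stopifnot(length(w$convs) == 16L)
  layout <- c(2L, 2L, 4L, 4L, 4L)
  idx <- split(seq_len(16L), rep(seq_len(5L), layout))
  blocks <- lapply(idx, function(ii) {
    lapply(ii, function(i) list(w = w$convs[[i]], b = w$conv_biases[[i]]))
  })
  structure(
    list(
      spec = backbone_spec("vgg19-imagenet",
        channel_means = c(103.939, 116.779, 123.68),
        channel_order = c(3L, 2L, 1L)
      ),
      blocks = blocks,
      fc6 = w$fc6, fc6_bias = w$fc6_bias,
      fc7 = w$fc7, fc7_bias = w$fc7_bias
    ),
    class = c("vgg19_backbone", "drawing_backbone")
  )
}

#' Feature table for a set of drawings
#'
#' Renders each drawing (produced-only or full, per `produced_only`),
#' preprocesses it and extracts the requested layers in one forward pass per
#' drawing.
#'
#' @param drawings A drawings tibble ([simulate_cohort()]).
#' @param backbone A `drawing_backbone`.
#' @param layers Character vector of analysis layers.
#' @param produced_only If `TRUE` the presented layer is removed before
#'   feature extraction; if `FALSE` the full recolored drawing is used.
#' @param canvas,width Rendering parameters ([rasterize()]).
#' @return A tibble with `drawing_id`, `stimulus_label`, `child_id`,
#'   `layer`, and a list-column `feature`.
#' @export
compute_drawing_features <- function(drawings, backbone, layers = "fc7",
                                     produced_only = TRUE,
                                     canvas = 224L, width = 2) {
  rows <- lapply(seq_len(nrow(drawings)), function(i) {
    dr <- drawings[i, ]
    img <- if (produced_only) {
      produced_only_image(dr, canvas, width)
    } else {
      full_drawing_image(dr, canvas, width)
    }
    feats <- forward_backbone(
      backbone, preprocess_for_backbone(img, backbone$spec), layers
    )
    tibble::tibble(
      drawing_id = dr$drawing_id,
      stimulus_label = dr$stimulus_label,
      child_id = dr$child_id,
      layer = layers,
      feature = unname(feats)
    )
  })
  dplyr::bind_rows(rows)
}
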