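# Rasterization and the exact preprocessing applied before feature
# extraction: layer merge, blue-to-black recoloring, presented-part removal,
# bilinear resize to the backbone input size and channel-mean subtraction.

RENDER_BLACK <- c(0L, 0L, 0L)
RENDER_BLUE <- c(0L, 0L, 255L)
RENDER_WHITE <- c(255L, 255L, 255L)

# Pixel centers covered by a polyline stamped with a disk of radius r px.
stroke_pixels <- function(stroke, canvas, width) {
  pts <- stroke * (canvas - 1) + 1 # unit -> pixel coordinates
  if (nrow(pts) > 1L) {
    dense <- lapply(seq_len(nrow(pts) - 1L), function(i) {
      a <- pts[i, ]
      b <- pts[i + 1L, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 0.5))
      cbind(seq(a[1], b[1], length.out = n), seq(a[2], b[2], length.out = n))
    })
    pts <- do.call(rbind, dense)
  }
  r <- width / 2
  ri <- ceiling(r)
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  px <- round(pts[, 1])
  py <- round(pts[, 2])
  x <- rep(px, times = nrow(off)) + rep(off$dx, each = length(px))
  y <- rep(py, times = nrow(off)) + rep(off$dy, each = length(py))
  keep <- x >= 1 & x <= canvas & y >= 1 & y <= canvas
  # array row = y measured from the top, so written PNGs have y up on screen
  row <- canvas - y[keep] + 1
  col <- x[keep]
  unique(row + (col - 1) * canvas)
}

paint <- function(img, strokes, canvas, width, rgb) {
  if (length(strokes) == 0L) {
    return(img)
  }
  idx <- unique(unlist(lapply(strokes, stroke_pixels, canvas = canvas, width = width)))
  npix <- canvas * canvas
  img[idx] <- rgb[1]
  img[idx + npix] <- rgb[2]
  img[idx + 2L * npix] <- rgb[3]
  img
}

#' Rasterize a drawing
#'
#' Renders the selected stroke layers of a drawing onto a white square
#' canvas: presented strokes in black, produced strokes in blue, with a
#' fixed stroke width. Rendering is deterministic.
#'
#' @param drawing A one-row drawing tibble ([simulate_drawing()]).
#' @param canvas Canvas side length in pixels.
#' @param width Stroke width in pixels (default 3 at the default 512 canvas;
#'   scaled widths should be passed explicitly for other canvas sizes).
#' @param include_presented,include_produced Which layers to render; at
#'   least one must be `TRUE`. An included but empty layer simply leaves the
#'   canvas white.
#' @return A `canvas x canvas x 3` integer array with values 0-255, of class
#'   `raster_image`.
#' @export
rasterize <- function(drawing, canvas = 512L, width = 3,
                      include_presented = TRUE, include_produced = TRUE) {
  if (!include_presented && !include_produced) {
    stop("at least one of include_presented/include_produced must be TRUE",
      call. = FALSE
    )
  }
  canvas <- as.integer(canvas)
  img <- array(255L, dim = c(canvas, canvas, 3L))
  if (include_presented) {
    img <- paint(img, drawing$presented[[1L]], canvas, width, RENDER_BLACK)
  }
  if (include_produced) {
    img <- paint(img, drawing$produced[[1L]], canvas, width, RENDER_BLUE)
  }
  structure(img, class = "raster_image")
}

#' Recolor blue strokes to black
#'
#' Turns every blue pixel black so that the distinction between presented
#' and produced strokes disappears before feature extraction. Blue is
#' detected by channel dominance (`B > R + margin` and `B > G + margin`),
#' which matches the renderer's pure blue exactly and tolerates
#' anti-aliased external scans. Idempotent; all other pixels are unchanged.
#'
#' @param image A `raster_image` array.
#' @param margin Dominance margin in intensity units.
#' @return The recolored `raster_image`.
#' @export
recolor_blue_to_black <- function(image, margin = 40L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  blue <- image[, , 3L] > image[, , 1L] + margin &
    image[, , 3L] > image[, , 2L] + margin
  if (any(blue)) {
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[blue] <- 0L
      image[, , ch] <- plane
    }
  }
  image
}

#' Produced-strokes-only image
#'
#' Renders only the strokes the participant produced (the presented layer is
#' dropped at the stroke level, not by pixel subtraction) and recolors them
#' black. Used for comparisons of how one participant drew on different
#' stimuli.
#'
#' @inheritParams rasterize
#' @return A `raster_image` with only produced ink, in black.
#' @export
produced_only_image <- function(drawing, canvas = 512L, width = 3) {
  recolor_blue_to_black(
    rasterize(drawing, canvas, width,
      include_presented = FALSE, include_produced = TRUE
    )
  )
}

#' Full-drawing image
#'
#' Renders both layers and recolors blue to black: the variant used when two
#' participants' drawings on the same presented stimulus are compared.
#'
#' @inheritParams rasterize
#' @return A `raster_image` with presented and produced ink, all black.
#' @export
full_drawing_image <- function(drawing, canvas = 512L, width = 3) {
  recolor_blue_to_black(rasterize(drawing, canvas, width))
}

#' Preprocess an image for a backbone
#'
#' Bilinearly resizes the image to the backbone's input size (224 x 224) and
#' subtracts the backbone's per-channel means, in the backbone's channel
#' order. Deterministic.
#'
#' @param image A `raster_image` array (0-255).
#' @param spec A backbone spec ([backbone_spec()]), providing `input_size`,
#'   `channel_means` and `channel_order`.
#' @return A `224 x 224 x 3` double array of class `backbone_input`.
#' @export
preprocess_for_backbone <- function(image, spec = test_backbone_spec()) {
  d <- dim(image)
  if (length(d) != 3L || d[1] < 1L || d[2] < 1L || d[3] != 3L) {
    stop("image must be a nonempty H x W x 3 array", call. = FALSE)
  }
  h <- spec$input_size[1]
  w <- spec$input_size[2]
  x <- array(as.double(image), dim = d)
  if (d[1] != h || d[2] != w) {
    # EBImage stores images x (width) first; square in/out so a plain
    # dimension swap round-trips exactly
    xi <- EBImage::Image(aperm(x / 255, c(2L, 1L, 3L)), colormode = "Color")
    x <- aperm(EBImage::imageData(
      EBImage::resize(xi, w = w, h = h, filter = "bilinear")
    ), c(2L, 1L, 3L)) * 255
  }
  x <- x[, , spec$channel_order, drop = FALSE]
  for (ch in 1:3) x[, , ch] <- x[, , ch] - spec$channel_means[ch]
  structure(x, class = "backbone_input", backbone_id = spec$backbone_id)
}

#' Write a raster image as PNG
#'
#' @param image A `raster_image` array (0-255).
#' @param path Output file path.
#' @export
write_drawing_png <- function(image, path) {
  png::writePNG(array(as.double(image) / 255, dim = dim(image)), target = path)
  invisible(path)
}

#' Read a PNG as a raster image
#'
#' @param path PNG file path.
#' @return A `raster_image` integer array (0-255); an alpha channel, if
#'   present, is dropped.
#' @export
read_drawing_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  structure(
    array(as.integer(round(x[, , 1:3] * 255)), dim = c(dim(x)[1:2], 3L)),
    class = "raster_image"
  )
}
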