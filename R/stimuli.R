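#' @useDynLib numspike, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom runif sd median aggregate cor.test dist
#' @importFrom utils write.csv read.csv
NULL

# Integer offsets of a centred disk covering exactly 25 pixels
# (all (dx, dy) with dx^2 + dy^2 <= 8.5).
disk_offsets <- function() {
  g <- expand.grid(dx = -2:2, dy = -2:2)
  g[g$dx^2 + g$dy^2 <= 8.5, , drop = FALSE]
}

DISK_AREA <- 25L         # pixels per item
IMG_SIDE  <- 28L         # image side length in pixels
PLACEMENT_MARGIN <- 3L   # minimum distance of a disk centre from the frame
MIN_CENTER_DIST  <- 6    # centre-to-centre distance guaranteeing disjoint masks
MAX_PLACEMENT_ATTEMPTS <- 10000L

#' Construct a stimulus image
#'
#' @param pixels 28 x 28 numeric matrix with intensities in `[0, 1]`.
#' @param label integer class label (numerosity 1-5 or digit 0-9).
#' @param kind `"numerosity"` or `"digit"`.
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(pixels, label, kind = c("numerosity", "digit")) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  if (!all(dim(pixels) == c(IMG_SIDE, IMG_SIDE)))
    stop("pixels must be a ", IMG_SIDE, "x", IMG_SIDE, " matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]")
  structure(list(pixels = pixels, label = as.integer(label), kind = kind),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image> kind=%s label=%d, %d foreground px (>0)\n",
              x$kind, x$label, sum(x$pixels > 0)))
  invisible(x)
}

#' Render one non-symbolic numerosity image
#'
#' Draws `n` disjoint disks of exactly 25 pixels each (intensity 1.0) on a
#' zero background, with uniform-random centres, rejection sampling against
#' overlap, and a margin keeping every disk fully inside the frame.
#'
#' @param n numerosity, an integer in 1..5.
#' @param seed integer seed; the image is deterministic given `(n, seed)`.
#' @return A `stimulus_image` of kind `"numerosity"` whose foreground pixel
#'   count equals `25 * n` exactly.
#' @export
render_numerosity_image <- function(n, seed) {
  if (length(n) != 1 || is.na(n) || n != as.integer(n) || n < 1 || n > 5)
    stop("invalid argument: numerosity n must be an integer in 1..5")
  set.seed(as.integer(seed))
  lo <- PLACEMENT_MARGIN + 1L
  hi <- IMG_SIDE - PLACEMENT_MARGIN
  centers <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  while (nrow(centers) < n) {
    attempts <- attempts + 1L
    if (attempts > MAX_PLACEMENT_ATTEMPTS)
      stop("placement error: could not place ", n,
           " disjoint items in ", MAX_PLACEMENT_ATTEMPTS, " attempts")
    cand <- c(sample(lo:hi, 1L), sample(lo:hi, 1L))
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (any(d < MIN_CENTER_DIST)) next
    }
    centers <- rbind(centers, cand)
  }
  px <- matrix(0, IMG_SIDE, IMG_SIDE)
  off <- disk_offsets()
  for (k in seq_len(n)) {
    rows <- centers[k, 1] + off$dx
    cols <- centers[k, 2] + off$dy
    px[cbind(rows, cols)] <- 1
  }
  stimulus_image(px, n, "numerosity")
}

#' Generate the non-symbolic numerosity dataset
#'
#' Produces `5 * images_per_class` dot-display images, numerosities 1..5 in
#' balanced counts. Per-image seeds are derived from the master seed up
#' front, so regeneration with the same seed is bit-identical.
#'
#' @param images_per_class images per numerosity (default 30, i.e. 150 total).
#' @param seed master integer seed.
#' @return An object of class `stimulus_dataset`.
#' @export
generate_numerosity_dataset <- function(images_per_class = 30, seed = 1) {
  if (images_per_class < 1) stop("images_per_class must be >= 1")
  labels <- rep(1:5, each = images_per_class)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, length(labels))
  images <- Map(render_numerosity_image, labels, sub_seeds)
  structure(list(images = images, images_per_class = as.integer(images_per_class),
                 seed = as.integer(seed), kind = "numerosity"),
            class = "stimulus_dataset")
}

#' Generate a dataset of synthetic digit glyphs
#'
#' A no-download stand-in emulating the handwritten-digit format: 28 x 28
#' grayscale glyphs of the digits 0-9 with seed-controlled jitter. This is a
#' synthetic test double, not real handwriting.
#'
#' @inheritParams generate_numerosity_dataset
#' @return A `stimulus_dataset` of kind `"digit"` with `10 * images_per_class`
#'   images.
#' @export
generate_digit_dataset <- function(images_per_class = 30, seed = 1) {
  if (images_per_class < 1) stop("images_per_class must be >= 1")
  labels <- rep(0:9, each = images_per_class)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, length(labels))
  images <- Map(render_digit_fixture, labels, sub_seeds)
  structure(list(images = images, images_per_class = as.integer(images_per_class),
                 seed = as.integer(seed), kind = "digit"),
            class = "stimulus_dataset")
}

#' @export
print.stimulus_dataset <- function(x, ...) {
  cat(sprintf("<stimulus_dataset> kind=%s, %d images (%d per class), seed=%d\n",
              x$kind, length(x$images), x$images_per_class, x$seed))
  invisible(x)
}

#' Extract the label vector of a dataset
#' @param dataset a `stimulus_dataset`.
#' @return Integer vector of class labels, one per image.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$images, function(im) im$label, integer(1))
}

# Seven-segment geometry used by the digit fixture, in (row, col) image
# coordinates. Segment endpoints are for a glyph box of height 16, width 8,
# top-left at (6, 10) before jitter.
segment_table <- function(top = 6, left = 10, h = 16, w = 8) {
  mid <- top + h / 2
  bot <- top + h
  right <- left + w
  list(
    a = c(top, left, top, right),
    b = c(top, right, mid, right),
    c = c(mid, right, bot, right),
    d = c(bot, left, bot, right),
    e = c(mid, left, bot, left),
    f = c(top, left, mid, left),
    g = c(mid, left, mid, right)
  )
}

digit_segments <- list(
  `0` = c("a", "b", "c", "d", "e", "f"),
  `1` = c("b", "c"),
  `2` = c("a", "b", "g", "e", "d"),
  `3` = c("a", "b", "g", "c", "d"),
  `4` = c("f", "g", "b", "c"),
  `5` = c("a", "f", "g", "c", "d"),
  `6` = c("a", "f", "g", "e", "c", "d"),
  `7` = c("a", "b", "c"),
  `8` = c("a", "b", "c", "d", "e", "f", "g"),
  `9` = c("a", "b", "c", "d", "f", "g")
)

# Distance from each pixel centre to a line segment, vectorised over pixels.
point_segment_dist <- function(pr, pc, seg) {
  r1 <- seg[1]; c1 <- seg[2]; r2 <- seg[3]; c2 <- seg[4]
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- vr^2 + vc^2
  t <- ((pr - r1) * vr + (pc - c1) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pr - (r1 + t * vr))^2 + (pc - (c1 + t * vc))^2)
}

#' Render a synthetic digit glyph
#'
#' Draws the digit as a stroke (seven-segment) glyph with an anti-aliased
#' edge, random integer translation of at most 2 px and mild stroke-thickness
#' jitter. Deterministic given `(digit, seed)`.
#'
#' @param digit integer in 0..9.
#' @param seed integer seed.
#' @return A `stimulus_image` of kind `"digit"` with intensities in `[0, 1]`.
#' @export
render_digit_fixture <- function(digit, seed) {
  if (length(digit) != 1 || is.na(digit) || digit != as.integer(digit) ||
      digit < 0 || digit > 9)
    stop("invalid argument: digit must be an integer in 0..9")
  set.seed(as.integer(seed))
  dr <- sample(-2:2, 1L)
  dc <- sample(-2:2, 1L)
  half_thick <- runif(1, 0.8, 1.3)
  segs <- segment_table(top = 6 + dr, left = 10 + dc)
  use <- digit_segments[[as.character(digit)]]
  idx <- expand.grid(r = 1:IMG_SIDE, c = 1:IMG_SIDE)
  dmin <- rep(Inf, nrow(idx))
  for (s in use)
    dmin <- pmin(dmin, point_segment_dist(idx$r, idx$c, segs[[s]]))
  inten <- pmin(pmax(1 - (dmin - half_thick), 0), 1)
  px <- matrix(inten, IMG_SIDE, IMG_SIDE)
  stimulus_image(px, digit, "digit")
}

#' Export a stimulus dataset to PNG files plus a CSV manifest
#'
#' @param dataset a `stimulus_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame (filename, label, kind, seed).
#' @export
export_stimuli <- function(dataset, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to export PNG stimuli")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%04d_label%d.png", dataset$kind,
                   seq_along(dataset$images), dataset_labels(dataset))
  for (i in seq_along(dataset$images))
    png::writePNG(dataset$images[[i]]$pixels, file.path(dir, files[i]))
  manifest <- data.frame(filename = files, label = dataset_labels(dataset),
                         kind = dataset$kind, seed = dataset$seed)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
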