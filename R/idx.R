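IDX_MAGIC_IMAGES <- 2051L  # 0x00000803: unsigned byte, 3 dimensions
IDX_MAGIC_LABELS <- 2049L  # 0x00000801: unsigned byte, 1 dimension

read_idx_header <- function(con, expected_magic, n_dims, path) {
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(magic) != 1 || is.na(magic) || magic != expected_magic)
    stop(sprintf("format error in '%s': bad magic number %s (expected %d)",
                 path, ifelse(length(magic) == 1, magic, "<missing>"),
                 expected_magic))
  dims <- readBin(con, "integer", n = n_dims, size = 4, endian = "big")
  if (length(dims) != n_dims || anyNA(dims) || any(dims < 0))
    stop(sprintf("format error in '%s': truncated or invalid dimension header",
                 path))
  dims
}

#' Read an IDX image file
#'
#' Reads 28 x 28 unsigned-byte image planes from the IDX binary format used
#' to distribute handwritten-digit datasets (magic 0x00000803, big-endian
#' dimensions) and rescales bytes to intensities in `[0, 1]` by division
#' by 255.
#'
#' @param path path to an IDX image file.
#' @return A numeric array of dimension `c(n, rows, cols)`.
#' @export
read_idx_images <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  dims <- read_idx_header(con, IDX_MAGIC_IMAGES, 3L, path)
  n <- dims[1]; nr <- dims[2]; nc <- dims[3]
  raw_px <- readBin(con, "integer", n = n * nr * nc, size = 1, signed = FALSE)
  if (length(raw_px) != n * nr * nc)
    stop(sprintf("format error in '%s': pixel data truncated (%d of %d bytes)",
                 path, length(raw_px), n * nr * nc))
  # IDX stores each image row-major: byte order is (col fastest, then row,
  # then image); permute to an (image, row, col) array
  arr <- aperm(array(raw_px, dim = c(nc, nr, n)), c(3L, 2L, 1L))
  arr / 255
}

#' Read an IDX label file
#'
#' @param path path to an IDX label file (magic 0x00000801).
#' @return Integer vector of labels.
#' @export
read_idx_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  dims <- read_idx_header(con, IDX_MAGIC_LABELS, 1L, path)
  labels <- readBin(con, "integer", n = dims[1], size = 1, signed = FALSE)
  if (length(labels) != dims[1])
    stop(sprintf("format error in '%s': label data truncated", path))
  labels
}

#' Write images to an IDX file
#'
#' Counterpart of [read_idx_images()], mainly used to build round-trip test
#' fixtures. Intensities in `[0, 1]` are quantised to bytes by `round(x*255)`.
#'
#' @param images numeric array `c(n, rows, cols)` or list of `stimulus_image`.
#' @param path output path.
#' @export
write_idx_images <- function(images, path) {
  if (is.list(images))
    images <- simplify2array_images(images)
  n <- dim(images)[1]; nr <- dim(images)[2]; nc <- dim(images)[3]
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(IDX_MAGIC_IMAGES, n, nr, nc), con, size = 4, endian = "big")
  for (i in seq_len(n)) {
    block <- as.integer(round(t(images[i, , ]) * 255))
    writeBin(as.raw(pmin(pmax(block, 0L), 255L)), con)
  }
  invisible(path)
}

simplify2array_images <- function(lst) {
  arr <- array(0, dim = c(length(lst), IMG_SIDE, IMG_SIDE))
  for (i in seq_along(lst)) arr[i, , ] <- lst[[i]]$pixels
  arr
}

#' Write labels to an IDX file
#' @param labels integer vector.
#' @param path output path.
#' @export
write_idx_labels <- function(labels, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(IDX_MAGIC_LABELS, length(labels)), con, size = 4, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  invisible(path)
}

#' Load a digit dataset from paired IDX image/label files
#'
#' @param images_path,labels_path paths to the IDX image and label files.
#' @param per_class if not `NULL`, keep only the first `per_class` images of
#'   each digit (0-9), in file order.
#' @return A `stimulus_dataset` of kind `"digit"`.
#' @export
load_idx_dataset <- function(images_path, labels_path, per_class = NULL) {
  arr <- read_idx_images(images_path)
  labels <- read_idx_labels(labels_path)
  if (dim(arr)[1] != length(labels))
    stop(sprintf(
      "format error: %d images in '%s' but %d labels in '%s'",
      dim(arr)[1], images_path, length(labels), labels_path))
  keep <- seq_along(labels)
  if (!is.null(per_class)) {
    keep <- unlist(lapply(0:9, function(d) {
      which(labels == d)[seq_len(min(per_class, sum(labels == d)))]
    }))
    keep <- sort(keep)
  }
  images <- lapply(keep, function(i)
    stimulus_image(arr[i, , ], labels[i], "digit"))
  structure(list(images = images,
                 images_per_class = if (is.null(per_class)) NA_integer_
                                    else as.integer(per_class),
                 seed = NA_integer_, kind = "digit"),
            class = "stimulus_dataset")
}
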