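#' Bernoulli rate-coding spike encoder
#'
#' Converts an image into a binary spike raster: each pixel drives one input
#' unit, which emits a spike in each timestep independently with probability
#' `gain * pixel`. With the default gain of 0.2 a saturating pixel spikes on
#' average every 5 ms.
#'
#' Units are indexed column-major over the 28 x 28 grid, consistent with the
#' grid geometry used by the lateral-inhibition kernels.
#'
#' @param image a `stimulus_image`.
#' @param duration stimulus duration in ms (default 2000).
#' @param dt timestep in ms (default 1; `duration` must be a multiple).
#' @param gain per-timestep spike probability per unit of intensity
#'   (default 0.2); `gain * max(intensity)` must not exceed 1.
#' @param seed integer seed; the raster is deterministic given the seed.
#' @return An object of class `spike_train`: list with `raster`
#'   (timesteps x units binary integer matrix), `dt`, and `duration`.
#' @export
encode_bernoulli <- function(image, duration = 2000, dt = 1, gain = 0.2,
                             seed = 1) {
  stopifnot(inherits(image, "stimulus_image"))
  if (duration %% dt != 0) stop("duration must be divisible by dt")
  p <- gain * as.vector(image$pixels)
  if (any(p > 1))
    stop("invalid probability: gain * intensity exceeds 1 for some pixel")
  nt <- as.integer(duration / dt)
  n_units <- length(p)
  set.seed(as.integer(seed))
  raster <- matrix(rbinom(nt * n_units, 1L, rep(p, each = nt)), nt, n_units)
  structure(list(raster = raster, dt = dt, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d steps x %d units, dt=%g ms, %d spikes\n",
              nrow(x$raster), ncol(x$raster), x$dt, sum(x$raster)))
  invisible(x)
}

#' Save / load a spike raster
#'
#' The raster is stored as a compressed stream of 0/1 bytes next to a small
#' JSON sidecar holding `dt`, `duration` and an optional source-image id.
#'
#' @param train a `spike_train`.
#' @param path base path; `<path>.bin.gz` and `<path>.json` are written.
#' @param image_id optional identifier recorded in the sidecar.
#' @return `save_spike_train()` invisibly returns `path`;
#'   `load_spike_train()` returns the reconstructed `spike_train`.
#' @export
save_spike_train <- function(train, path, image_id = NULL) {
  con <- gzfile(paste0(path, ".bin.gz"), "wb")
  writeBin(as.raw(train$raster), con)
  close(con)
  meta <- list(dt = train$dt, duration = train$duration,
               timesteps = nrow(train$raster), units = ncol(train$raster),
               image_id = image_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_spike_train
#' @export
load_spike_train <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(paste0(path, ".bin.gz"), "rb")
  bytes <- readBin(con, "raw", n = meta$timesteps * meta$units)
  close(con)
  raster <- matrix(as.integer(bytes), meta$timesteps, meta$units)
  structure(list(raster = raster, dt = meta$dt, duration = meta$duration),
            class = "spike_train")
}
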