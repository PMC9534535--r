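# Shared fixtures: a short-duration network configuration for fast tests,
# a reference R-loop simulator, and a connectivity check for glyphs.

fast_config <- function(duration = 200, ...) {
  network_config(duration = duration, ...)
}

# Pure-R two-layer simulation built on lif_step(); the independent oracle the
# C++ core is checked against on small grids.
simulate_reference <- function(raster, w_ff, lat_in, lat_out, params, amp, dt) {
  n_in <- ncol(lat_in); n_out <- ncol(lat_out)
  st_in <- lif_init(n_in, params)
  st_out <- lif_init(n_out, params)
  prev_in <- numeric(n_in); prev_out <- numeric(n_out)
  counts_in <- integer(n_in); counts_out <- integer(n_out)
  for (t in seq_len(nrow(raster))) {
    ext_in <- amp * raster[t, ] + as.vector(lat_in %*% prev_in)
    ext_out <- as.vector(crossprod(w_ff, prev_in)) +
      as.vector(lat_out %*% prev_out)
    s1 <- lif_step(st_in, ext_in, params, dt)
    s2 <- lif_step(st_out, ext_out, params, dt)
    st_in <- s1$state; st_out <- s2$state
    prev_in <- s1$spikes; prev_out <- s2$spikes
    counts_in <- counts_in + s1$spikes
    counts_out <- counts_out + s2$spikes
  }
  list(input_counts = counts_in, output_counts = counts_out)
}

# Number of 4-connected foreground components of a binary matrix.
count_components <- function(mask) {
  n <- 0L
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || visited[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j))
    visited[i, j] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            mask[q[1], q[2]] && !visited[q[1], q[2]]) {
          visited[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  n
}
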