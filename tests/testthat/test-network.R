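test_that("lateral kernels match closed-form values and structure", {
  k <- build_lateral_weights(c(28, 28), alpha = 10, form = "corrected")
  w <- k$weights
  expect_identical(diag(w), rep(0, 784))
  expect_equal(w, t(w))
  expect_true(all(w <= 0))
  # adjacent grid units (R = 1): units 1 and 2 are vertical neighbours
  expect_equal(w[1, 2], -exp(-1 / 200), tolerance = 1e-12)
  # R = 10: unit (1,1) and unit (11,1)
  expect_equal(w[1, 11], -exp(-0.5), tolerance = 1e-12)
  lit <- build_lateral_weights(c(28, 28), alpha = 10, form = "literal")
  expect_equal(lit$weights[1, 2], -exp(-100), tolerance = 1e-12)
  expect_error(build_lateral_weights(c(28, 28), alpha = 0), "invalid argument")
})

test_that("kernel magnitude decreases with distance and grows with alpha", {
  k <- build_lateral_weights(c(28, 28), alpha = 10)
  w_row <- abs(k$weights[1, ])               # distances from corner unit
  d <- sqrt(colSums((t(grid_coords(c(28, 28))) - c(1, 1))^2))
  ord <- order(d)
  expect_true(all(diff(w_row[ord][-1]) <= 0))  # exclude self (d = 0, w = 0)
  k2 <- build_lateral_weights(c(28, 28), alpha = 20)
  off_diag <- upper.tri(k$weights)
  expect_true(all(abs(k2$weights[off_diag]) > abs(k$weights[off_diag])))
})

test_that("feedforward weights have the right moments and are reproducible", {
  w <- build_feedforward_weights(seed = 21)
  expect_identical(dim(w), c(784L, 784L))
  expect_lt(abs(mean(w) - 0.5), 0.005)
  expect_lt(abs(var(as.vector(w)) - 0.1), 0.005)
  expect_identical(w, build_feedforward_weights(seed = 21))
})

test_that("membrane voltage decays toward rest with the closed-form factor", {
  p <- lif_params()
  st <- lif_init(1, p)
  st$v <- -58.5
  for (t in 1:100) st <- lif_step(st, 0, p, dt = 1)$state
  expect_lt(abs(st$v - (p$rest + (-58.5 - p$rest) * exp(-1))), 1e-6)
  # resting state with zero current is a fixed point
  st0 <- lif_init(3, p)
  for (t in 1:50) st0 <- lif_step(st0, c(0, 0, 0), p)$state
  expect_identical(st0$v, rep(p$rest, 3))
})

test_that("threshold crossing spikes, resets and enforces 5 ms refractoriness", {
  p <- lif_params()
  st <- lif_init(1, p)
  st$v <- p$thresh                       # at threshold entering the step
  out <- lif_step(st, 1, p, dt = 1)      # any positive drive keeps it there
  expect_identical(out$spikes, 1L)
  expect_equal(out$state$v, p$reset)
  expect_equal(out$state$refrac_count, p$refrac)
  # silent for the following 5 ms despite strong input
  for (k in 1:5) {
    out <- lif_step(out$state, 100, p, dt = 1)
    expect_identical(out$spikes, 0L)
    expect_equal(out$state$v, p$reset)
  }
  # afterwards the accumulated current fires it again
  out <- lif_step(out$state, 100, p, dt = 1)
  expect_identical(out$spikes, 1L)
})

test_that("subthreshold voltage approaches rest + i * tc_decay", {
  p <- lif_params()
  st <- lif_init(1, p)
  ext <- 0.001                            # keeps the unit far below threshold
  for (t in 1:1500) st <- lif_step(st, ext, p, dt = 1)$state
  i_star <- ext / (1 - exp(-1 / p$tc_i_decay))
  expect_lt(abs((st$v - p$rest) - i_star * p$tc_decay),
            0.01 * i_star * p$tc_decay)
})

test_that("C++ core reproduces the pure-R reference simulation exactly", {
  p <- lif_params()
  shape <- c(3, 3)
  lat_in <- build_lateral_weights(shape, alpha = 2)$weights
  lat_out <- build_lateral_weights(shape, alpha = 3)$weights
  for (seed in 1:3) {
    set.seed(seed)
    raster <- matrix(rbinom(60 * 9, 1, 0.3), 60, 9)
    w_ff <- matrix(rnorm(81, 0.5, sqrt(0.1)), 9, 9)
    ref <- simulate_reference(raster, w_ff, lat_in, lat_out, p, amp = 8, dt = 1)
    core <- numspike:::sim_core_cpp(raster, t(w_ff), lat_in, lat_out,
                                    8, 1, p$thresh, p$rest, p$reset,
                                    p$refrac, p$tc_decay, p$tc_i_decay)
    expect_identical(core$input_counts, as.integer(ref$input_counts))
    expect_identical(core$output_counts, as.integer(ref$output_counts))
  }
})

test_that("trials are deterministic, bounded by refractoriness and silent on blank input", {
  cfg <- fast_config(duration = 200)
  kernels <- build_kernel_pair(cfg)
  blank <- stimulus_image(matrix(0, 28, 28), 1, "numerosity")
  tr0 <- simulate_trial(blank, cfg, seed = 5, kernels = kernels)
  expect_identical(sum(tr0$spike_counts), 0L)
  expect_identical(sum(tr0$input_spike_counts), 0L)

  img <- render_numerosity_image(4, 17)
  a <- simulate_trial(img, cfg, seed = 5, kernels = kernels)
  b <- simulate_trial(img, cfg, seed = 5, kernels = kernels)
  expect_identical(a$spike_counts, b$spike_counts)
  expect_true(all(a$spike_counts >= 0))
  max_spikes <- cfg$duration / (cfg$lif$refrac + cfg$dt)
  expect_true(all(a$spike_counts <= max_spikes))
  expect_equal(a$rates, a$spike_counts / (cfg$duration / 1000))
})

test_that("disabling lateral inhibition never lowers total output activity", {
  cfg <- fast_config(duration = 300)
  kernels <- build_kernel_pair(cfg)
  zeroed <- kernels
  zeroed$input$weights[] <- 0
  zeroed$output$weights[] <- 0
  img <- render_numerosity_image(3, 23)
  with_inh <- simulate_trial(img, cfg, seed = 9, kernels = kernels)
  without <- simulate_trial(img, cfg, seed = 9, kernels = zeroed)
  expect_gte(sum(without$spike_counts), sum(with_inh$spike_counts))
})

test_that("saturating drive without inhibition fires at the refractory limit", {
  p <- lif_params()
  raster <- matrix(1L, 120, 9)
  zero <- matrix(0, 9, 9)
  w_ff <- matrix(1, 9, 9)
  core <- numspike:::sim_core_cpp(raster, t(w_ff), zero, zero,
                                  50, 1, p$thresh, p$rest, p$reset,
                                  p$refrac, p$tc_decay, p$tc_i_decay)
  limit <- 120 / (p$refrac + 1)
  expect_true(all(core$input_counts <= limit))
  expect_true(all(core$input_counts >= limit - 1))
})

test_that("LIF and network parameter validation rejects bad values", {
  expect_error(lif_params(thresh = -70), "thresh")
  expect_error(lif_params(tc_decay = 0), "time constants")
  expect_error(network_config(alpha_input = -1), "alpha")
  expect_error(network_config(duration = 150, dt = 7), "divisible")
  img10 <- stimulus_image(matrix(0, 28, 28), 1, "numerosity")
  cfg <- fast_config()
  bad_kernels <- list(input = build_lateral_weights(c(3, 3), 2),
                      output = build_lateral_weights(c(3, 3), 2))
  expect_error(simulate_trial(img10, cfg, kernels = bad_kernels),
               "configuration error")
})
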