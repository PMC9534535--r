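# A small synthetic trial table: 3 units, 5 classes, 2 trials per class.
toy_rates <- function() {
  labels <- rep(1:5, each = 2)
  # unit 1 peaks at class 3; unit 2 is flat; unit 3 silent
  u1 <- c(1, 1, 2, 2, 5, 5, 2, 2, 1, 1)
  u2 <- rep(4, 10)
  u3 <- rep(0, 10)
  list(rates = cbind(u1, u2, u3), labels = labels)
}

test_that("tuning curves average rates and apply the selectivity rule", {
  toy <- toy_rates()
  tc <- compute_tuning_curves(toy$rates, toy$labels)
  expect_identical(dim(tc$mean_rates), c(3L, 5L))
  expect_equal(unname(tc$mean_rates[1, ]), c(1, 2, 5, 2, 1))
  expect_identical(tc$preferred, c(3L, NA, NA))
  expect_error(compute_tuning_curves(toy$rates[1:4, ], toy$labels[1:4],
                                     classes = 1:5),
               "missing class")
})

test_that("mean rates match a hand-computed average on uneven trials", {
  set.seed(42)
  labels <- sample(rep(1:5, each = 30))
  rates <- matrix(rpois(150 * 3, 4), 150, 3)
  tc <- compute_tuning_curves(rates, labels)
  for (cl in 1:5)
    expect_equal(unname(tc$mean_rates[, as.character(cl)]),
                 colMeans(rates[labels == cl, , drop = FALSE]))
})

test_that("preference distribution counts selective units only", {
  rates <- rbind(c(9, 1, 1, 1, 1),
                 c(8, 2, 1, 1, 1),
                 c(1, 1, 1, 1, 9),
                 c(1, 1, 7, 1, 1),
                 c(2, 2, 2, 2, 2))        # tied -> excluded
  tc <- compute_tuning_curves(t(rates)[rep(1:5, each = 2), ],
                              rep(1:5, each = 2))
  pd <- preference_distribution(tc)
  expect_equal(pd$percent, c(50, 0, 25, 0, 25))
  expect_identical(attr(pd, "n_selective"), 4L)
  expect_equal(sum(pd$percent), 100, tolerance = 1e-6)
})

test_that("a randomized preference assignment matches a brute-force tally", {
  set.seed(7)
  n_units <- 100
  peak <- sample(1:5, n_units, replace = TRUE)
  rates <- matrix(1, n_units, 5)
  rates[cbind(1:n_units, peak)] <- 5
  # two trials per class with identical rates
  trial_rates <- t(rates)[rep(1:5, each = 2), ]
  tc <- compute_tuning_curves(trial_rates, rep(1:5, each = 2))
  pd <- preference_distribution(tc)
  brute <- as.vector(table(factor(peak, levels = 1:5)))
  expect_identical(pd$n, as.integer(brute))
  expect_equal(pd$percent, 100 * brute / n_units)
})

test_that("average curves are min-max normalized and idempotent", {
  rates <- rbind(c(2, 4, 10, 4, 2),
                 c(2, 4, 10, 4, 2))
  tc <- compute_tuning_curves(t(rates)[rep(1:5, each = 2), ],
                              rep(1:5, each = 2))
  avg <- suppressMessages(average_normalized_curves(tc))
  cur <- avg[avg$preferred == 3, ]
  expect_equal(cur$response, c(0, 0.25, 1, 0.25, 0))
  expect_identical(unique(avg$preferred), 3L)   # other classes omitted
  expect_identical(cur$n_units[1], 2L)
})

test_that("every average curve attains both 0 and 1", {
  set.seed(11)
  rates <- matrix(rpois(50 * 20, 3) + runif(1000), 50, 20)
  tc <- compute_tuning_curves(rates, rep(1:5, each = 10))
  avg <- suppressMessages(average_normalized_curves(tc))
  for (cl in unique(avg$preferred)) {
    r <- avg$response[avg$preferred == cl]
    expect_equal(min(r), 0)
    expect_equal(max(r), 1)
  }
})

test_that("abscissa transforms follow the four scales with the digit shift", {
  expect_identical(transform_scale(3, "linear"), 3)
  expect_equal(transform_scale(4, "log2"), 2)
  expect_equal(transform_scale(8, "cbrt"), 2)
  expect_equal(transform_scale(9, "sqrt"), 3)
  expect_equal(transform_scale(0:3, "log2", digit = TRUE), log2(1:4))
  expect_error(transform_scale(0, "log2"), "domain error")
})

test_that("exact Gaussian data are recovered with r2 = 1", {
  t <- 1:5
  y <- 1 * exp(-(t - 2)^2 / (2 * 0.8^2))
  f <- fit_gaussian(t, y)
  expect_true(f$converged)
  expect_lt(abs(f$a - 1), 1e-6)
  expect_lt(abs(f$center - 2), 1e-6)
  expect_lt(abs(f$sigma - 0.8), 1e-6)
  expect_lt(abs(f$r2 - 1), 1e-9)
})

test_that("a symmetric tent curve fits with its centre at the midpoint", {
  t <- 1:5
  y <- c(0, 0.25, 1, 0.25, 0)
  f <- fit_gaussian(t, y)
  # independent coarse grid search over (a, center, sigma) confirms the centre
  grid <- expand.grid(a = seq(0.8, 1.2, 0.02),
                      center = seq(2, 4, 0.01),
                      sigma = seq(0.3, 2, 0.02))
  sse <- mapply(function(a, c0, s) sum((y - a * exp(-(t - c0)^2 / (2 * s^2)))^2),
                grid$a, grid$center, grid$sigma)
  expect_lt(abs(grid$center[which.min(sse)] - 3), 0.02)
  expect_true(f$converged)
  expect_lt(abs(f$center - 3), 0.01)
})

test_that("r2 never exceeds 1 and degenerate input raises an error", {
  set.seed(3)
  for (k in 1:20) {
    y <- runif(5)
    if (diff(range(y)) == 0) next
    f <- fit_gaussian(1:5, y)
    if (f$converged) expect_lte(f$r2, 1)
  }
  expect_error(fit_gaussian(1:5, rep(0.4, 5)), "fit-degenerate")
  expect_error(fit_gaussian(1:2, c(0, 1)), ">= 3")
})

test_that("mean r2 per scale is the arithmetic mean over converged fits", {
  fits <- structure(
    data.frame(scale = rep(c("linear", "log2"), each = 3),
               preferred = rep(1:3, 2),
               a = 1, center = 2, sigma = 1,
               r2 = c(0.8, 0.9, 1.0, 0.7, 0.7, 0.7),
               converged = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    class = c("scale_fits", "data.frame"))
  m <- mean_r2_per_scale(fits)
  expect_equal(m$mean_r2[m$scale == "linear"], 0.9)
  expect_equal(m$mean_r2[m$scale == "log2"], 0.7)
  expect_identical(m$n_curves, c(3L, 2L))
})

test_that("sigma_vs_preference preserves constructed orderings", {
  mk <- function(sigmas) structure(
    data.frame(scale = "linear", preferred = seq_along(sigmas), a = 1,
               center = seq_along(sigmas), sigma = sigmas, r2 = 1,
               converged = TRUE),
    class = c("scale_fits", "data.frame"))
  widening <- sigma_vs_preference(mk(c(0.5, 1, 1.5, 2, 3)), "linear")
  expect_true(all(diff(widening$sigma) > 0))
  flat <- sigma_vs_preference(mk(rep(1.2, 5)), "linear")
  expect_true(all(flat$sigma == 1.2))
})

test_that("full-curve fits on simulated-style data keep the size effect", {
  # synthetic average curves widening with preferred class
  t <- 1:5
  avg <- do.call(rbind, lapply(1:5, function(cl) {
    y <- exp(-(t - cl)^2 / (2 * (0.3 + 0.4 * cl)^2))
    y <- (y - min(y)) / (max(y) - min(y))
    data.frame(preferred = cl, class = t, response = y, n_units = 10)
  }))
  avg <- structure(avg, class = c("avg_tuning_curves", "data.frame"))
  fits <- fit_all_scales(avg)
  s <- sigma_vs_preference(fits, "linear")
  expect_gt(suppressWarnings(
    cor.test(s$preferred, s$sigma, method = "spearman")$estimate), 0)
})

test_that("curve skewness is signed and vanishes for symmetric curves", {
  t <- 1:5
  expect_equal(curve_skewness(c(0, 0.25, 1, 0.25, 0), t), 0)
  right_tail <- curve_skewness(c(0, 1, 0.6, 0.4, 0.3), t)
  expect_gt(right_tail, 0)
  expect_error(curve_skewness(c(-1, 0, 1, 0, 0), t), "non-negative")
})

test_that("distance effect checker flags increases away from the peak", {
  mk_avg <- function(resp, cl) structure(
    data.frame(preferred = cl, class = 1:5, response = resp, n_units = 5),
    class = c("avg_tuning_curves", "data.frame"))
  ok <- mk_avg(c(0.2, 0.6, 1, 0.5, 0.1), 3)
  expect_true(distance_effect_holds(ok)[["3"]])
  bumpy <- mk_avg(c(0.2, 0.6, 1, 0.2, 0.4), 3)   # rises 0.2 -> 0.4
  expect_false(distance_effect_holds(bumpy)[["3"]])
  expect_true(distance_effect_holds(bumpy, tol = 0.25)[["3"]])
})
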