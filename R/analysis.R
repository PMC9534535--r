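#' Stack trial results into a rate matrix
#'
#' @param trials list of `trial_result` objects.
#' @return List with `rates` (trials x units matrix) and `labels`.
#' @export
trials_to_matrix <- function(trials) {
  labels <- vapply(trials, function(tr) tr$image_label, integer(1))
  rates <- do.call(rbind, lapply(trials, function(tr) tr$rates))
  list(rates = rates, labels = labels)
}

#' Compute per-unit tuning curves and preferred classes
#'
#' For every output unit, the mean firing rate over all trials of each
#' stimulus class. A unit is *selective* when it fired at least once across
#' the experiment and the maximum of its tuning curve is attained at exactly
#' one class; that class is its preferred class. Units that never fired, or
#' whose maximum is tied, get `NA` (no preference).
#'
#' @param rates trials x units matrix of firing rates (Hz), or a list of
#'   `trial_result` objects.
#' @param labels integer class label per trial (ignored when `rates` is a
#'   list of trials).
#' @param classes expected class labels (defaults to the labels present);
#'   a class with no trials raises a missing-class error.
#' @return An object of class `tuning_curves`: `mean_rates`
#'   (units x classes matrix, columns named by class), `preferred` (integer
#'   vector, `NA` for non-selective units), and `classes`.
#' @export
compute_tuning_curves <- function(rates, labels = NULL, classes = NULL) {
  if (is.list(rates) && !is.matrix(rates)) {
    m <- trials_to_matrix(rates)
    rates <- m$rates; labels <- m$labels
  }
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two stimulus classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0)) stop("missing class: no trials for some class")
  # class x units mean matrix -> transpose to units x classes
  sums <- rowsum(rates, group = factor(labels, levels = classes))
  mean_rates <- t(sums / as.vector(counts))
  colnames(mean_rates) <- classes
  preferred <- apply(mean_rates, 1, function(r) {
    if (all(r == 0)) return(NA_integer_)
    mx <- max(r)
    hit <- which(r == mx)
    if (length(hit) != 1) return(NA_integer_)
    classes[hit]
  })
  structure(list(mean_rates = mean_rates, preferred = as.integer(preferred),
                 classes = classes),
            class = "tuning_curves")
}

#' @export
print.tuning_curves <- function(x, ...) {
  cat(sprintf("<tuning_curves> %d units, %d classes, %d selective\n",
              nrow(x$mean_rates), length(x$classes), sum(!is.na(x$preferred))))
  invisible(x)
}

#' Distribution of preferred classes over selective units
#'
#' @param curves a [compute_tuning_curves()] result.
#' @return Data frame with `class`, `n` and `percent` (over selective units;
#'   percentages sum to 100). Attributes: `n_selective`, and `percent_all`
#'   (the same counts expressed over all units, selective or not).
#' @export
preference_distribution <- function(curves) {
  stopifnot(inherits(curves, "tuning_curves"))
  pref <- curves$preferred[!is.na(curves$preferred)]
  if (length(pref) == 0) stop("empty result: no selective units")
  n <- vapply(curves$classes, function(cl) sum(pref == cl), numeric(1))
  out <- data.frame(class = curves$classes, n = as.integer(n),
                    percent = 100 * n / length(pref))
  attr(out, "n_selective") <- length(pref)
  attr(out, "percent_all") <- 100 * n / length(curves$preferred)
  out
}

#' Average normalized tuning curves by preferred class
#'
#' Tuning curves of units sharing a preferred class are averaged unit-wise,
#' then min-max normalized to `[0, 1]`. Preferred classes with no selective
#' units are omitted (with a message).
#'
#' @param curves a [compute_tuning_curves()] result.
#' @return An object of class `avg_tuning_curves`: a data frame with columns
#'   `preferred`, `class`, `response` (normalized mean rate) and `n_units`.
#' @export
average_normalized_curves <- function(curves) {
  stopifnot(inherits(curves, "tuning_curves"))
  rows <- list()
  for (cl in curves$classes) {
    sel <- which(!is.na(curves$preferred) & curves$preferred == cl)
    if (length(sel) == 0) {
      message("no selective units prefer class ", cl, "; curve omitted")
      next
    }
    avg <- colMeans(curves$mean_rates[sel, , drop = FALSE])
    rng <- range(avg)
    if (rng[2] > rng[1]) avg <- (avg - rng[1]) / (rng[2] - rng[1])
    rows[[as.character(cl)]] <- data.frame(
      preferred = cl, class = curves$classes, response = as.vector(avg),
      n_units = length(sel))
  }
  if (length(rows) == 0) stop("empty result: no selective units at all")
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("avg_tuning_curves", "data.frame"))
}

#' Abscissa transforms for tuning-curve fits
#'
#' The four scales on which tuning symmetry is compared: identity,
#' square root, cube root and base-2 logarithm. For digit classes (which
#' include 0) the log2 scale uses `log2(x + 1)`.
#'
#' @param x class values.
#' @param scale one of `"linear"`, `"sqrt"`, `"cbrt"`, `"log2"`.
#' @param digit logical; apply the `+1` shift on the log2 scale.
#' @return Transformed abscissa values.
#' @export
transform_scale <- function(x, scale = c("linear", "sqrt", "cbrt", "log2"),
                            digit = FALSE) {
  scale <- match.arg(scale)
  switch(scale,
         linear = x,
         sqrt = x^(1 / 2),
         cbrt = x^(1 / 3),
         log2 = {
           if (digit) log2(x + 1)
           else {
             if (any(x <= 0)) stop("domain error: log2 of non-positive class")
             log2(x)
           }
         })
}

TUNING_SCALES <- c("linear", "sqrt", "cbrt", "log2")

#' Fit a Gaussian to one tuning curve
#'
#' Nonlinear least squares fit of `a * exp(-(t - center)^2 / (2 sigma^2))`
#' to (transformed class value, normalized response) pairs, by
#' Levenberg-Marquardt. Initialisation: `a` at the maximum response,
#' `center` at its abscissa, `sigma` at half the abscissa range; `sigma` is
#' bounded below by 1e-3.
#'
#' @param t transformed abscissa values (>= 3 points).
#' @param y responses at those points.
#' @return List with `a`, `center`, `sigma`, `r2` and `converged`. A fit that
#'   fails to converge is returned with `converged = FALSE` and `NA`
#'   parameters.
#' @export
fit_gaussian <- function(t, y) {
  if (length(t) != length(y) || length(t) < 3)
    stop("need >= 3 (t, y) points")
  if (diff(range(y)) == 0)
    stop("fit-degenerate: constant responses cannot be fit")
  resid_fn <- function(par) y - par[1] * exp(-(t - par[2])^2 / (2 * par[3]^2))
  rng <- diff(range(t))
  # The centre is constrained to the tested class range and the amplitude to
  # non-negative values: tuning curves peaking at an edge class otherwise
  # drift along a ridge (a -> Inf, centre -> -Inf) that fits well but has no
  # tuning interpretation. Sharp single-class peaks need a narrow initial
  # sigma, so several widths are tried and the best converged fit kept.
  lower <- c(0, min(t), 1e-3)
  upper <- c(2 * max(abs(y)), max(t), Inf)
  starts <- lapply(c(rng / 8, rng / 4, rng / 2, rng),
                   function(s) c(max(y), t[which.max(y)], s))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4 || !all(is.finite(fit$par))) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best))
    return(list(a = NA_real_, center = NA_real_, sigma = NA_real_,
                r2 = NA_real_, converged = FALSE))
  ss_tot <- sum((y - mean(y))^2)
  list(a = best$par[1], center = best$par[2], sigma = abs(best$par[3]),
       r2 = 1 - best$sse / ss_tot, converged = TRUE)
}

#' Gaussian fits of all average curves on all four scales
#'
#' @param avg an [average_normalized_curves()] result.
#' @param digit logical; use the digit shift for the log2 abscissa.
#' @param scales subset of the four scales (default all).
#' @return An object of class `scale_fits`: data frame with `scale`,
#'   `preferred`, `a`, `center`, `sigma`, `r2`, `converged`. Failed fits are
#'   kept (flagged, `NA` parameters) and a warning reports how many.
#' @export
fit_all_scales <- function(avg, digit = FALSE, scales = TUNING_SCALES) {
  stopifnot(inherits(avg, "avg_tuning_curves"))
  scales <- match.arg(scales, TUNING_SCALES, several.ok = TRUE)
  rows <- list()
  for (sc in scales) {
    for (cl in unique(avg$preferred)) {
      cur <- avg[avg$preferred == cl, ]
      t <- transform_scale(cur$class, sc, digit = digit)
      f <- tryCatch(fit_gaussian(t, cur$response),
                    error = function(e)
                      list(a = NA_real_, center = NA_real_, sigma = NA_real_,
                           r2 = NA_real_, converged = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        scale = sc, preferred = cl, a = f$a, center = f$center,
        sigma = f$sigma, r2 = f$r2, converged = f$converged)
    }
  }
  out <- do.call(rbind, rows)
  n_fail <- sum(!out$converged)
  if (n_fail > 0)
    warning(n_fail, " Gaussian fit(s) failed to converge and are excluded",
            " from scale averages")
  structure(out, class = c("scale_fits", "data.frame"))
}

#' Mean goodness of fit per abscissa scale
#'
#' @param fits a [fit_all_scales()] result.
#' @return Data frame with `scale`, `mean_r2` (over converged fits) and
#'   `n_curves`, in the canonical scale order.
#' @export
mean_r2_per_scale <- function(fits) {
  stopifnot(inherits(fits, "scale_fits"))
  out <- do.call(rbind, lapply(intersect(TUNING_SCALES, unique(fits$scale)),
                               function(sc) {
    ok <- fits$scale == sc & fits$converged
    if (!any(ok)) stop("missing scale: no converged fits on scale ", sc)
    data.frame(scale = sc, mean_r2 = mean(fits$r2[ok]), n_curves = sum(ok))
  }))
  out
}

#' Fitted tuning bandwidth by preferred class
#'
#' @param fits a [fit_all_scales()] result.
#' @param scale which abscissa scale to extract.
#' @return Data frame with `preferred` and `sigma`, ordered by preferred
#'   class; only converged fits are returned.
#' @export
sigma_vs_preference <- function(fits, scale = "linear") {
  stopifnot(inherits(fits, "scale_fits"))
  scale <- match.arg(scale, TUNING_SCALES)
  cur <- fits[fits$scale == scale & fits$converged, ]
  if (nrow(cur) == 0) stop("missing scale: no converged fits on scale ", scale)
  cur <- cur[order(cur$preferred), c("preferred", "sigma")]
  rownames(cur) <- NULL
  cur
}

#' Signed skewness of a tuning curve around its mass centre
#'
#' Treats the (non-negative) responses as weights over the abscissa and
#' returns the weighted third standardized central moment. Used to compare
#' curve symmetry between linear and logarithmic abscissae: tuning that is
#' log-compressed is more symmetric (smaller `|skewness|`) on the log2 axis.
#'
#' @param response non-negative responses.
#' @param t abscissa values.
#' @return Signed skewness (0 for a symmetric curve).
#' @export
curve_skewness <- function(response, t) {
  if (any(response < 0)) stop("responses must be non-negative")
  w <- response / sum(response)
  mu <- sum(w * t)
  s2 <- sum(w * (t - mu)^2)
  if (s2 == 0) return(0)
  sum(w * (t - mu)^3) / s2^1.5
}

#' Check the distance effect on an average tuning curve
#'
#' The distance effect holds when the normalized response is non-increasing
#' as the class moves away from the preferred class on either side, up to a
#' violation tolerance.
#'
#' @param avg an [average_normalized_curves()] result.
#' @param tol largest allowed increase (normalized units) away from the peak.
#' @return Named logical vector, one entry per preferred class.
#' @export
distance_effect_holds <- function(avg, tol = 0.05) {
  stopifnot(inherits(avg, "avg_tuning_curves"))
  vapply(unique(avg$preferred), function(cl) {
    cur <- avg[avg$preferred == cl, ]
    cur <- cur[order(cur$class), ]
    k <- which(cur$class == cl)
    right <- cur$response[k:nrow(cur)]
    left <- rev(cur$response[1:k])
    all(diff(right) <= tol) && all(diff(left) <= tol)
  }, logical(1), USE.NAMES = FALSE) |>
    stats::setNames(unique(avg$preferred))
}
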