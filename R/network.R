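#' Current-based LIF neuron parameters
#'
#' Defaults follow the standard parameterisation of a current-based leaky
#' integrate-and-fire neuron: threshold -52 mV, resting and post-spike reset
#' voltage -65 mV, 5 ms refractory period, 100 ms membrane time constant and
#' 2 ms synaptic-current time constant.
#'
#' @param thresh spike threshold voltage (mV).
#' @param rest resting membrane voltage (mV).
#' @param reset post-spike reset voltage (mV).
#' @param refrac refractory period (ms).
#' @param tc_decay membrane voltage decay time constant (ms).
#' @param tc_i_decay synaptic input current decay time constant (ms).
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(thresh = -52.0, rest = -65.0, reset = -65.0,
                       refrac = 5, tc_decay = 100.0, tc_i_decay = 2.0) {
  if (!(thresh > rest)) stop("thresh must exceed rest")
  if (reset > thresh) stop("reset must not exceed thresh")
  if (refrac < 0) stop("refrac must be >= 0")
  if (tc_decay <= 0 || tc_i_decay <= 0) stop("time constants must be positive")
  structure(list(thresh = thresh, rest = rest, reset = reset, refrac = refrac,
                 tc_decay = tc_decay, tc_i_decay = tc_i_decay),
            class = "lif_params")
}

#' Network configuration
#'
#' Geometry, weight statistics and timing of the two-layer network: both
#' layers are 28 x 28 grids of LIF units; feedforward weights are drawn
#' fresh for every image from N(mean, variance); within-layer lateral
#' inhibition uses a Gaussian distance kernel with standard deviation
#' `alpha_input` (input layer) and `alpha_output` (output layer).
#'
#' @param grid_shape integer 2-vector, units per layer as (rows, cols).
#' @param ff_weight_mean,ff_weight_variance mean and variance of the fresh
#'   feedforward Gaussian weights (defaults 0.5 and 0.1).
#' @param alpha_input,alpha_output lateral-inhibition kernel widths in grid
#'   units (defaults 10 and 20).
#' @param lateral_form `"corrected"` (Gaussian with standard deviation alpha,
#'   `w = -exp(-R^2 / (2 alpha^2))`, the default) or `"literal"`
#'   (`w = -exp(-R^2 * alpha^2)`). See the methods vignette for why the
#'   corrected form is the default.
#' @param input_injection_amplitude current injected into an input unit per
#'   encoder spike (default 1).
#' @param dt simulation timestep in ms.
#' @param duration stimulus duration in ms (default 2000).
#' @param encoder_gain Bernoulli encoder gain (default 0.2).
#' @param lif a [lif_params()] object.
#' @return An object of class `network_config`.
#' @export
network_config <- function(grid_shape = c(28L, 28L),
                           ff_weight_mean = 0.5, ff_weight_variance = 0.1,
                           alpha_input = 10, alpha_output = 20,
                           lateral_form = c("corrected", "literal"),
                           input_injection_amplitude = 1.0,
                           dt = 1, duration = 2000, encoder_gain = 0.2,
                           lif = lif_params()) {
  lateral_form <- match.arg(lateral_form)
  if (alpha_input <= 0 || alpha_output <= 0) stop("alpha values must be positive")
  if (ff_weight_variance <= 0) stop("ff_weight_variance must be positive")
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  if (duration %% dt != 0) stop("duration must be divisible by dt")
  stopifnot(inherits(lif, "lif_params"))
  structure(list(grid_shape = as.integer(grid_shape),
                 ff_weight_mean = ff_weight_mean,
                 ff_weight_variance = ff_weight_variance,
                 alpha_input = alpha_input, alpha_output = alpha_output,
                 lateral_form = lateral_form,
                 input_injection_amplitude = input_injection_amplitude,
                 dt = dt, duration = duration, encoder_gain = encoder_gain,
                 lif = lif),
            class = "network_config")
}

# (row, col) grid coordinates of unit u = 1..prod(shape), column-major.
grid_coords <- function(grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cbind(row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr))
}

#' Build a lateral-inhibition weight kernel
#'
#' Within-layer weights are negative and shrink in magnitude with the
#' Euclidean distance R between the two units' grid positions. The
#' `corrected` form is a Gaussian with standard deviation `alpha`,
#' `w = -exp(-R^2 / (2 alpha^2))`; the `literal` form is
#' `w = -exp(-R^2 * alpha^2)`. Self-connections are excluded (zero diagonal).
#'
#' @param grid_shape integer 2-vector (rows, cols).
#' @param alpha kernel width; must be positive.
#' @param form `"corrected"` or `"literal"`.
#' @return An object of class `lateral_kernel` with elements `weights`
#'   (units x units symmetric matrix, entries <= 0), `alpha`, `form` and
#'   `grid_shape`.
#' @export
build_lateral_weights <- function(grid_shape = c(28L, 28L), alpha,
                                  form = c("corrected", "literal")) {
  form <- match.arg(form)
  if (alpha <= 0) stop("invalid argument: alpha must be positive")
  coords <- grid_coords(grid_shape)
  d2 <- as.matrix(dist(coords))^2
  w <- if (form == "corrected") -exp(-d2 / (2 * alpha^2)) else -exp(-d2 * alpha^2)
  diag(w) <- 0
  dimnames(w) <- NULL
  structure(list(weights = w, alpha = alpha, form = form,
                 grid_shape = as.integer(grid_shape)),
            class = "lateral_kernel")
}

#' Draw a fresh feedforward weight matrix
#'
#' Independent Gaussian draws with mean `mean` and variance `variance`
#' (no clipping), one weight per (input unit, output unit) pair. A fresh
#' matrix is drawn for every stimulus presentation: the network is untrained
#' and its weights are disposable.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param n_in,n_out layer sizes.
#' @param mean,variance weight distribution parameters.
#' @return `n_in` x `n_out` numeric matrix; entry (i, j) connects input
#'   unit i to output unit j.
#' @export
build_feedforward_weights <- function(seed = NULL, n_in = 784L, n_out = 784L,
                                      mean = 0.5, variance = 0.1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  matrix(rnorm(n_in * n_out, mean, sqrt(variance)), n_in, n_out)
}

#' Initial LIF state for a layer
#' @param n number of units.
#' @param params a [lif_params()] object.
#' @return List with voltages `v` (at rest), currents `i` (zero) and
#'   `refrac_count` (zero).
#' @export
lif_init <- function(n, params = lif_params()) {
  list(v = rep(params$rest, n), i = rep(0, n), refrac_count = rep(0, n))
}

#' Advance a layer of LIF neurons by one timestep
#'
#' Reference (pure R) implementation of the update used by the simulation
#' core. Per step: synaptic current decays by `exp(-dt/tc_i_decay)` and then
#' receives the external input; the voltage of non-refractory units decays
#' toward rest by `exp(-dt/tc_decay)` and then integrates `i * dt`; units
#' reaching threshold spike, reset to `reset` and become refractory for
#' `refrac` ms; refractory units hold the reset voltage and ignore input.
#'
#' @param state list with `v`, `i`, `refrac_count` (see [lif_init()]).
#' @param external_current per-unit input current for this step.
#' @param params a [lif_params()] object.
#' @param dt timestep in ms.
#' @return List with the updated `state` and a binary `spikes` vector.
#' @export
lif_step <- function(state, external_current, params = lif_params(), dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  refractory <- state$refrac_count > 0
  i <- state$i * exp(-dt / params$tc_i_decay) + external_current
  v <- state$v
  decay_v <- exp(-dt / params$tc_decay)
  v[!refractory] <- params$rest + (v[!refractory] - params$rest) * decay_v +
    i[!refractory] * dt
  v[refractory] <- params$reset
  spikes <- as.integer(!refractory & v >= params$thresh)
  fired <- spikes == 1L
  v[fired] <- params$reset
  rc <- state$refrac_count
  rc[refractory] <- pmax(rc[refractory] - dt, 0)
  rc[fired] <- params$refrac
  list(state = list(v = v, i = i, refrac_count = rc), spikes = spikes)
}

#' Simulate one stimulus presentation
#'
#' Composes the Bernoulli encoder, a fresh feedforward weight draw and the
#' two-layer LIF dynamics with lateral inhibition. Encoder spikes inject
#' `input_injection_amplitude` current into the matching input unit; input
#' spikes feed back within the input layer through its lateral kernel and
#' forward to the output layer through the feedforward matrix, both with a
#' one-timestep synaptic delay; output spikes feed back within the output
#' layer through its own lateral kernel.
#'
#' @param image a `stimulus_image`.
#' @param config a [network_config()].
#' @param seed integer seed for this trial (encoder draws and feedforward
#'   weights both derive from it).
#' @param kernels optional list with precomputed `input` and `output`
#'   [build_lateral_weights()] kernels (built from `config` when `NULL`);
#'   pass kernels with zeroed weights to disable lateral inhibition.
#' @return An object of class `trial_result`: output-unit `spike_counts` and
#'   `rates` (Hz), input-layer counts, the image label and the seed.
#' @export
simulate_trial <- function(image, config = network_config(), seed = 1,
                           kernels = NULL) {
  stopifnot(inherits(image, "stimulus_image"), inherits(config, "network_config"))
  n_units <- prod(config$grid_shape)
  if (length(image$pixels) != n_units)
    stop("configuration error: image size does not match grid_shape")
  if (is.null(kernels)) kernels <- build_kernel_pair(config)
  if (!all(dim(kernels$input$weights) == n_units) ||
      !all(dim(kernels$output$weights) == n_units))
    stop("configuration error: kernel dimensions do not match grid_shape")

  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max, 2)
  train <- encode_bernoulli(image, duration = config$duration, dt = config$dt,
                            gain = config$encoder_gain, seed = sub[1])
  w_ff <- build_feedforward_weights(sub[2], n_units, n_units,
                                    config$ff_weight_mean,
                                    config$ff_weight_variance)

  res <- sim_core_cpp(train$raster, t(w_ff),
                      kernels$input$weights, kernels$output$weights,
                      config$input_injection_amplitude, config$dt,
                      config$lif$thresh, config$lif$rest, config$lif$reset,
                      config$lif$refrac, config$lif$tc_decay,
                      config$lif$tc_i_decay)
  duration_s <- config$duration / 1000
  structure(list(spike_counts = res$output_counts,
                 rates = res$output_counts / duration_s,
                 input_spike_counts = res$input_counts,
                 image_label = image$label, seed = as.integer(seed)),
            class = "trial_result")
}

#' Build the input/output lateral kernel pair for a configuration
#' @param config a [network_config()].
#' @return List with `input` and `output` `lateral_kernel` objects.
#' @export
build_kernel_pair <- function(config) {
  list(input = build_lateral_weights(config$grid_shape, config$alpha_input,
                                     config$lateral_form),
       output = build_lateral_weights(config$grid_shape, config$alpha_output,
                                      config$lateral_form))
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> label=%d, output spikes=%d, mean rate=%.2f Hz\n",
              x$image_label, sum(x$spike_counts), mean(x$rates)))
  invisible(x)
}
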