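#' Experiment configuration
#'
#' Bundles the dataset choice, dataset size, network configuration, master
#' seed and output location of one end-to-end run.
#'
#' @param dataset `"numerosity"` (dot displays, classes 1-5),
#'   `"digit-fixture"` (synthetic glyphs, classes 0-9) or `"mnist"`
#'   (handwritten digits read from IDX files).
#' @param images_per_class images per class (default 30).
#' @param network a [network_config()].
#' @param master_seed integer; every random draw of the run derives from it.
#' @param output_dir directory for report files.
#' @param emit_figures render PNG figures from the written CSVs
#'   (requires ggplot2).
#' @param mnist_images,mnist_labels IDX file paths, required when
#'   `dataset = "mnist"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset = c("numerosity", "mnist", "digit-fixture"),
                              images_per_class = 30,
                              network = network_config(),
                              master_seed = 1,
                              output_dir = tempfile("numspike-run-"),
                              emit_figures = FALSE,
                              mnist_images = NULL, mnist_labels = NULL) {
  dataset <- match.arg(dataset)
  if (images_per_class < 1) stop("images_per_class must be >= 1")
  stopifnot(inherits(network, "network_config"))
  if (dataset == "mnist") {
    missing_files <- c(
      if (is.null(mnist_images) || !file.exists(mnist_images))
        "an IDX image file (e.g. train-images-idx3-ubyte) as `mnist_images`",
      if (is.null(mnist_labels) || !file.exists(mnist_labels))
        "an IDX label file (e.g. train-labels-idx1-ubyte) as `mnist_labels`")
    if (length(missing_files) > 0)
      stop("dataset = \"mnist\" needs ", paste(missing_files, collapse = " and "))
  }
  structure(list(dataset = dataset,
                 images_per_class = as.integer(images_per_class),
                 network = network, master_seed = as.integer(master_seed),
                 output_dir = output_dir, emit_figures = emit_figures,
                 mnist_images = mnist_images, mnist_labels = mnist_labels),
            class = "experiment_config")
}

config_defaults <- function() {
  net <- network_config()
  list(dataset = "numerosity", images_per_class = 30,
       master_seed = 1, output_dir = ".", emit_figures = FALSE,
       mnist_images = NULL, mnist_labels = NULL,
       network = list(
         grid_shape = net$grid_shape, ff_weight_mean = net$ff_weight_mean,
         ff_weight_variance = net$ff_weight_variance,
         alpha_input = net$alpha_input, alpha_output = net$alpha_output,
         lateral_form = net$lateral_form,
         input_injection_amplitude = net$input_injection_amplitude,
         dt = net$dt, duration = net$duration, encoder_gain = net$encoder_gain,
         lif = unclass(lif_params())))
}

# Flatten nested names as "network.lif.thresh" for error reporting.
flat_names <- function(defaults, prefix = "") {
  out <- character(0)
  for (nm in names(defaults)) {
    full <- paste0(prefix, nm)
    out <- c(out, full)
    if (is.list(defaults[[nm]]))
      out <- c(out, flat_names(defaults[[nm]], paste0(full, ".")))
  }
  out
}

#' Validate a raw experiment configuration
#'
#' Accepts a YAML file path or a nested list keyed by the
#' [experiment_config()] / [network_config()] / [lif_params()] field names,
#' fills every missing field with its default, and reports *all* violations
#' (unknown keys, with a closest-match suggestion, and out-of-range values)
#' in a single error.
#'
#' @param raw a path to a YAML config file, a named list, or `NULL` (all
#'   defaults).
#' @return A validated `experiment_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping or a named list")
  defaults <- config_defaults()
  known <- flat_names(defaults)
  problems <- character(0)

  check_keys <- function(x, template, prefix = "") {
    for (nm in names(x)) {
      full <- paste0(prefix, nm)
      if (!nm %in% names(template)) {
        sugg <- known[which.min(utils::adist(full, known))]
        problems <<- c(problems, sprintf(
          "unknown key '%s' (did you mean '%s'?)", full, sugg))
      } else if (is.list(template[[nm]]) && is.list(x[[nm]])) {
        check_keys(x[[nm]], template[[nm]], paste0(full, "."))
      }
    }
  }
  check_keys(raw, defaults)

  merged <- utils::modifyList(defaults, raw)
  num_rules <- list(
    c("images_per_class >= 1", merged$images_per_class >= 1),
    c("network.alpha_input > 0", merged$network$alpha_input > 0),
    c("network.alpha_output > 0", merged$network$alpha_output > 0),
    c("network.ff_weight_variance > 0", merged$network$ff_weight_variance > 0),
    c("network.dt > 0", merged$network$dt > 0),
    c("network.duration > 0", merged$network$duration > 0),
    c("network.encoder_gain in (0, 1]",
      merged$network$encoder_gain > 0 && merged$network$encoder_gain <= 1),
    c("network.lif.thresh > network.lif.rest",
      merged$network$lif$thresh > merged$network$lif$rest),
    c("network.lif.refrac >= 0", merged$network$lif$refrac >= 0),
    c("network.lif.tc_decay > 0", merged$network$lif$tc_decay > 0),
    c("network.lif.tc_i_decay > 0", merged$network$lif$tc_i_decay > 0))
  for (rule in num_rules)
    if (!isTRUE(as.logical(rule[2])))
      problems <- c(problems, paste("constraint violated:", rule[1]))
  if (!merged$dataset %in% c("numerosity", "mnist", "digit-fixture"))
    problems <- c(problems,
                  "dataset must be numerosity, mnist or digit-fixture")
  if (length(problems) > 0)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))

  lifp <- do.call(lif_params, merged$network$lif)
  net_args <- merged$network
  net_args$lif <- lifp
  net <- do.call(network_config, net_args)
  experiment_config(dataset = merged$dataset,
                    images_per_class = merged$images_per_class,
                    network = net, master_seed = merged$master_seed,
                    output_dir = merged$output_dir,
                    emit_figures = merged$emit_figures,
                    mnist_images = merged$mnist_images,
                    mnist_labels = merged$mnist_labels)
}

build_dataset <- function(config) {
  switch(config$dataset,
    numerosity = generate_numerosity_dataset(config$images_per_class,
                                             config$master_seed),
    `digit-fixture` = generate_digit_dataset(config$images_per_class,
                                             config$master_seed),
    mnist = load_idx_dataset(config$mnist_images, config$mnist_labels,
                             per_class = config$images_per_class))
}

#' Simulate every image of a dataset
#'
#' Presents each image once, with a fresh feedforward weight draw per trial;
#' per-trial seeds derive from `master_seed`.
#'
#' @param dataset a `stimulus_dataset`.
#' @param network a [network_config()].
#' @param master_seed integer master seed.
#' @param kernels optional precomputed [build_kernel_pair()] result.
#' @param verbose print a progress line every 25 trials.
#' @return List of `trial_result`, one per image.
#' @export
simulate_dataset <- function(dataset, network = network_config(),
                             master_seed = 1, kernels = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(dataset, "stimulus_dataset"))
  if (is.null(kernels)) kernels <- build_kernel_pair(network)
  set.seed(as.integer(master_seed))
  trial_seeds <- sample.int(.Machine$integer.max, length(dataset$images))
  trials <- vector("list", length(dataset$images))
  for (i in seq_along(dataset$images)) {
    trials[[i]] <- simulate_trial(dataset$images[[i]], network,
                                  seed = trial_seeds[i], kernels = kernels)
    if (verbose && i %% 25 == 0)
      message("simulated ", i, "/", length(dataset$images), " trials")
  }
  trials
}

#' Run a full experiment
#'
#' Generates (or loads) the stimulus set, simulates every image once with
#' fresh feedforward weights, derives tuning curves, preference
#' distributions and four-scale Gaussian fits, and writes all report files
#' into `config$output_dir`:
#' `trials.csv`, `tuning_curves.csv`, `preferences.csv`, `fits.csv`,
#' `summary.json`, and (optionally) PNG figures rendered from the CSVs.
#'
#' @param config an [experiment_config()] (or anything [validate_config()]
#'   accepts).
#' @param verbose print progress messages.
#' @return An object of class `experiment_report`: list of output paths plus
#'   run metadata (seed, config hash, software version).
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  if (!inherits(config, "experiment_config")) config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  stage <- "stimuli"
  report <- tryCatch({
    dataset <- build_dataset(config)
    if (verbose) message("stage stimuli: ", length(dataset$images), " images")

    stage <- "simulate"
    trials <- simulate_dataset(dataset, config$network, config$master_seed,
                               verbose = verbose)
    paths <- list(trials = file.path(config$output_dir, "trials.csv"))
    write_trials_csv(trials, paths$trials)

    stage <- "analyze"
    curves <- compute_tuning_curves(trials)
    prefs <- preference_distribution(curves)
    avg <- suppressMessages(average_normalized_curves(curves))
    fits <- suppressWarnings(
      fit_all_scales(avg, digit = dataset$kind == "digit"))
    r2 <- mean_r2_per_scale(fits)

    paths$tuning_curves <- file.path(config$output_dir, "tuning_curves.csv")
    write.csv(tuning_curves_long(curves), paths$tuning_curves,
              row.names = FALSE)
    paths$preferences <- file.path(config$output_dir, "preferences.csv")
    write.csv(prefs, paths$preferences, row.names = FALSE)
    paths$average_curves <- file.path(config$output_dir, "average_curves.csv")
    write.csv(as.data.frame(avg), paths$average_curves, row.names = FALSE)
    paths$fits <- file.path(config$output_dir, "fits.csv")
    write.csv(as.data.frame(fits), paths$fits, row.names = FALSE)

    paths$summary <- file.path(config$output_dir, "summary.json")
    summary <- list(
      dataset = config$dataset,
      n_trials = length(trials),
      n_units = length(curves$preferred),
      n_selective = attr(prefs, "n_selective"),
      percent_per_class_selective = as.list(
        stats::setNames(prefs$percent, prefs$class)),
      percent_per_class_all_units = as.list(
        stats::setNames(attr(prefs, "percent_all"), prefs$class)),
      mean_r2_per_scale = as.list(stats::setNames(r2$mean_r2, r2$scale)),
      n_failed_fits = sum(!fits$converged),
      master_seed = config$master_seed,
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("numspike")))
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    if (config$emit_figures) {
      stage <- "figures"
      paths <- c(paths, render_figures(config$output_dir))
    }
    paths
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  structure(list(paths = report, master_seed = config$master_seed,
                 config_hash = config_hash(config),
                 started = t0, finished = Sys.time(),
                 package_version = as.character(utils::packageVersion("numspike"))),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> seed=", x$master_seed,
      " hash=", x$config_hash, "\n", sep = "")
  for (nm in names(x$paths)) cat(sprintf("  %-15s %s\n", nm, x$paths[[nm]]))
  invisible(x)
}

write_trials_csv <- function(trials, path) {
  n_units <- length(trials[[1]]$spike_counts)
  df <- data.frame(
    trial = rep(seq_along(trials), each = n_units),
    label = rep(vapply(trials, `[[`, integer(1), "image_label"), each = n_units),
    unit = rep(seq_len(n_units), length(trials)),
    spike_count = unlist(lapply(trials, `[[`, "spike_counts")),
    rate = unlist(lapply(trials, `[[`, "rates")))
  write.csv(df, path, row.names = FALSE)
}

tuning_curves_long <- function(curves) {
  data.frame(
    unit = rep(seq_len(nrow(curves$mean_rates)), length(curves$classes)),
    class = rep(curves$classes, each = nrow(curves$mean_rates)),
    mean_rate = as.vector(curves$mean_rates),
    preferred = rep(curves$preferred, length(curves$classes)))
}

# Reproducible identifier of the scientific content of a configuration:
# md5 of its canonical YAML dump, excluding fields (output location, figure
# switch) that do not alter the computed results.
config_hash <- function(config) {
  keep <- unclass(config)
  keep$output_dir <- NULL
  keep$emit_figures <- NULL
  dump <- yaml::as.yaml(rapply(keep, as.vector, how = "replace"))
  f <- tempfile()
  writeLines(dump, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Render report figures from a run's CSV files
#'
#' Figures are drawn from the written CSVs, not from in-memory state, so the
#' report directory is the single source of truth: average tuning curves on
#' the linear and log2 abscissae, the preference histogram, mean r-squared
#' per scale, and fitted bandwidth against preferred class.
#'
#' @param dir a directory written by [run_experiment()].
#' @return Named list of PNG paths.
#' @export
render_figures <- function(dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the 'ggplot2' package is required for figures")
  g <- ggplot2::ggplot
  aes <- ggplot2::aes
  avg <- read.csv(file.path(dir, "average_curves.csv"))
  prefs <- read.csv(file.path(dir, "preferences.csv"))
  fits <- read.csv(file.path(dir, "fits.csv"))
  digit <- 0 %in% avg$class
  avg$log2class <- transform_scale(avg$class, "log2", digit = digit)
  out <- list()
  save_fig <- function(name, plot, width = 5, height = 4) {
    path <- file.path(dir, paste0(name, ".png"))
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    out[[name]] <<- path
  }
  save_fig("avg_curves_linear",
           g(avg, aes(class, response, colour = factor(preferred))) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::labs(x = "class", y = "normalized response",
                           colour = "preferred"))
  save_fig("avg_curves_log2",
           g(avg, aes(log2class, response, colour = factor(preferred))) +
             ggplot2::geom_line() + ggplot2::geom_point() +
             ggplot2::labs(x = "log2 class", y = "normalized response",
                           colour = "preferred"))
  save_fig("preference_distribution",
           g(prefs, aes(factor(class), percent)) +
             ggplot2::geom_col() +
             ggplot2::labs(x = "preferred class", y = "% of selective units"))
  r2 <- stats::aggregate(r2 ~ scale, data = fits[fits$converged, ], FUN = mean)
  r2$scale <- factor(r2$scale, levels = TUNING_SCALES)
  save_fig("mean_r2_per_scale",
           g(r2, aes(scale, r2)) + ggplot2::geom_col() +
             ggplot2::labs(y = "mean r-squared"))
  save_fig("sigma_vs_preference",
           g(fits[fits$converged, ], aes(preferred, sigma, colour = scale)) +
             ggplot2::geom_point() +
             ggplot2::labs(x = "preferred class", y = "fitted sigma"))
  out
}
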