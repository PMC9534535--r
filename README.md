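# numspike

Simulation and tuning-curve analysis of an **untrained** two-layer spiking
neural network with lateral inhibition, built to ask a question from
numerical cognition: which signatures of the biological "number sense"
(numerosity-selective neurons, distance and size effects, Weber–Fechner
log-compression) emerge from random connectivity alone — and do the same
signatures appear when the inputs are symbolic digit glyphs instead of dot
displays?

The package is aimed at computational-neuroscience users who want a small,
fully reproducible model of numerosity tuning they can probe on a desktop.

## The model

Two 28×28 sheets of current-based leaky integrate-and-fire neurons
(threshold −52 mV, rest/reset −65 mV, refractory 5 ms, membrane time
constant 100 ms, synaptic-current time constant 2 ms), simulated at 1-ms
resolution:

* **Encoding** — each pixel of intensity *z* ∈ [0,1] spikes per millisecond
  with Bernoulli probability 0.2 *z*, for 2 s per image.
* **Feedforward** — full connectivity, weights redrawn for *every image*
  from N(0.5, 0.1): the network is never trained.
* **Lateral inhibition** — within each layer,
  *w(R) = −exp(−R² / 2α²)* with the Euclidean grid distance R,
  α = 10 (input layer) and α = 20 (output layer).

Tuning analysis: per-unit mean rate per stimulus class → preferred class by
unique argmax → class-wise averaged, min–max-normalized tuning curves →
three-parameter Gaussian fits on four abscissae (x, √x, ∛x, log₂x) with
per-scale mean r² and fitted bandwidths σ.

The hot loop is C++ (RcppArmadillo) with sparse spike propagation; a full
150-image experiment takes ~20 s on one core.

## Worked example

```r
library(numspike)

ds     <- generate_numerosity_dataset(images_per_class = 30, seed = 1)  # 150 images
trials <- simulate_dataset(ds, network_config(), master_seed = 1)
curves <- compute_tuning_curves(trials)

preference_distribution(curves)
#>   class   n percent
#> 1     1  95    13.7
#> 2     2 109    15.7
#> 3     3 118    17.0
#> 4     4 164    23.6
#> 5     5 208    30.0     (694 of 784 units selective)

avg  <- average_normalized_curves(curves)
fits <- fit_all_scales(avg)
mean_r2_per_scale(fits)
#>    scale mean_r2 n_curves
#> 1 linear   0.817        5
#> 2   sqrt   0.825        5
#> 3   cbrt   0.829        5
#> 4   log2   0.840        5

sigma_vs_preference(fits, "linear")
#>   preferred sigma
#> 1         1 0.193
#> 2         2 0.417
#> 3         3 0.793
#> 4         4 1.185
#> 5         5 1.841
```

Reading the output: almost every output unit is numerosity-selective even
though the network never learned anything; numerosity 5 attracts the most
preferences (30%) and 1 a substantial share (13.7%); the Gaussian fit
quality rises monotonically as the abscissa becomes more compressive
(0.817 → 0.840), and the linear-scale bandwidth σ widens with the preferred
numerosity (0.19 → 1.84) — the distance/size-effect picture expected of a
number-sense circuit. The same pipeline with `generate_digit_dataset()`
(or real handwritten digits through `load_idx_dataset()`) produces flat,
poorly-Gaussian digit tuning (mean r² ≈ 0.32) with no distance effect —
the contrast the model exists to demonstrate.

End-to-end runs with report files (CSV + JSON, optional figures):

```r
cfg <- experiment_config(dataset = "numerosity", master_seed = 1,
                         output_dir = "run1", emit_figures = TRUE)
run_experiment(cfg)
```

or from a shell: `Rscript scripts/run_experiment.R --dataset numerosity
--seed 1 --out run1 --figures` (YAML configs via `--config`).

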