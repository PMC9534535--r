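---
title: "Number tuning in an untrained spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Number tuning in an untrained spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numspike)
```

## The question

Numerosity-selective neurons — units whose firing peaks at a particular
number of items — appear in animals without any numerical training, and
their tuning shows two robust signatures: a *distance effect* (responses
fall off as the presented numerosity moves away from the preferred one) and
a *size effect* (tuning curves broaden as the preferred numerosity grows, so
curves become symmetric on a logarithmic axis — Weber–Fechner compression).
`numspike` simulates a deliberately minimal, *untrained* spiking network and
asks which of these signatures emerge from random connectivity alone, and
whether they also emerge when the inputs are symbolic digit glyphs rather
than dot displays.

## The model

The network is two 28×28 sheets of current-based leaky integrate-and-fire
(LIF) neurons. Images are turned into spikes by a Bernoulli rate code: a
pixel of intensity $z \in [0,1]$ emits a spike in each 1-ms step with
probability $0.2\,z$, for 2 s per image. Each encoder spike injects a fixed
current (default 1.0) into the matching input-layer unit.

Between the layers, every input unit connects to every output unit with a
weight drawn fresh for **every image** from $\mathcal N(0.5,\,0.1)$ — the
network never learns; its feedforward wiring is disposable noise around a
positive mean.

Within each layer, units inhibit one another with a strength that decays
with the Euclidean distance $R$ between their grid positions:

$$w_{xy} = -\exp\!\left(-\frac{R_{xy}^2}{2\alpha^2}\right),$$

with $\alpha_\text{input} = 10$ and $\alpha_\text{output} = 20$ grid units.
Lateral inhibition is what converts "more items" into structured
competition instead of uniformly more activity.

Membrane dynamics per 1-ms step: the synaptic current decays by
$e^{-dt/\tau_i}$ ($\tau_i = 2$ ms) and collects the step's input; the
voltage of non-refractory units decays toward rest ($-65$ mV,
$\tau_v = 100$ ms) and integrates the current; crossing $-52$ mV emits a
spike, resets the voltage to $-65$ mV and silences the unit for 5 ms.
Refractory units hold the reset voltage and ignore input. The exponential
decay factors are exact for the linear subthreshold dynamics, so the only
discretisation effect is the 1-ms alignment of spikes, and the update is
deterministic given the encoder raster and the weights. Voltage has no
lower bound.

### Choices the design left open

* **Kernel form.** A literal reading of the lateral weight as
  $-e^{-R^2\alpha^2}$ contradicts calling $\alpha$ a standard deviation and
  the statement that larger $\alpha$ widens the inhibition range (it would
  do the opposite, collapsing the kernel to almost nothing beyond $R = 0$).
  The default is therefore the Gaussian written above; the literal variant
  stays available as `lateral_form = "literal"` for anyone who wants the
  printed formula verbatim.
* **Self-connections** are excluded (zero kernel diagonal): self-inhibition
  is not part of the described circuit, and refractoriness already limits
  self-firing.
* **One recurrent stage per layer.** Lateral inhibition acts as ordinary
  recurrent connections with a one-timestep synaptic delay — each layer
  inhibits itself continuously as it fires, not through an iterated
  relaxation to equilibrium.
* **Encoder coupling.** How strongly an encoder spike drives its input
  neuron is not specified anywhere; `input_injection_amplitude = 1` makes a
  saturating pixel (0.2 spikes/ms) depolarise its unit far beyond the 13 mV
  needed to fire, which is the weakest assumption that makes bright pixels
  reliably active. It is a configuration field, not a constant.

## Stimuli

*Numerosity displays.* 28×28 binary images containing 1–5 disks of exactly
25 foreground pixels each (the pixel-offset set $dx^2 + dy^2 \le 8.5$ has
exactly 25 members). Centres are drawn uniformly with rejection: at least
3 px from the frame and at least 6 px apart, which guarantees disjoint
masks; placement failing 10,000 rejection draws is an error, never a
quieter image. The default dataset is 30 images per numerosity (150 total).

*Digit glyphs.* The package reads real handwritten-digit datasets from IDX
files (`read_idx_images()`, `load_idx_dataset()`). For fully offline work it
also ships a **synthetic** stroke-rendered digit fixture: seven-segment
glyphs with anti-aliased edges, ±2 px translation jitter and mild stroke
width variation. The fixture emulates the *format* of handwritten digits
(centered grayscale glyph, ten classes), not their statistics: its per-class
ink areas are nearly uniform, whereas real handwriting gives some digits
(0, 8) markedly more ink than others (1, 7). Conclusions that depend on
those class asymmetries — notably which digits attract the most preferences
— do not transfer from the fixture to real data, and the fixture is
documented as a test double for exactly that reason.

## Analysis

Per output unit, the mean rate per class over all trials of that class is
its tuning curve; a unit that fired at least once and whose curve has a
unique maximum is *selective*, preferring the argmax class. Ties are
excluded rather than broken arbitrarily, to keep the preference histogram
unbiased. The preference distribution is reported both as a share of
selective units and of all 784 units (`summary.json` carries both, since
either denominator is defensible).

Curves sharing a preferred class are averaged unit-wise and min–max
normalized to $[0,1]$. Each average curve is then fitted with a
three-parameter Gaussian $a\,e^{-(t-\mu)^2/2\sigma^2}$ on four abscissae:
$x$, $x^{1/2}$, $x^{1/3}$ and $\log_2 x$ (digits use $\log_2(x+1)$ because
class 0 exists). The goodness of fit is $r^2 = 1 - SS_{res}/SS_{tot}$; if
tuning is log-compressed, $r^2$ should rise with abscissa non-linearity
and the linear-scale $\sigma$ should grow with the preferred class while
the nonlinear-scale $\sigma$ stays flat.

### Numerical choices in the fit

Fits use Levenberg–Marquardt (`minpack.lm::nls.lm`) with the amplitude
started at the curve maximum, the centre at its abscissa, and several
initial widths (1/8 to 1 of the abscissa range), keeping the best converged
solution. Parameters are bounded: $a \in [0, 2\max|y|]$, $\mu$ within the
tested class range, $\sigma \ge 10^{-3}$. The centre bound matters: curves
peaking at an edge class otherwise drift along a ridge
($a \to$ hundreds, $\mu \to$ far outside the axis) that lowers the residual
slightly but has no tuning interpretation and corrupts the bandwidth
summaries. Non-converged fits are flagged, excluded from scale averages,
and counted in the report rather than dropped silently.

## What a default run computes

One experiment (`run_experiment()`) simulates each image once — fresh
feedforward weights per image, per-trial seeds derived from the master seed
up front so results are independent of execution order — and writes
`trials.csv`, `tuning_curves.csv`, `preferences.csv`, `average_curves.csv`,
`fits.csv` and `summary.json`; figures are optional and always re-derived
from the CSVs. Identical configuration and seed reproduce the CSVs
byte-for-byte.

The reference analyses in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run the 150-image numerosity study at three master
seeds (450 trials, ~1 minute on one core thanks to the sparse-propagation
C++ loop): preference percentages are computed per seed and averaged, while
the average tuning curves and their Gaussian fits are computed once over the
pooled trials (90 images per class), mirroring the practice of fitting the
*averaged* curves rather than averaging per-run fits. The digit study uses
the synthetic fixture at 30 glyphs per class.

With the defaults above, the simulations in this package's test suite
reproduce the qualitative contrast the model was built to show — numerosity
tuning is strongly Gaussian (mean $r^2 \approx 0.84$–0.90 linear, rising
monotonically toward $\log_2$) while digit tuning is not (mean
$r^2 \approx 0.32$, no distance effect on any curve) — and the extreme
numerosities 1 and 5 attract preferences at rates compatible with the
published ones. Two finer signatures do **not** fully emerge under these
conditions: middle numerosities (especially 4) retain more preferences than
a clean U-shape implies, and the nonlinear-scale bandwidths compress
(about 4× spread on the linear axis versus 1.9× on $\log_2$) without
becoming flat. Both traces stem from overall activity growing with item
count under the unspecified encoder coupling; the corresponding acceptance
checks are left failing rather than the conditions being adjusted to pass
them.

## Limitations

* The model is untrained by construction; nothing here supports claims
  about learned symbolic-number representations.
* The digit fixture cannot stand in for real handwriting where class-wise
  ink statistics matter (see above); pass real IDX files via
  `dataset = "mnist"` for those questions.
* Tuning in this network is a property of *population statistics* (fresh
  random weights each trial), not of persistent single-unit wiring; unit
  identities carry no meaning across experiments.
* Spike traces and any plasticity-related machinery are deliberately not
  modelled.
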