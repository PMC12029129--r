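# nmrquant

Neural-network quantification of metabolite concentrations directly from
simulated 1D ¹H-NMR spectra.

## The problem

Turning a one-dimensional proton NMR spectrum of a biological extract
into a table of metabolite concentrations is traditionally a
lineshape-fitting exercise: minutes per spectrum, expert supervision,
and poor scaling to modern cohort sizes. A trained neural network does
the same mapping in milliseconds. The catch is training data — real
spectra with accurate ground truth are scarce — so the practical route
is to *simulate* realistic mixture spectra from a reference library and
train on those.

`nmrquant` implements that entire workflow in R, with no deep-learning
framework dependency:

* **Simulation** — per-metabolite 1 mM reference spectra as Lorentzian
  multiplet sums on a shared −0.32…10.21 ppm grid (or loaded from
  `ppm,intensity` text files), five concentration samplers spanning a
  high dynamic range (0.005–20 mM), analyte leave-out schemes, and a
  data-augmentation workflow: per-analyte chemical-shift jitter
  (≤ 3.4 ppb), exponential line broadening (0–1 Hz), up to three
  interference singlets, Gaussian noise (30–115% of a reference level,
  scaled across field strengths by (400/f)^{3/2}), and baseline drift
  (≤ 5.6% of the TSP peak). Every spectrum carries the 0.3 mM TSP-d4
  internal standard; glucose anomers are combined 0.36/0.64.
* **Models** — multi-layered perceptron, 1-D CNN, and encoder-only
  transformer (binned spectrum → shared linear embedding → sinusoidal
  positional encodings → encoder blocks → flatten → linear head), with
  forward passes, hand-derived backpropagation and AdamW implemented in
  base matrix algebra and verified against finite differences.
* **Losses** — RAE, RSE, MSE, quantile (q = 0.1/0.5/0.9), LogCosh,
  MSLE, MAPE, and a standardised 50:50 MSE+MAPE mix, as pure functions
  with analytic gradients.
* **Protocol** — gradient accumulation to an effective batch size,
  best-checkpoint early stopping (patience 50), per-architecture epoch
  caps, per-spectrum MAPE with Student-t 95% intervals, normalisation
  against baseline reports, and a seeded hyperparameter search with
  median/threshold pruning.

The core statistic everywhere is the mean absolute percent error,
MAPE = 100 · mean(|ĉ − c| / c), averaged over analytes within a
spectrum and then over test spectra.

## Worked example

Simulate an 8-metabolite library, train a compact transformer, and
evaluate it (a few minutes on one CPU; shrink `n_spectra`/`max_epochs`
for a smoke run):

```r
library(nmrquant)

res <- run_headline_experiment(seed = 1)
res$mean_mape   # mean MAPE (%) over 10 uniform test spectra
res$nnls_mape   # non-negative least squares on the same spectra
glance(res$fit) # epochs, best validation RAE
```

On this run (seed 1) the printout was:

```
> res$mean_mape
[1] 2.251
> res$nnls_mape
[1] 37.116
```

i.e. the transformer quantifies all eight analytes of the uniform test
spectra to ~2% mean error, while the classical linear baseline (NNLS
against the clean reference library) is defeated by the augmentations —
baseline drift, shift jitter, line broadening and interference — that
the network has learned to be invariant to.

The lower-level surface is pipe-friendly: `default_library()` →
`build_dataset()` → `train_model()` → `evaluate_model()`, with
`tidy()`/`glance()`/`autoplot()` methods on fitted models and reports,
`baseline_presets()` for the six reference configurations, `tune()` for
hyperparameter search, and a CLI (`inst/scripts/nmrquant`) wrapping
simulate/train/evaluate/tune for shell use.

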