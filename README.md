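# pcdrad

Simulation and evaluation of **spectral chest radiography with CdTe
photon-counting detectors (PCDs)** in R.

Spectral radiography sorts detected photons into energy bins set by
comparator thresholds. Because aluminum (bone-equivalent) and PMMA
(soft-tissue-equivalent) attenuate with different energy dependence, the
per-pixel bin counts can be inverted into basis-material thickness maps
("material decomposition"). How well that inversion works depends on the
detector's spectral distortions (charge sharing, electronic noise, escape),
the dose, the number of thresholds, and — centrally — the regression model
used for the inversion and the density of the calibration data it is
trained on. `pcdrad` is a desk-scale laboratory for those trade-offs,
aimed at medical-imaging physicists: it generates digital LucAl/IEC-style
phantoms, forward-projects them through a parametric CdTe PCD model with
charge sharing and Poisson noise, decomposes the bin images with three
regressors, and scores the results with quantitative and task-based
figures of merit.

## What it computes

* **Forward model** — polychromatic Beer–Lambert transmission
  `I(E) = I0(E) exp(−μ_Al(E)·x_Al − μ_PMMA(E)·x_PMMA)` through per-pixel
  thickness maps; a detector response function (DRF) matrix `R_ij`
  (photopeak + charge-sharing tail + Cd/Te escape lines + Gaussian
  broadening); threshold binning; a 3×3 charge-sharing convolution of the
  mean bin images; independent Poisson sampling; 10×10 rebinning to 1 mm
  analysis pixels.
* **Decomposition** — per-pixel features `f_k = −log(n_k / n_{k,0})`
  mapped to `(t̂_Al, t̂_PMMA)` by (i) a full second-degree polynomial,
  (ii) a 2×128 ReLU multilayer perceptron, (iii) RBF support vector
  regression (`C = 100`, `ε = 0.01`), all trained on the same noise-free
  calibration grid (`decomp_fit()`, with `predict`/`coef`/`residuals`
  methods).
* **Quantitative accuracy** — per-insert bias `Δ = mean(t̂ − t_true)` and
  `RMSE = sqrt(mean((t̂ − t_true)²))` over ROI means from repeated noise
  realizations.
* **Detectability** — unknown-location low-contrast detection scored by a
  unit-sum disk matched filter, summarized by the nonparametric EFROC area
  `A_FE = (1/I) Σ_i exp(−(1/N) Σ_j H(y_j − x_i))` with Hanley–McNeil
  standard errors.
* **Sweeps** — dose (0.075 / 1.725 / 7.5 mAs), calibration grid (3×3,
  5×5, 8×8), and threshold count (M = 2–6) experiments via
  `run_accuracy_sweep()`, `run_efroc_sweep()`, and an MLP architecture
  study (`run_mlp_architecture_study()`).

## Worked example

```r
library(pcdrad)
spectrum   <- load_spectrum()                 # 120 kVp, 2 mm Al
drf        <- build_drf()                     # parametric CdTe response
thresholds <- default_thresholds(4)           # 20, 40, 60, 80 keV
grid   <- make_calibration_grid(8, spectrum, drf, thresholds)
model  <- decomp_fit(grid, "poly2")

phantom <- build_quant_phantom()              # 4.1 mm Al + 83 mm PMMA + inserts
noisy   <- simulate_acquisition(phantom, spectrum, drf, thresholds,
                                exposure_mas = 7.5, seed = 0)
open_beam <- open_beam_counts(spectrum, drf, thresholds, 7.5)
maps <- decompose(model, to_features(noisy, open_beam))
insert_accuracy(list(maps), phantom)
```

```
   insert material t_true_mm   bias_mm  rmse_mm std_mm n_realizations
1       1       al       4.6 -0.000816 0.000816      0              1
2       2       al       5.1 -0.001438 0.001438      0              1
...
10     10     pmma      93.0  0.001375 0.001375      0              1
```

At 7.5 mAs with an 8×8 calibration grid and four thresholds, the
polynomial decomposition recovers every insert thickness to a few
micrometers' ROI-mean error — noise and model bias are both far below the
insert contrasts. The matching detection task saturates:

```r
run_efroc_task("al_lcd", model, spectrum, drf, thresholds,
               dose_mas = 7.5, R = 10, seed_base = 0)
#> <efroc_result> al_lcd, model, 7.5 mAs: A_FE = 1.0000 (sigma 0.0000), I = 10, J = 951
```

i.e. every true-positive score beats all 951 pooled false-positive marks,
so the 0.1 mm aluminum disk is detected essentially perfectly at the
highest dose. A command-line wrapper for the sweep experiments is
installed at `inst/scripts/pcdrad`.

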