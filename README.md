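# oxispec

Multi-wavelength spectral pulse oximetry in R: estimate peripheral
oxygen saturation (SpO₂) from finger-transmission spectra with a small
one-dimensional convolutional network, and compare it against the
classical dual-wavelength ratio-of-ratios method.

## The problem and the approach

A transmission pulse oximeter shines light through a finger and infers
the arterial oxygen saturation from how strongly oxyhemoglobin (HbO₂)
and deoxyhemoglobin (Hb) absorb at different wavelengths. The classical
two-wavelength method forms the ratio of ratios

    Q = ln((DC₁ − AC₁)/DC₁) / ln((DC₂ − AC₂)/DC₂) ≈ (AC₁/DC₁)/(AC₂/DC₂)

from the pulsatile (AC) and quasi-static (DC) intensity at a red and a
near-infrared wavelength and maps it to SpO₂ through an empirical
calibration. With a 12-channel spectral sensor pair (channel centers
450–860 nm) one can do better: feed the normalized transmitted spectrum
to a 1D-CNN classifier over the ten labels {81, 83, …, 99} % and decode
its softmax weights W into a scalar estimate by weighted-label
expectation,

    SpO₂ = Σᵢ Lᵢ · Wᵢ ,

which yields sub-percent resolution from a 2-percentage-point label
grid.

The package implements the full pipeline:

- **Simulator** — Beer–Lambert transmission through a perfused finger
  (`simulator_config()`, `simulate_frame()`, `generate_sweep()`), with
  Gaussian channel bands, a bloodless-tissue baseline, pulsatile AC
  generation and 16-bit quantization. The packaged extinction table
  (`hemoglobin_extinction()`) is transcribed from the standard
  Prahl/Zijlstra compilation.
- **Preprocessing** — per-curve min–max normalization, region
  selection (`FIRST` = 450–610 nm, `SECOND` = 650–860 nm, `FULL`, and
  the S11–S24 three-channel sub-regions), and uniform multiplicative
  noise augmentation into 1000 rows per concentration
  (`build_dataset()`).
- **Model** — the 1D-CNN (conv–conv–pool twice, dense hidden layers
  with dropout, 10-way softmax) written in plain R with Adam and
  backpropagation: `oxi_cnn()` returns a classed fit with `predict`,
  `print`, `summary`, `plot`, `residuals` methods; `decode_spo2()` is
  the expectation decoder.
- **Hyperparameter search** — exhaustive `grid_search()` with
  stratified cross-validation and Gaussian-process `bayes_opt()` with
  expected improvement, plus two-stage `coarse_then_fine()`.
- **Baseline** — `q_exact()`, `q_approx()`, `fit_q_calibration()`,
  `spo2_from_q()`.
- **Evaluation** — `accuracy()`, `deviation_report()`,
  `calibration_fit()`, and the region × noise `run_ablation()` harness.
- **Streaming** — `median_filter()`, `moving_average()`,
  `stream_estimate()` for dynamic measurement at the sensor's 0.7 s
  interval.

A thin command-line interface is installed at
`system.file("cli", "oxispec.R", package = "oxispec")` with subcommands
`simulate`, `build-dataset`, `train`, `tune`, `evaluate`, `ablate`,
`stream` and `baseline`.

## Worked example

```r
library(oxispec)

# 1. simulate one clean frame per concentration, 81..99 % step 2
frames <- generate_sweep(cfg = simulator_config(sensor_noise_sd = 0), seed = 1)

# 2. second-region dataset, 2 % noise augmentation, 200 rows per label
ds <- build_dataset(frames, "SECOND", noise_ratio = 0.02,
                    n_rows_per_label = 200, seed = 1)
sp <- train_test_split(ds, prop = 0.8, seed = 1)

# 3. train the 1D-CNN (best-model architecture, reduced 30-epoch budget)
fit <- oxi_cnn(sp$train, config = cnn_config(epochs = 30, seed = 1))
accuracy(fit, sp$test, type = "class")
#> [1] 0.945

# 4. decode and summarize per-concentration deviations
decoded <- predict(fit, sp$test$X, type = "spo2")
deviation_report(decoded, sp$test$y)
#> Per-concentration deviation of decoded SpO2 (%):
#>  label max_abs_deviation mean_abs_deviation std_deviation
#>     81            1.0565            0.85721       0.10296
#>     83            0.8952            0.49065       0.24822
#>     ...
#>     99            0.0327            0.00194       0.00575
#> Total relative error: 0.450%

calibration_fit(decoded, sp$test$y)
#> <calibration_fit> predicted = 0.9994 * reference +0.1776  (R^2 = 0.9911, n = 400)

# 5. classical dual-wavelength baseline on the same sweep
cal <- fit_q_calibration(frames)
mean(abs(spo2_from_q(frames, cal) - seq(81, 99, 2)))
#> [1] 1.052812
```

The argmax accuracy (0.94 here) is the fraction of test rows classified
into exactly the right 2-point label; the total relative error (≈0.45 %)
summarizes the expectation-decoded estimates, whose calibration against
the true labels has slope ≈ 1 and R² ≈ 0.99. The ratio-of-ratios
baseline on the same simulated sweep is an order of magnitude coarser
(MAE ≈ 1 %), illustrating why the multi-wavelength classifier is worth
its complexity.

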