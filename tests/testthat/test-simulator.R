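test_that("band weights form a normalized truncated Gaussian", {
  for (center in c(450, 650, 860)) {
    ch <- sensor_channels(center)
    w <- band_weights(ch, grid_step_nm = 1)
    expect_equal(sum(w$weight), 1, tolerance = 1e-9)
    expect_equal(w$wavelength_nm[which.max(w$weight)], center)
    # half maximum at center +/- FWHM/2
    half <- w$weight[w$wavelength_nm == center + ch$fwhm_nm / 2] /
      w$weight[w$wavelength_nm == center]
    expect_equal(half, 0.5, tolerance = 0.05 * 0.5)
    expect_equal(range(w$wavelength_nm),
                 c(center - 2 * ch$fwhm_nm, center + 2 * ch$fwhm_nm))
  }
  expect_error(band_weights(sensor_channels(650), grid_step_nm = 0),
               "positive")
})

test_that("absorbance follows the Beer-Lambert mixture", {
  cfg <- clean_cfg()
  # saturation-independence at an exactly isosbestic wavelength
  iso <- data.frame(wavelength_nm = c(500, 700, 900),
                    eps_hb = c(2, 1, 0.5), eps_hbo2 = c(2, 1, 0.5))
  cfg_iso <- simulator_config(chromophores = iso, sensor_noise_sd = 0)
  a <- vapply(seq(0, 1, by = 0.25), absorbance,
              channel = 9, cfg = cfg_iso, numeric(1))
  expect_equal(diff(range(a)), 0, tolerance = 1e-12)
  # zero path and zero tissue give zero absorbance
  cfg0 <- simulator_config(path_length_cm = 1e-12, tissue_od = rep(0, 12),
                           sensor_noise_sd = 0)
  expect_equal(absorbance(0.9, 7, cfg0), 0, tolerance = 1e-9)
  # with the packaged table, 650 nm absorbance falls as saturation rises
  a650 <- vapply(c(0, 0.5, 1), absorbance, channel = 7, cfg = cfg, numeric(1))
  expect_true(all(diff(a650) < 0))
  expect_error(absorbance(1.2, 7, cfg), "\\[0, 1\\]")
})

test_that("frames are deterministic, pulsation-free at zero fraction, and ADC-bounded", {
  cfg <- simulator_config(pulsatile_fraction = 0)
  f <- simulate_frame(91, cfg, seed = 5)
  expect_true(all(f$ac == 0))
  cfg2 <- simulator_config()
  f1 <- simulate_frame(91, cfg2, seed = 5)
  f2 <- simulate_frame(91, cfg2, seed = 5)
  expect_identical(f1$dc, f2$dc)
  expect_identical(f1$ac, f2$ac)
  expect_true(all(f1$dc >= f1$ac & f1$ac >= 0))
  expect_true(all(f1$dc <= 2^16 - 1))
  expect_true(all(f1$dc == round(f1$dc)))
  expect_error(simulate_frame(79, cfg2), "\\[81, 99\\]")
})

test_that("second-region curves separate across saturation far more than first-region", {
  f81 <- simulate_frame(81, clean_cfg())
  f99 <- simulate_frame(99, clean_cfg())
  nrm <- function(f, region) {
    suppressWarnings(normalize_spectrum(select_region(f, region)$dc))
  }
  d_first <- mean(abs(nrm(f81, "FIRST") - nrm(f99, "FIRST")))
  d_second <- mean(abs(nrm(f81, "SECOND") - nrm(f99, "SECOND")))
  expect_gt(d_second, d_first)
  expect_gt(d_second, 0.02)
})

test_that("DC intensity decreases with path length and AC/DC stays small-signal", {
  base <- hires_cfg()
  longer <- simulator_config(channels = sensor_channels(adc_bits = 24),
                             source_intensity = 1.5e7, sensor_noise_sd = 0,
                             path_length_cm = 1.15)
  f1 <- simulate_frame(91, base)
  f2 <- simulate_frame(91, longer)
  live <- f1$dc > 0
  expect_true(all(f2$dc[live] < f1$dc[live]))
  # pulsatile_fraction at the 0.05 limit keeps AC/DC < 0.1 across the
  # usable (second-region) channels - the regime where the approximate
  # ratio-of-ratios formula applies
  nir <- paste0("nm", region_spec("SECOND")$centers_nm)
  for (lab in c(81, 99)) {
    cfg5 <- simulator_config(channels = sensor_channels(adc_bits = 24),
                             source_intensity = 1.5e7, sensor_noise_sd = 0,
                             pulsatile_fraction = 0.05)
    f <- simulate_frame(lab, cfg5)
    expect_true(all(f$ac[nir] / f$dc[nir] < 0.1))
  }
  # at the default 16-bit resolution every live channel is small-signal
  cfg16 <- simulator_config(pulsatile_fraction = 0.05, sensor_noise_sd = 0)
  f16 <- simulate_frame(81, cfg16)
  live <- f16$dc > 0
  expect_true(all(names(f16$dc)[live] %in% nir))
})

test_that("sweeps have the right size, labels and determinism", {
  frames <- generate_sweep(cfg = clean_cfg(), seed = 1)
  expect_length(frames, 10)
  expect_equal(vapply(frames, function(f) f$spo2, numeric(1)),
               seq(81, 99, by = 2))
  s1 <- generate_sweep(n_per_label = 3, cfg = simulator_config(), seed = 9)
  s2 <- generate_sweep(n_per_label = 3, cfg = simulator_config(), seed = 9)
  expect_length(s1, 30)
  expect_identical(lapply(s1, `[[`, "dc"), lapply(s2, `[[`, "dc"))
  expect_error(generate_sweep(numeric(0), cfg = simulator_config()),
               "non-empty")
})

test_that("chromophore table passes its physical invariants and bad tables fail", {
  tab <- hemoglobin_extinction()
  expect_equal(nrow(tab), 12)
  expect_true(all(diff(tab$wavelength_nm) > 0))
  i650 <- tab$wavelength_nm == 650
  expect_gt(tab$eps_hb[i650], tab$eps_hbo2[i650])
  bad <- tab
  bad$eps_hb[i650] <- bad$eps_hbo2[i650] / 2
  expect_error(validate_chromophores(bad), "red-region")
  expect_error(validate_chromophores(tab[c(2, 1, 3:12), ]), "ascending")
})
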