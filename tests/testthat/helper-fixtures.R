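# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Noiseless simulator configuration (quantization still active).
clean_cfg <- function() {
  fixture("clean_cfg", function() simulator_config(sensor_noise_sd = 0))
}

# High-resolution configuration: 24-bit ADC and a bright source, for
# probing the optical laws without quantization artifacts.
hires_cfg <- function() {
  fixture("hires_cfg", function() {
    simulator_config(channels = sensor_channels(adc_bits = 24),
                     source_intensity = 1.5e7, sensor_noise_sd = 0)
  })
}

clean_frames <- function() {
  fixture("clean_frames", function() generate_sweep(cfg = clean_cfg(), seed = 1))
}

hires_frames <- function() {
  fixture("hires_frames", function() generate_sweep(cfg = hires_cfg(), seed = 1))
}

# Small second-region dataset at 2% noise and a model trained on it.
small_dataset <- function() {
  fixture("small_dataset", function() {
    build_dataset(clean_frames(), "SECOND", noise_ratio = 0.02,
                  n_rows_per_label = 100, seed = 1)
  })
}

small_model <- function() {
  fixture("small_model", function() {
    oxi_cnn(small_dataset(), config = cnn_config(epochs = 60, seed = 1))
  })
}
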