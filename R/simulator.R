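#' Exponentially decaying baseline tissue optical density
#'
#' Effective bloodless-tissue attenuation (absorption plus scattering
#' loss) per channel, modeled as a single decreasing exponential of
#' wavelength. The default magnitude places the visible channels of a
#' transilluminated finger at or below the detector quantization floor
#' while leaving the NIR channels in the sensor's dynamic range.
#'
#' @param centers_nm Channel centers in nm.
#' @param od_450 Optical density at 450 nm.
#' @param decay_nm Exponential decay constant in nm.
#' @return Numeric vector of optical densities, one per channel.
#' @export
tissue_od_exponential <- function(centers_nm, od_450 = 52, decay_nm = 60) {
  od_450 * exp(-(centers_nm - 450) / decay_nm)
}

#' Simulator configuration
#'
#' Bundles everything the Beer-Lambert finger-transmission simulator
#' needs: the chromophore extinction table, the optical path, the
#' effective hemoglobin concentration along it, the pulsatile path
#' fraction driving the AC component, the per-channel bloodless-tissue
#' optical density, the per-channel source intensity, and a fractional
#' sensor noise level.
#'
#' @param chromophores Chromophore table, see [hemoglobin_extinction()].
#' @param channels Sensor channel table, see [sensor_channels()].
#' @param path_length_cm Optical path length through the finger (cm).
#' @param hb_total Effective total hemoglobin concentration along the
#'   path (mmol/L). This is a path-averaged quantity: whole blood is
#'   ~2.3 mmol/L but occupies only part of the transilluminated volume.
#' @param pulsatile_fraction Fraction of the arterial path modulated by
#'   the pulse (dimensionless, must lie in (0, 0.2) or be exactly 0).
#' @param tissue_od Per-channel baseline optical density of bloodless
#'   tissue.
#' @param source_intensity Per-channel illumination reaching the detector
#'   through a bloodless, tissueless path, in ADC counts (scalar recycled).
#' @param sensor_noise_sd Fractional (multiplicative, Gaussian) intensity
#'   noise applied before quantization; 0 gives noiseless frames.
#' @param grid_step_nm Wavelength grid step for band integration (nm).
#' @return An object of class `simulator_config`.
#' @export
#' @examples
#' cfg <- simulator_config()
#' cfg$hb_total
simulator_config <- function(chromophores = hemoglobin_extinction(),
                             channels = sensor_channels(),
                             path_length_cm = 1.0,
                             hb_total = 0.70,
                             pulsatile_fraction = 0.02,
                             tissue_od = tissue_od_exponential(channels$center_nm),
                             source_intensity = 60000,
                             sensor_noise_sd = 0.005,
                             grid_step_nm = 1) {
  validate_chromophores(chromophores)
  if (path_length_cm <= 0) stop("path_length_cm must be positive", call. = FALSE)
  if (pulsatile_fraction < 0 || pulsatile_fraction >= 0.2) {
    stop("pulsatile_fraction must lie in [0, 0.2)", call. = FALSE)
  }
  n <- nrow(channels)
  source_intensity <- rep_len(source_intensity, n)
  tissue_od <- rep_len(tissue_od, n)
  if (any(source_intensity <= 0)) stop("source_intensity must be positive", call. = FALSE)
  if (any(tissue_od < 0)) stop("tissue_od must be non-negative", call. = FALSE)
  if (sensor_noise_sd < 0) stop("sensor_noise_sd must be non-negative", call. = FALSE)
  structure(list(
    chromophores = chromophores,
    channels = channels,
    path_length_cm = path_length_cm,
    hb_total = hb_total,
    pulsatile_fraction = pulsatile_fraction,
    tissue_od = tissue_od,
    source_intensity = source_intensity,
    sensor_noise_sd = sensor_noise_sd,
    grid_step_nm = grid_step_nm
  ), class = "simulator_config")
}

# Band-averaged extinction (L/mmol/cm) of a saturation-s hemoglobin mixture
# over one channel's Gaussian band; extinction is interpolated linearly over
# the chromophore table and clamped at its ends.
band_extinction <- function(s, channel, cfg) {
  bw <- band_weights(channel, cfg$grid_step_nm)
  tab <- cfg$chromophores
  eps_hb <- stats::approx(tab$wavelength_nm, tab$eps_hb, bw$wavelength_nm,
                          rule = 2)$y
  eps_hbo2 <- stats::approx(tab$wavelength_nm, tab$eps_hbo2, bw$wavelength_nm,
                            rule = 2)$y
  sum(bw$weight * (s * eps_hbo2 + (1 - s) * eps_hb))
}

#' Optical density of the simulated finger at one channel
#'
#' Beer-Lambert absorbance of the hemoglobin mixture at fractional
#' arterial saturation `s`, band-averaged over the channel response,
#' plus the bloodless-tissue baseline at that channel:
#' A = d * c_Hb * (s * eps_HbO2 + (1 - s) * eps_Hb) + A_tissue.
#'
#' @param spo2_fraction Saturation as a fraction in \[0, 1\].
#' @param channel One row of `cfg$channels` (or its index into them).
#' @param cfg A [simulator_config()].
#' @return Optical density (dimensionless, >= 0).
#' @export
#' @examples
#' cfg <- simulator_config()
#' absorbance(0.97, 7, cfg)  # 650 nm channel
absorbance <- function(spo2_fraction, channel, cfg) {
  if (spo2_fraction < 0 || spo2_fraction > 1) {
    stop("spo2_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.numeric(channel) && length(channel) == 1 && channel == floor(channel)) {
    idx <- as.integer(channel)
    channel <- cfg$channels[idx, ]
    t_od <- cfg$tissue_od[idx]
  } else {
    idx <- match(channel$center_nm[1], cfg$channels$center_nm)
    t_od <- if (is.na(idx)) 0 else cfg$tissue_od[idx]
  }
  eps <- band_extinction(spo2_fraction, channel, cfg)
  cfg$path_length_cm * cfg$hb_total * eps + t_od
}

#' Simulate one finger-clip spectral frame
#'
#' Transmitted DC intensity per channel follows Beer-Lambert decay,
#' `DC = S * 10^(-A)`; the pulsatile AC amplitude is the intensity lost
#' when the arterial path lengthens by `pulsatile_fraction * path` of
#' blood during systole. Both are quantized to the ADC integer range
#' (round-half-even); channels whose raw intensity quantizes to zero are
#' flagged as underflowed, saturating channels as saturated.
#'
#' @param spo2_percent True SpO2 label in percent, in \[81, 99\].
#' @param cfg A [simulator_config()].
#' @param seed Optional integer seed for the sensor noise; ignored when
#'   `cfg$sensor_noise_sd == 0`.
#' @param timestamp Acquisition time in seconds.
#' @return An object of class `spectral_frame`: list with `channels`,
#'   `dc`, `ac` (named by `nm<center>`), `spo2`, `timestamp`, and a
#'   per-channel `flag` ("ok", "underflow" or "saturated").
#' @export
#' @examples
#' fr <- simulate_frame(97, simulator_config(), seed = 1)
#' fr$dc
simulate_frame <- function(spo2_percent, cfg, seed = NULL, timestamp = 0) {
  if (spo2_percent < 81 || spo2_percent > 99) {
    stop("spo2_percent must lie in [81, 99]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  s <- spo2_percent / 100
  ch <- cfg$channels
  n <- nrow(ch)
  adc_max <- 2^ch$adc_bits - 1

  a_dc <- vapply(seq_len(n), function(i) absorbance(s, i, cfg), numeric(1))
  # extra systolic path of blood only (no tissue term)
  eps_band <- vapply(seq_len(n), function(i) band_extinction(s, ch[i, ], cfg),
                     numeric(1))
  a_pulse <- cfg$pulsatile_fraction * cfg$path_length_cm * cfg$hb_total * eps_band

  dc_raw <- cfg$source_intensity * 10^(-a_dc)
  if (cfg$sensor_noise_sd > 0) {
    dc_raw <- dc_raw * (1 + stats::rnorm(n, 0, cfg$sensor_noise_sd))
    dc_raw <- pmax(dc_raw, 0)
  }
  ac_raw <- dc_raw * (1 - 10^(-a_pulse))

  saturated <- dc_raw > adc_max
  dc <- round(pmin(dc_raw, adc_max))
  ac <- pmin(round(ac_raw), dc)
  flag <- rep("ok", n)
  flag[dc == 0] <- "underflow"
  flag[saturated] <- "saturated"

  nm <- paste0("nm", ch$center_nm)
  structure(list(
    channels = ch,
    dc = stats::setNames(as.numeric(dc), nm),
    ac = stats::setNames(as.numeric(ac), nm),
    spo2 = spo2_percent,
    timestamp = timestamp,
    flag = stats::setNames(flag, nm)
  ), class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat("<spectral_frame> SpO2 =", x$spo2, "% at t =", x$timestamp, "s\n")
  print(rbind(dc = x$dc, ac = x$ac))
  if (any(x$flag != "ok")) {
    cat("flags:", paste0(names(x$flag)[x$flag != "ok"], "=",
                         x$flag[x$flag != "ok"], collapse = " "), "\n")
  }
  invisible(x)
}

#' Simulate a labeled sweep of spectral frames
#'
#' Generates `n_per_label` frames for each SpO2 label, deterministically
#' under `seed`. Frames are time-stamped at the sensor's 0.7 s reading
#' interval in generation order.
#'
#' @param labels Ascending vector of SpO2 labels in percent
#'   (default 81, 83, ..., 99).
#' @param n_per_label Frames per label.
#' @param cfg A [simulator_config()].
#' @param seed Integer seed.
#' @param interval_s Spacing of successive timestamps in seconds.
#' @return List of [simulate_frame()] results, one element per frame.
#' @export
#' @examples
#' frames <- generate_sweep(cfg = simulator_config(), seed = 1)
#' length(frames)  # 10
generate_sweep <- function(labels = seq(81, 99, by = 2), n_per_label = 1,
                           cfg = simulator_config(), seed = 1,
                           interval_s = 0.7) {
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  if (is.unsorted(labels, strictly = TRUE)) {
    stop("labels must be strictly ascending", call. = FALSE)
  }
  if (n_per_label < 1) stop("n_per_label must be positive", call. = FALSE)
  set.seed(seed)
  k <- 0L
  frames <- vector("list", length(labels) * n_per_label)
  for (lab in labels) {
    for (j in seq_len(n_per_label)) {
      k <- k + 1L
      frames[[k]] <- simulate_frame(lab, cfg, seed = NULL,
                                    timestamp = (k - 1L) * interval_s)
    }
  }
  frames
}
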