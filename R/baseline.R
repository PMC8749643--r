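#' Exact dual-wavelength absorption ratio Q
#'
#' The classical transmission-oximetry statistic comparing pulsatile
#' attenuation at two wavelengths:
#' `Q = ln((DC1 - AC1)/DC1) / ln((DC2 - AC2)/DC2)`.
#' DC is the quasi-static transmitted intensity, AC the pulsatile
#' amplitude, conventionally red (650 nm here) over NIR (860 nm).
#'
#' @param ac1,dc1 Pulsatile amplitude and DC intensity at wavelength 1.
#' @param ac2,dc2 Same at wavelength 2.
#' @return List with `q` and `method = "exact"`.
#' @export
#' @examples
#' q_exact(2, 100, 1, 100)$q  # log(0.98)/log(0.99)
q_exact <- function(ac1, dc1, ac2, dc2) {
  check_ppg_pair(ac1, dc1, ac2, dc2)
  list(q = log((dc1 - ac1) / dc1) / log((dc2 - ac2) / dc2), method = "exact")
}

#' Approximate ratio-of-ratios Q
#'
#' First-order approximation `Q = (AC1/DC1) / (AC2/DC2)`, valid in the
#' small-signal regime AC/DC << 1.
#'
#' @inheritParams q_exact
#' @return List with `q` and `method = "approximate"`.
#' @export
#' @examples
#' q_approx(2, 100, 1, 100)$q  # 2
q_approx <- function(ac1, dc1, ac2, dc2) {
  check_ppg_pair(ac1, dc1, ac2, dc2)
  list(q = (ac1 / dc1) / (ac2 / dc2), method = "approximate")
}

check_ppg_pair <- function(ac1, dc1, ac2, dc2) {
  if (dc1 <= 0 || dc2 <= 0) stop("DC intensities must be positive", call. = FALSE)
  if (ac1 < 0 || ac2 < 0) stop("AC amplitudes must be non-negative", call. = FALSE)
  if (ac1 >= dc1 || ac2 >= dc2) stop("AC must be smaller than DC", call. = FALSE)
  if (ac2 == 0) stop("undefined ratio: AC at the reference wavelength is zero",
                     call. = FALSE)
  invisible(TRUE)
}

# Q values for a list of frames at the default red/NIR channel pairing.
frames_q <- function(frames, lambda1 = 650, lambda2 = 860, method = "exact") {
  n1 <- paste0("nm", lambda1); n2 <- paste0("nm", lambda2)
  fn <- if (method == "exact") q_exact else q_approx
  vapply(frames, function(f) {
    fn(f$ac[[n1]], f$dc[[n1]], f$ac[[n2]], f$dc[[n2]])$q
  }, numeric(1))
}

#' Fit the empirical linear Q-to-SpO2 calibration
#'
#' Classical pulse oximeters map the ratio-of-ratios to saturation with
#' an empirically calibrated curve; the smallest such model is linear,
#' `SpO2 = intercept - slope * Q`. Coefficients are fitted by ordinary
#' least squares on labeled frames (for example a simulator sweep).
#'
#' @param frames List of labeled `spectral_frame`s.
#' @param lambda1,lambda2 Channel centers of the red/NIR pairing
#'   (defaults 650 and 860 nm).
#' @param method `"exact"` or `"approx"` Q computation.
#' @return Object of class `q_calibration`: list with `slope`,
#'   `intercept`, `lambda1`, `lambda2`, `method`, and the fit residuals.
#' @export
#' @examples
#' frames <- generate_sweep(cfg = simulator_config(sensor_noise_sd = 0))
#' cal <- fit_q_calibration(frames)
#' cal$slope
fit_q_calibration <- function(frames, lambda1 = 650, lambda2 = 860,
                              method = c("exact", "approx")) {
  method <- match.arg(method)
  q <- frames_q(frames, lambda1, lambda2, method)
  spo2 <- vapply(frames, function(f) f$spo2, numeric(1))
  fit <- stats::lm(spo2 ~ q)
  structure(list(
    slope = -unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    lambda1 = lambda1, lambda2 = lambda2, method = method,
    residuals = unname(stats::residuals(fit))
  ), class = "q_calibration")
}

#' Map a Q value (or labeled frames) to an SpO2 estimate
#'
#' Applies the linear empirical calibration `SpO2 = intercept - slope*Q`,
#' clamped to \[0, 100\] percent.
#'
#' @param q Numeric Q value(s), or a list of `spectral_frame`s (in which
#'   case Q is computed at the calibration's channel pairing first).
#' @param calibration A [fit_q_calibration()] result, or `NULL` when
#'   giving `slope` and `intercept` directly.
#' @param slope,intercept Calibration coefficients (used when
#'   `calibration` is `NULL`).
#' @return Numeric SpO2 estimate(s) in percent.
#' @export
spo2_from_q <- function(q, calibration = NULL, slope = NULL, intercept = NULL) {
  if (!is.null(calibration)) {
    if (is.list(q) && !is.numeric(q)) {
      q <- frames_q(q, calibration$lambda1, calibration$lambda2,
                    calibration$method)
    }
    slope <- calibration$slope
    intercept <- calibration$intercept
  }
  if (is.null(slope) || is.null(intercept)) {
    stop("provide a calibration or slope and intercept", call. = FALSE)
  }
  pmin(pmax(intercept - slope * q, 0), 100)
}

#' @export
print.q_calibration <- function(x, ...) {
  cat("<q_calibration> SpO2 = ", format(x$intercept, digits = 5), " - ",
      format(x$slope, digits = 5), " * Q  (", x$method, " Q at ",
      x$lambda1, "/", x$lambda2, " nm)\n", sep = "")
  invisible(x)
}
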