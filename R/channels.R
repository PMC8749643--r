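#' Hemoglobin extinction coefficients at the sensor channel centers
#'
#' Loads the packaged table of molar extinction coefficients of
#' deoxyhemoglobin (Hb) and oxyhemoglobin (HbO2) at the twelve sensor
#' channel centers, transcribed from the standard Prahl/Zijlstra
#' compilation and expressed in L·mmol^-1·cm^-1. The simulator treats
#' these values as input data, not asserted truth: any table passing
#' [validate_chromophores()] can be substituted.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `wavelength_nm`, `eps_hb`, `eps_hbo2`.
#' @return A data.frame with columns `wavelength_nm`, `eps_hb`, `eps_hbo2`.
#' @export
#' @examples
#' tab <- hemoglobin_extinction()
#' tab[tab$wavelength_nm == 650, ]
hemoglobin_extinction <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hb_extinction.csv", package = "oxispec",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_chromophores(tab)
  tab
}

#' Validate a chromophore extinction table
#'
#' Checks the physical invariants the simulator relies on: strictly
#' ascending wavelengths inside 400-1100 nm, strictly positive extinction
#' values, and the red-region contrast eps_Hb > eps_HbO2 in the 660 nm
#' neighborhood that makes dual-wavelength oximetry possible at all.
#'
#' @param tab data.frame with columns `wavelength_nm`, `eps_hb`, `eps_hbo2`.
#' @return `tab`, invisibly, if valid; otherwise an error.
#' @export
validate_chromophores <- function(tab) {
  need <- c("wavelength_nm", "eps_hb", "eps_hbo2")
  if (!all(need %in% names(tab))) {
    stop("chromophore table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  wl <- tab$wavelength_nm
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly ascending", call. = FALSE)
  if (any(wl < 400 | wl > 1100)) stop("wavelengths must lie in [400, 1100] nm", call. = FALSE)
  if (any(tab$eps_hb <= 0) || any(tab$eps_hbo2 <= 0)) {
    stop("all extinction values must be positive", call. = FALSE)
  }
  red <- wl >= 630 & wl <= 690
  if (any(red) && !all(tab$eps_hb[red] > tab$eps_hbo2[red])) {
    stop("red-region contrast violated: eps_hb must exceed eps_hbo2 near 660 nm",
         call. = FALSE)
  }
  invisible(tab)
}

# The twelve channel centers of the paired 6+6-channel visible/NIR detector.
CHANNEL_CENTERS <- c(450, 500, 550, 570, 600, 610, 650, 680, 730, 760, 810, 860)
# Centers served by the visible-range die (40 nm FWHM); the NIR die has 20 nm.
VIS_CENTERS <- c(450, 500, 550, 570, 600, 650)

#' Sensor channel descriptions
#'
#' Builds the channel table for the 12-channel spectral sensor pair: six
#' visible channels with 40 nm full width at half maximum and six
#' visible/NIR channels with 20 nm FWHM, all digitized at 16 bits.
#'
#' @param centers_nm Channel centers, a subset of the twelve supported
#'   centers (450, 500, 550, 570, 600, 610, 650, 680, 730, 760, 810, 860 nm).
#' @param adc_bits A/D converter resolution in bits.
#' @return data.frame with columns `center_nm`, `fwhm_nm`, `adc_bits`.
#' @export
#' @examples
#' sensor_channels()            # all 12
#' sensor_channels(c(650, 860)) # the classical red/NIR pair
sensor_channels <- function(centers_nm = CHANNEL_CENTERS, adc_bits = 16) {
  if (!all(centers_nm %in% CHANNEL_CENTERS)) {
    stop("centers must be drawn from the 12 supported channels: ",
         paste(CHANNEL_CENTERS, collapse = ", "), call. = FALSE)
  }
  if (adc_bits < 1) stop("adc_bits must be >= 1", call. = FALSE)
  centers_nm <- sort(centers_nm)
  data.frame(
    center_nm = centers_nm,
    fwhm_nm   = ifelse(centers_nm %in% VIS_CENTERS, 40, 20),
    adc_bits  = adc_bits
  )
}

#' Gaussian band-integration weights for one sensor channel
#'
#' A sensor channel integrates light over a spectral band, not at a single
#' wavelength. The band is modeled as a Gaussian centered at `center_nm`
#' with sigma = FWHM / 2.355, truncated at +/- 2 FWHM, sampled every
#' `grid_step_nm`, and normalized to sum to one.
#'
#' @param channel One row of [sensor_channels()] (or any list with
#'   `center_nm` and `fwhm_nm`).
#' @param grid_step_nm Sampling step of the wavelength grid in nm.
#' @return data.frame with columns `wavelength_nm` and `weight`
#'   (weights sum to 1).
#' @export
#' @examples
#' w <- band_weights(sensor_channels(650), grid_step_nm = 1)
#' sum(w$weight)
band_weights <- function(channel, grid_step_nm = 1) {
  if (!is.numeric(grid_step_nm) || length(grid_step_nm) != 1 || grid_step_nm <= 0) {
    stop("grid_step_nm must be a positive number", call. = FALSE)
  }
  center <- channel$center_nm[1]
  fwhm <- channel$fwhm_nm[1]
  if (is.null(fwhm) || fwhm <= 0) stop("channel fwhm_nm must be positive", call. = FALSE)
  sigma <- fwhm / 2.355
  grid <- seq(center - 2 * fwhm, center + 2 * fwhm, by = grid_step_nm)
  w <- exp(-((grid - center)^2) / (2 * sigma^2))
  data.frame(wavelength_nm = grid, weight = w / sum(w))
}
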