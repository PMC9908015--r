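#' Two-mode plasmon-ruler scattering parameters
#'
#' Parametrises the gap-dependent scattering of a film-coupled gold
#' nanoparticle as the sum of two Lorentzian modes: an uncoupled "green"
#' particle mode (~600 nm) and a gap-sensitive "red" coupled mode that
#' sits at `red_center_contact` (~720 nm) at contact and relaxes toward
#' `red_center_uncoupled` as the gap opens. The red amplitude decays as
#' exp(-gap/coupling_decay); the green amplitude recovers as
#' 1 - amplitude_tradeoff * exp(-gap/coupling_decay).
#'
#' The default `coupling_decay` and `amplitude_tradeoff` were calibrated
#' once so the bound/unbound tether ensembles of the default 66-nt
#' construct produce a simulated RG increase from ~1.24 to ~1.56
#' (at 720/600 nm), matching the scale of the measured ensemble shift.
#' They are surrogate constants, not electromagnetic computations.
#'
#' @param green_center Green mode center, nm.
#' @param red_center_contact Red mode center at gap 0, nm.
#' @param red_center_uncoupled Red mode center at large gap, nm.
#' @param coupling_decay Gap scale of coupling relaxation, nm (> 0).
#' @param green_width,red_width Lorentzian FWHM, nm.
#' @param amplitude_tradeoff Fraction of green amplitude suppressed at
#'   contact, in \[0, 1\].
#' @return An object of class `plasmon_params`.
#' @export
plasmon_params <- function(green_center = 600,
                           red_center_contact = 720,
                           red_center_uncoupled = 650,
                           coupling_decay = 23.5,
                           green_width = 70,
                           red_width = 70,
                           amplitude_tradeoff = 0.77) {
  stopifnot(coupling_decay > 0, green_width > 0, red_width > 0,
            amplitude_tradeoff >= 0, amplitude_tradeoff <= 1)
  structure(
    list(green_center = green_center,
         red_center_contact = red_center_contact,
         red_center_uncoupled = red_center_uncoupled,
         coupling_decay = coupling_decay,
         green_width = green_width,
         red_width = red_width,
         amplitude_tradeoff = amplitude_tradeoff),
    class = "plasmon_params"
  )
}

# unit-peak Lorentzian with FWHM w centered at c
.lorentzian <- function(lambda, center, width) {
  hw2 <- (width / 2)^2
  hw2 / ((lambda - center)^2 + hw2)
}

#' Wavelength grid used throughout (dark-field collection band)
#' @param by Grid spacing in nm.
#' @return Numeric vector 430-800 nm.
#' @export
default_wavelengths <- function(by = 1) seq(430, 800, by = by)

#' Scattering spectrum of a particle at a fixed gap
#'
#' @param gap Particle-film gap in nm (>= 0).
#' @param params A [plasmon_params()].
#' @param wavelengths Ascending wavelength grid, nm; must cover both mode
#'   centers.
#' @return A `spectrum`: tibble with columns `wavelength_nm`, `intensity`.
#' @export
scattering_spectrum_at_gap <- function(gap, params = plasmon_params(),
                                       wavelengths = default_wavelengths()) {
  if (!is.numeric(gap) || length(gap) != 1 || is.na(gap) || gap < 0) {
    stop("`gap` must be a single non-negative number (nm)", call. = FALSE)
  }
  .check_grid(wavelengths, params)
  e <- exp(-gap / params$coupling_decay)
  red_c <- params$red_center_uncoupled +
    (params$red_center_contact - params$red_center_uncoupled) * e
  intensity <- e * .lorentzian(wavelengths, red_c, params$red_width) +
    (1 - params$amplitude_tradeoff * e) *
      .lorentzian(wavelengths, params$green_center, params$green_width)
  new_spectrum(wavelengths, intensity,
               meta = list(kind = "single_gap", gap_nm = gap))
}

.check_grid <- function(wavelengths, params) {
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  }
  centers <- c(params$green_center, params$red_center_contact)
  if (min(wavelengths) > min(centers) || max(wavelengths) < max(centers)) {
    stop("wavelength grid must cover both mode centers", call. = FALSE)
  }
  invisible(TRUE)
}

new_spectrum <- function(wavelengths, intensity, meta = list()) {
  out <- tibble::tibble(wavelength_nm = wavelengths, intensity = intensity)
  attr(out, "meta") <- meta
  class(out) <- c("spectrum", class(out))
  out
}

#' Time-averaged spectrum over a set of gap samples
#'
#' Each sample carries equal time weight, so the result is the unweighted
#' mean of the per-sample spectra (spectra are linear in the mixture).
#'
#' @param z_samples Numeric vector of gaps in nm, or a `position_ensemble`
#'   / `trajectory` (column `z_nm`).
#' @inheritParams scattering_spectrum_at_gap
#' @return A `spectrum` tibble.
#' @export
time_averaged_spectrum <- function(z_samples, params = plasmon_params(),
                                   wavelengths = default_wavelengths()) {
  z <- if (is.numeric(z_samples)) z_samples else z_samples$z_nm
  if (length(z) == 0) stop("empty sample set", call. = FALSE)
  if (any(is.na(z)) || any(z < 0)) {
    stop("gap samples must be non-negative", call. = FALSE)
  }
  .check_grid(wavelengths, params)
  e <- exp(-z / params$coupling_decay)
  red_c <- params$red_center_uncoupled +
    (params$red_center_contact - params$red_center_uncoupled) * e
  mean_green_amp <- mean(1 - params$amplitude_tradeoff * e)
  hw2 <- (params$red_width / 2)^2
  red_part <- vapply(wavelengths, function(l) {
    mean(e * hw2 / ((l - red_c)^2 + hw2))
  }, numeric(1))
  intensity <- red_part + mean_green_amp *
    .lorentzian(wavelengths, params$green_center, params$green_width)
  new_spectrum(wavelengths, intensity,
               meta = list(kind = "time_averaged", n_samples = length(z)))
}

#' Red/green intensity ratio of a spectrum
#'
#' RG = I(red)/I(green) with linear interpolation at the two evaluation
#' wavelengths. Defaults are the measurement wavelengths 709/585 nm; the
#' simulated two-mode spectra are conventionally read at 720/600 nm.
#' The ratio is invariant under any multiplicative intensity rescaling,
#' which is why it is preferred over absolute peak heights.
#'
#' @param spectrum A `spectrum` tibble (columns `wavelength_nm`,
#'   `intensity`).
#' @param red_wl,green_wl Evaluation wavelengths in nm; must lie inside
#'   the grid (no extrapolation).
#' @return A single dimensionless ratio.
#' @export
rg_ratio <- function(spectrum, red_wl = 709, green_wl = 585) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength_nm", "intensity") %in% names(spectrum)))
  wl <- spectrum$wavelength_nm
  for (w in c(red_wl, green_wl)) {
    if (w < min(wl) || w > max(wl)) {
      stop(sprintf("wavelength %.1f nm lies outside the spectrum grid", w),
           call. = FALSE)
    }
  }
  ir <- stats::approx(wl, spectrum$intensity, xout = red_wl)$y
  ig <- stats::approx(wl, spectrum$intensity, xout = green_wl)$y
  if (!is.finite(ig) || ig <= 0) {
    stop(sprintf("green intensity at %.1f nm is %.3g; RG undefined (division by non-positive value)",
                 green_wl, ig), call. = FALSE)
  }
  ir / ig
}
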