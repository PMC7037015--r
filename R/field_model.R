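#' Static field, sample geometry and slice-selection gradient
#'
#' Describes the spectrometer and the sample column along z: carrier
#' frequency, effective coil length, the isochromat grid used for lineshape
#' simulation, a static-field inhomogeneity profile, and the weak
#' slice-selection gradient used by the Zangger-Sterk scheme.
#'
#' The inhomogeneity profile is linear in z by default (`offset = slope * z`),
#' emulating a deshim of the linear z shim; an arbitrary profile can be
#' supplied as a function of z (cm) returning Hz, which then overrides the
#' slope for lineshape synthesis.
#'
#' @param spectrometer_mhz Proton carrier frequency in MHz (default 500).
#' @param carrier_ppm Position of the carrier / rotating frame in ppm
#'   (default 0). Simulated offsets are taken relative to this, so it should
#'   sit near the middle of the occupied shift range for a given sample.
#' @param coil_length_cm Effective RF coil (sample) length in cm (default 1.5).
#' @param n_z Number of z isochromats (integer >= 1, default 1).
#' @param inhom_slope_hz_per_cm Linear inhomogeneity coefficient in Hz/cm
#'   (default 0, i.e. well shimmed). The full-sample frequency spread is
#'   `slope * coil_length_cm`.
#' @param gamma_hz_per_gauss Gyromagnetic conversion for 1H in Hz/G
#'   (default 4257.7).
#' @param g4_gauss_per_cm Weak slice-selection gradient amplitude in G/cm
#'   (>= 0; 0 disables slice selection).
#' @param inhom_profile Optional function(z_cm) -> Hz replacing the linear
#'   profile.
#' @return An object of class `"field_model"`.
#' @examples
#' fm <- field_model(n_z = 201, inhom_slope_hz_per_cm = 118.23,
#'                   g4_gauss_per_cm = 0.56)
#' @export
field_model <- function(spectrometer_mhz = 500, carrier_ppm = 0,
                        coil_length_cm = 1.5, n_z = 1L,
                        inhom_slope_hz_per_cm = 0,
                        gamma_hz_per_gauss = 4257.7,
                        g4_gauss_per_cm = 0, inhom_profile = NULL) {
  check_positive_scalar(spectrometer_mhz, "spectrometer_mhz")
  check_finite_scalar(carrier_ppm, "carrier_ppm")
  check_positive_scalar(coil_length_cm, "coil_length_cm")
  if (!is.numeric(n_z) || length(n_z) != 1L || n_z < 1 ||
      n_z != round(n_z)) {
    stop("`n_z` must be an integer >= 1", call. = FALSE)
  }
  check_finite_scalar(inhom_slope_hz_per_cm, "inhom_slope_hz_per_cm")
  check_positive_scalar(gamma_hz_per_gauss, "gamma_hz_per_gauss")
  check_finite_scalar(g4_gauss_per_cm, "g4_gauss_per_cm")
  if (g4_gauss_per_cm < 0) stop("`g4_gauss_per_cm` must be >= 0",
                                call. = FALSE)
  if (!is.null(inhom_profile) && !is.function(inhom_profile)) {
    stop("`inhom_profile` must be NULL or a function(z_cm) -> Hz",
         call. = FALSE)
  }
  structure(
    list(spectrometer_mhz = spectrometer_mhz, carrier_ppm = carrier_ppm,
         coil_length_cm = coil_length_cm, n_z = as.integer(n_z),
         inhom_slope_hz_per_cm = inhom_slope_hz_per_cm,
         gamma_hz_per_gauss = gamma_hz_per_gauss,
         g4_gauss_per_cm = g4_gauss_per_cm,
         inhom_profile = inhom_profile),
    class = "field_model"
  )
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf(
    "<field_model> %g MHz (carrier %g ppm), L = %g cm, n_z = %d\n",
    x$spectrometer_mhz, x$carrier_ppm, x$coil_length_cm, x$n_z))
  cat(sprintf("  inhomogeneity: %s, G4 = %g G/cm (gamma %g Hz/G)\n",
              if (is.null(x$inhom_profile))
                sprintf("linear %g Hz/cm", x$inhom_slope_hz_per_cm)
              else "tabulated profile",
              x$g4_gauss_per_cm, x$gamma_hz_per_gauss))
  invisible(x)
}

#' Frequency-selective inversion pulse
#'
#' The Gauss-shaped selective pi pulse is idealized as a rectangular
#' inversion band of width `bandwidth_factor / duration_s` (Hz). The default
#' factor 0.84 is the usual Gaussian-envelope FWHM heuristic; it is exposed
#' because the effective-bandwidth convention is a calibration choice.
#'
#' @param duration_s Pulse length in seconds (> 0).
#' @param bandwidth_factor Dimensionless K with bandwidth `K / duration_s`.
#' @return An object of class `"slice_pulse"`.
#' @export
slice_pulse <- function(duration_s, bandwidth_factor = 0.84) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(bandwidth_factor, "bandwidth_factor")
  structure(list(duration_s = duration_s,
                 bandwidth_factor = bandwidth_factor),
            class = "slice_pulse")
}

#' Isochromat positions along z
#'
#' `n_z` points uniformly spanning the sample, inclusive of both ends at
#' +/- L/2; a single isochromat sits at the coil center.
#'
#' @param field A [field_model()].
#' @return Numeric vector of z positions in cm.
#' @export
z_grid <- function(field) {
  L <- field$coil_length_cm
  if (field$n_z == 1L) return(0)
  seq(-L / 2, L / 2, length.out = field$n_z)
}

#' Local field offset at a z position
#'
#' @param field A [field_model()].
#' @param z Position(s) in cm; must lie within the sample, |z| <= L/2.
#' @return Frequency offset(s) in Hz.
#' @export
inhomogeneity_offset <- function(field, z) {
  if (any(!is.finite(z)) || any(abs(z) > field$coil_length_cm / 2 + 1e-12)) {
    stop(sprintf("z must lie within the sample, |z| <= %g cm",
                 field$coil_length_cm / 2), call. = FALSE)
  }
  if (!is.null(field$inhom_profile)) {
    return(vapply(z, field$inhom_profile, numeric(1)))
  }
  field$inhom_slope_hz_per_cm * z
}

#' Slice position, width and volume fraction for a resonance
#'
#' Under the weak gradient G4 each resonance maps to a z slice: the selective
#' pulse inverts the coupling partners of spins sitting where the gradient
#' shifts the site onto the pulse frequency. The slice center is
#' `offset / (gamma * G4)` (clipped to the sample), the width is
#' `bandwidth / (gamma * G4)`, and the detected volume fraction is
#' `min(width, L) / L`. Sensitivity of the pure-shift experiment scales with
#' this fraction.
#'
#' @param field A [field_model()] with `g4_gauss_per_cm > 0`.
#' @param pulse A [slice_pulse()].
#' @param site_offset_hz Site frequency relative to the carrier, in Hz.
#' @return List with `slice_center_cm` (clipped), `slice_width_cm`,
#'   `slice_fraction`, and `inside` (FALSE when the unclipped slice lies
#'   entirely outside the sample).
#' @examples
#' fm <- field_model(g4_gauss_per_cm = 0.56)
#' slice_geometry(fm, slice_pulse(16.2e-3), 0)
#' @export
slice_geometry <- function(field, pulse, site_offset_hz) {
  if (field$g4_gauss_per_cm <= 0) {
    stop("slice selection requires g4_gauss_per_cm > 0", call. = FALSE)
  }
  check_finite_scalar(site_offset_hz, "site_offset_hz")
  L <- field$coil_length_cm
  hz_per_cm <- field$gamma_hz_per_gauss * field$g4_gauss_per_cm
  center_raw <- site_offset_hz / hz_per_cm
  width <- (pulse$bandwidth_factor / pulse$duration_s) / hz_per_cm
  inside <- (center_raw - width / 2) < L / 2 &&
            (center_raw + width / 2) > -L / 2
  list(
    slice_center_cm = min(max(center_raw, -L / 2), L / 2),
    slice_width_cm = width,
    slice_fraction = min(width, L) / L,
    inside = inside
  )
}
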