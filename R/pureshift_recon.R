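#' Fourier transform a FID into a 1D spectrum
#'
#' Optional exponential apodization `exp(-pi * lb * t)`, zero filling to
#' `zero_fill` times the next power of two, discrete Fourier transform, and
#' zero-order phasing. With the default phase (0 rad) a FID starting real and
#' positive -- the convention of all simulators in this package -- transforms
#' to pure-absorption real lineshapes.
#'
#' Axes follow the NMR convention: ppm (and the matching Hz axis, relative to
#' the 0 ppm position) are presented in descending order.
#'
#' @param fid Complex FID sampled at the dwell time `1/spectral_width_hz`.
#' @param spectral_width_hz Sampling bandwidth in Hz.
#' @param spectrometer_mhz Spectrometer frequency in MHz (for the ppm axis).
#' @param carrier_ppm Carrier position in ppm.
#' @param lb_hz Exponential line broadening in Hz (default 0).
#' @param zero_fill Integer >= 1; total length is `zero_fill * 2^ceil(log2 N)`.
#' @param phase0_rad Zero-order phase correction in radians.
#' @param first_point_half Scale the first FID point by 0.5 before the
#'   transform (default TRUE). This standard correction removes the flat
#'   baseline offset (`s(0)/2`) that the discrete transform of a truncated
#'   decay otherwise spreads across the spectrum; without it, baseline
#'   contamination from strong sites biases tracked heights of weak ones.
#' @return An object of class `"nmr_spectrum"`: list with `axis_hz`,
#'   `axis_ppm` (both descending), complex `values`, and `meta`.
#' @export
fid_to_spectrum <- function(fid, spectral_width_hz, spectrometer_mhz = 500,
                            carrier_ppm = 0, lb_hz = 0, zero_fill = 2L,
                            phase0_rad = 0, first_point_half = TRUE) {
  if (length(fid) == 0) stop("`fid` must be nonempty", call. = FALSE)
  check_positive_scalar(spectral_width_hz, "spectral_width_hz")
  if (!is.numeric(zero_fill) || length(zero_fill) != 1L || zero_fill < 1 ||
      zero_fill != round(zero_fill)) {
    stop("`zero_fill` must be an integer >= 1", call. = FALSE)
  }
  n <- length(fid)
  t <- (seq_len(n) - 1) / spectral_width_hz
  if (lb_hz != 0) fid <- fid * exp(-pi * lb_hz * t)
  if (isTRUE(first_point_half)) fid[1] <- fid[1] / 2
  n2 <- as.integer(zero_fill * 2^ceiling(log2(n)))
  s <- stats::fft(c(fid, complex(real = rep(0, n2 - n))))
  # fftshift: ascending frequency axis -sw/2 .. +sw/2 - sw/n2
  half <- n2 %/% 2L
  s <- c(s[(half + 1L):n2], s[1:half])
  f <- (seq_len(n2) - 1L - half) * spectral_width_hz / n2
  if (phase0_rad != 0) s <- s * exp(-1i * phase0_rad)
  hz <- rev(f) + carrier_ppm * spectrometer_mhz  # absolute Hz, descending
  structure(
    list(axis_hz = hz,
         axis_ppm = hz / spectrometer_mhz,
         values = rev(s),
         meta = list(spectral_width_hz = spectral_width_hz,
                     spectrometer_mhz = spectrometer_mhz,
                     carrier_ppm = carrier_ppm, lb_hz = lb_hz,
                     zero_fill = as.integer(zero_fill),
                     npoints_fid = n)),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<nmr_spectrum> %d points, %.3f .. %.3f ppm (sw %g Hz at %g MHz)\n",
    length(x$values), min(x$axis_ppm), max(x$axis_ppm),
    x$meta$spectral_width_hz, x$meta$spectrometer_mhz))
  invisible(x)
}

#' @export
as.data.frame.nmr_spectrum <- function(x, ...) {
  data.frame(ppm = x$axis_ppm, hz = x$axis_hz,
             real = Re(x$values), imag = Im(x$values))
}

# ascending-ppm view used by the measurement routines
ascending_real <- function(spec) {
  ord <- order(spec$axis_ppm)
  list(ppm = spec$axis_ppm[ord], hz = spec$axis_hz[ord],
       re = Re(spec$values)[ord])
}

#' Full width at half maximum of a peak
#'
#' Locates the highest local maximum of the real spectrum inside a search
#' window around `peak_ppm` and returns the linearly interpolated full width
#' at half that maximum, in Hz.
#'
#' @param spec An [fid_to_spectrum()] result.
#' @param peak_ppm Expected peak position (ppm).
#' @param window_ppm Width of the search window (ppm, default 0.5).
#' @return FWHM in Hz.
#' @export
measure_fwhm <- function(spec, peak_ppm, window_ppm = 0.5) {
  a <- ascending_real(spec)
  sel <- which(abs(a$ppm - peak_ppm) <= window_ppm / 2)
  if (length(sel) < 3) {
    stop(sprintf("search window %g +/- %g ppm contains too few points",
                 peak_ppm, window_ppm / 2), call. = FALSE)
  }
  imax <- sel[which.max(a$re[sel])]
  if (imax <= 1L || imax >= length(a$re) ||
      !(a$re[imax] > a$re[imax - 1L] && a$re[imax] > a$re[imax + 1L])) {
    stop(sprintf("no local maximum found within %g +/- %g ppm",
                 peak_ppm, window_ppm / 2), call. = FALSE)
  }
  half <- a$re[imax] / 2
  # walk outward to the half-height crossings and interpolate linearly
  i <- imax
  while (i > 1L && a$re[i] > half) i <- i - 1L
  if (a$re[i] > half) stop("left half-height crossing not found",
                           call. = FALSE)
  fl <- a$hz[i] + (half - a$re[i]) / (a$re[i + 1L] - a$re[i]) *
    (a$hz[i + 1L] - a$hz[i])
  j <- imax
  nn <- length(a$re)
  while (j < nn && a$re[j] > half) j <- j + 1L
  if (a$re[j] > half) stop("right half-height crossing not found",
                           call. = FALSE)
  fr <- a$hz[j - 1L] + (half - a$re[j - 1L]) / (a$re[j] - a$re[j - 1L]) *
    (a$hz[j] - a$hz[j - 1L])
  abs(fr - fl)
}

#' Pick peaks in the real spectrum
#'
#' Local maxima of the real part above `min_height_fraction` of the global
#' maximum, refined by three-point parabolic interpolation.
#'
#' @param spec An [fid_to_spectrum()] result.
#' @param min_height_fraction Threshold in (0, 1) relative to the tallest
#'   point.
#' @param fwhm Logical: also measure each peak's FWHM (NA where the
#'   half-height is not reached, e.g. shoulders)?
#' @return Data frame with `position_ppm`, `height`, `fwhm_hz`, sorted by
#'   descending ppm. May have zero rows.
#' @export
pick_peaks <- function(spec, min_height_fraction = 0.05, fwhm = FALSE) {
  if (!is.numeric(min_height_fraction) || min_height_fraction <= 0 ||
      min_height_fraction >= 1) {
    stop("`min_height_fraction` must be in (0, 1)", call. = FALSE)
  }
  a <- ascending_real(spec)
  r <- a$re
  n <- length(r)
  thr <- min_height_fraction * max(r)
  i <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] > r[3:n]) + 1L
  i <- i[r[i] >= thr]
  if (length(i) == 0) {
    return(data.frame(position_ppm = numeric(0), height = numeric(0),
                      fwhm_hz = numeric(0)))
  }
  # parabolic refinement through the three points around each maximum
  denom <- r[i - 1L] - 2 * r[i] + r[i + 1L]
  d <- ifelse(denom == 0, 0, 0.5 * (r[i - 1L] - r[i + 1L]) / denom)
  dppm <- a$ppm[2] - a$ppm[1]
  pos <- a$ppm[i] + d * dppm
  height <- r[i] - 0.25 * (r[i - 1L] - r[i + 1L]) * d
  out <- data.frame(position_ppm = pos, height = height)
  out$fwhm_hz <- if (isTRUE(fwhm)) {
    vapply(pos, function(p) {
      tryCatch(measure_fwhm(spec, p, window_ppm = 20 * abs(dppm)),
               error = function(e) NA_real_)
    }, numeric(1))
  } else NA_real_
  out <- out[order(-out$position_ppm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick reference peaks for intensity tracking
#'
#' Chooses the series member with the largest total signal magnitude -- the
#' fully recovered (last) spectrum of an IR series, the shortest-delay
#' (first) spectrum of a CPMG series -- picks peaks there, and returns them
#' for use as fixed tracking positions across the whole array.
#'
#' @param series A `"relaxation_series"`.
#' @param min_height_fraction Passed to [pick_peaks()].
#' @param lb_hz,zero_fill Reconstruction parameters (must match those used
#'   for tracking).
#' @return Data frame of peaks as from [pick_peaks()].
#' @export
reference_peaks <- function(series, min_height_fraction = 0.05, lb_hz = 0,
                            zero_fill = 2L) {
  tot <- vapply(series$fids, function(f) sum(Mod(f)), numeric(1))
  ref <- which.max(tot)
  spec <- series_spectrum(series, ref, lb_hz, zero_fill)
  pick_peaks(spec, min_height_fraction)
}

# reconstruct member i of a series with given recon params
series_spectrum <- function(series, i, lb_hz = 0, zero_fill = 2L) {
  fid_to_spectrum(series$fids[[i]],
                  spectral_width_hz = series$meta$spectral_width_hz,
                  spectrometer_mhz = series$meta$spectrometer_mhz,
                  carrier_ppm = series$meta$carrier_ppm,
                  lb_hz = lb_hz, zero_fill = zero_fill)
}

#' Track peak intensities across a relaxation series
#'
#' Reconstructs every member of the series with identical parameters and
#' reads the signed real-part height at each fixed reference position
#' (linear interpolation between grid points). Signed heights preserve the
#' negative early points of an inversion-recovery array.
#'
#' @param series A `"relaxation_series"`.
#' @param peaks Data frame with a `position_ppm` column (e.g. from
#'   [reference_peaks()]).
#' @param lb_hz,zero_fill Reconstruction parameters, applied identically to
#'   every member.
#' @return Data frame: first column `delay_s`, then one signed-intensity
#'   column per peak (named `ppm_<position>`). Zero peaks give a one-column
#'   table.
#' @export
track_intensities <- function(series, peaks, lb_hz = 0, zero_fill = 2L) {
  stopifnot(inherits(series, "relaxation_series"))
  if (!is.data.frame(peaks) || !"position_ppm" %in% names(peaks)) {
    stop("`peaks` must be a data frame with a position_ppm column",
         call. = FALSE)
  }
  out <- data.frame(delay_s = series$delays)
  if (nrow(peaks) == 0) return(out)
  cols <- matrix(NA_real_, nrow = length(series$delays),
                 ncol = nrow(peaks))
  for (i in seq_along(series$fids)) {
    spec <- series_spectrum(series, i, lb_hz, zero_fill)
    a <- ascending_real(spec)
    cols[i, ] <- stats::approx(a$ppm, a$re, xout = peaks$position_ppm,
                               rule = 2)$y
  }
  colnames(cols) <- sprintf("ppm_%.4f", peaks$position_ppm)
  cbind(out, as.data.frame(cols))
}
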