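#' Define a proton site
#'
#' A site groups `n_equivalent` magnetically equivalent protons sharing one
#' chemical shift and one pair of relaxation times. Equivalent protons within
#' a site do not split each other (standard first-order convention).
#'
#' @param label Site label (unique within a system).
#' @param shift_ppm Chemical shift in ppm relative to 0 ppm.
#' @param t1_s Longitudinal relaxation time in seconds (> 0).
#' @param t2_s Transverse relaxation time in seconds (> 0).
#' @param n_equivalent Number of equivalent protons at the site (integer >= 1).
#'   The site amplitude (equilibrium magnetization) is proportional to it.
#' @return An object of class `"spin"`.
#' @examples
#' spin("CH3", 0.92, t1_s = 5.8, t2_s = 3.0, n_equivalent = 3)
#' @export
spin <- function(label, shift_ppm, t1_s, t2_s, n_equivalent = 1L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  check_finite_scalar(shift_ppm, "shift_ppm")
  check_positive_scalar(t1_s, "t1_s")
  check_positive_scalar(t2_s, "t2_s")
  if (!is.numeric(n_equivalent) || length(n_equivalent) != 1L ||
      n_equivalent < 1 || n_equivalent != round(n_equivalent)) {
    stop("`n_equivalent` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(label = label, shift_ppm = shift_ppm, t1_s = t1_s, t2_s = t2_s,
         n_equivalent = as.integer(n_equivalent)),
    class = "spin"
  )
}

#' Define a scalar coupling between two sites
#'
#' @param site_a,site_b Labels of the two coupled sites (must differ).
#' @param j_hz Scalar coupling constant in Hz (>= 0).
#' @return An object of class `"coupling"`.
#' @export
coupling <- function(site_a, site_b, j_hz) {
  stopifnot(is.character(site_a), is.character(site_b))
  if (identical(site_a, site_b)) {
    stop("a site cannot be coupled to itself", call. = FALSE)
  }
  check_finite_scalar(j_hz, "j_hz")
  if (j_hz < 0) stop("`j_hz` must be >= 0", call. = FALSE)
  structure(list(site_a = site_a, site_b = site_b, j_hz = j_hz),
            class = "coupling")
}

#' Assemble a weakly coupled spin system
#'
#' Couplings must reference existing site labels and each unordered pair may
#' appear at most once. The weak-coupling condition |nu_a - nu_b| >= 5 J at
#' the stated spectrometer frequency is checked for every coupling; a
#' violation emits a warning (first-order multiplet rules degrade, but the
#' system is still usable).
#'
#' @param spins List of [spin()] objects.
#' @param couplings List of [coupling()] objects (may be empty).
#' @param name Optional system name.
#' @param spectrometer_mhz Frequency used for the weak-coupling check (MHz).
#' @return An object of class `"spin_system"`.
#' @examples
#' ax <- spin_system(
#'   spins = list(spin("A", 3.4, 5, 2.8), spin("X", 1.8, 4, 2.2)),
#'   couplings = list(coupling("A", "X", 7))
#' )
#' @export
spin_system <- function(spins, couplings = list(), name = "system",
                        spectrometer_mhz = 500) {
  if (inherits(spins, "spin")) spins <- list(spins)
  if (inherits(couplings, "coupling")) couplings <- list(couplings)
  stopifnot(is.list(spins), length(spins) >= 1L, is.list(couplings))
  lapply(spins, function(s) {
    if (!inherits(s, "spin")) stop("`spins` must be a list of spin() objects",
                                   call. = FALSE)
  })
  labels <- vapply(spins, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate site labels", call. = FALSE)
  seen <- character(0)
  for (cp in couplings) {
    if (!inherits(cp, "coupling")) {
      stop("`couplings` must be a list of coupling() objects", call. = FALSE)
    }
    if (!all(c(cp$site_a, cp$site_b) %in% labels)) {
      stop(sprintf("coupling %s-%s references an unknown site",
                   cp$site_a, cp$site_b), call. = FALSE)
    }
    key <- paste(sort(c(cp$site_a, cp$site_b)), collapse = "\r")
    if (key %in% seen) {
      stop(sprintf("coupling %s-%s appears more than once",
                   cp$site_a, cp$site_b), call. = FALSE)
    }
    seen <- c(seen, key)
  }
  sys <- structure(list(spins = spins, couplings = couplings, name = name),
                   class = "spin_system")
  check_weak_coupling(sys, spectrometer_mhz)
  sys
}

check_weak_coupling <- function(system, spectrometer_mhz) {
  for (cp in system$couplings) {
    if (cp$j_hz == 0) next
    a <- site_by_label(system, cp$site_a)
    b <- site_by_label(system, cp$site_b)
    dnu <- abs(a$shift_ppm - b$shift_ppm) * spectrometer_mhz
    if (dnu < 5 * cp$j_hz) {
      warning(sprintf(
        "coupling %s-%s: shift difference %.1f Hz < 5 J = %.1f Hz at %g MHz; first-order (weak-coupling) treatment is inaccurate",
        cp$site_a, cp$site_b, dnu, 5 * cp$j_hz, spectrometer_mhz),
        call. = FALSE)
    }
  }
  invisible(TRUE)
}

site_by_label <- function(system, label) {
  for (s in system$spins) if (s$label == label) return(s)
  stop(sprintf("no site labelled '%s'", label), call. = FALSE)
}

site_labels <- function(system) {
  vapply(system$spins, `[[`, character(1), "label")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system '%s'>: %d site(s), %d coupling(s)\n",
              x$name, length(x$spins), length(x$couplings)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  if (length(x$couplings)) {
    cat("couplings:\n")
    for (cp in x$couplings) {
      cat(sprintf("  %s-%s  J = %g Hz\n", cp$site_a, cp$site_b, cp$j_hz))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.spin_system <- function(x, ...) {
  data.frame(
    label = site_labels(x),
    shift_ppm = vapply(x$spins, `[[`, numeric(1), "shift_ppm"),
    t1_s = vapply(x$spins, `[[`, numeric(1), "t1_s"),
    t2_s = vapply(x$spins, `[[`, numeric(1), "t2_s"),
    n_equivalent = vapply(x$spins, `[[`, integer(1), "n_equivalent"),
    stringsAsFactors = FALSE
  )
}

#' Resonance offset of a site in Hz
#'
#' Converts a chemical shift in ppm to a frequency offset in Hz relative to
#' the 0 ppm position: `offset = shift_ppm * spectrometer_mhz`.
#'
#' @param spin A [spin()] object (or anything with a `shift_ppm` field).
#' @param spectrometer_mhz Spectrometer proton frequency in MHz (> 0).
#' @return Offset in Hz.
#' @examples
#' resonance_offset_hz(spin("a", 3.42, 1, 1), 500)  # 1710 Hz
#' @export
resonance_offset_hz <- function(spin, spectrometer_mhz) {
  check_positive_scalar(spectrometer_mhz, "spectrometer_mhz")
  check_finite_scalar(spin$shift_ppm, "shift_ppm")
  spin$shift_ppm * spectrometer_mhz
}

#' First-order multiplet pattern of a site
#'
#' Expands a site into its weak-coupling multiplet line list. Each coupling
#' partner with `n_p` equivalent protons contributes an (n_p + 1)-line
#' binomial pattern at offsets `(k - n_p/2) * J`, k = 0..n_p; patterns from
#' several partners combine by convolution. Intensities are normalized to
#' sum to one, so the pattern redistributes, never changes, total amplitude.
#'
#' @param spin The site to expand.
#' @param system The [spin_system()] providing coupling partners.
#' @return A data frame with columns `offset_hz` (relative to the site
#'   frequency) and `intensity`, sorted by offset.
#' @examples
#' ax <- spin_system(list(spin("A", 3.4, 5, 2.8), spin("X", 1.8, 4, 2.2)),
#'                   list(coupling("A", "X", 7)))
#' multiplet_pattern(ax$spins[[1]], ax)  # doublet at -3.5/+3.5 Hz
#' @export
multiplet_pattern <- function(spin, system) {
  lines <- data.frame(offset_hz = 0, intensity = 1)
  for (cp in system$couplings) {
    partner <- if (cp$site_a == spin$label) cp$site_b
               else if (cp$site_b == spin$label) cp$site_a
               else next
    np <- site_by_label(system, partner)$n_equivalent
    k <- 0:np
    sub <- data.frame(offset_hz = (k - np / 2) * cp$j_hz,
                      intensity = choose(np, k) / 2^np)
    lines <- convolve_lines(lines, sub)
  }
  lines <- lines[order(lines$offset_hz), , drop = FALSE]
  rownames(lines) <- NULL
  lines$intensity <- lines$intensity / sum(lines$intensity)
  lines
}

# outer sum of offsets, outer product of intensities, merging coincident lines
convolve_lines <- function(a, b, tol = 1e-9) {
  off <- outer(a$offset_hz, b$offset_hz, `+`)
  amp <- outer(a$intensity, b$intensity)
  df <- data.frame(offset_hz = as.vector(off), intensity = as.vector(amp))
  df <- df[order(df$offset_hz), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(df$offset_hz) > tol))
  data.frame(offset_hz = as.vector(tapply(df$offset_hz, grp, mean)),
             intensity = as.vector(tapply(df$intensity, grp, sum)))
}

# ---- shared validation helpers ----

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  check_finite_scalar(x, name)
  if (x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
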