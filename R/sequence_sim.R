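#' Inversion-recovery delay scheme
#'
#' @param tau1_list Inversion-recovery delays tau1 in seconds, strictly
#'   increasing, each >= 0.
#' @param inversion_efficiency Inversion efficiency in (0, 1]; 1 is a perfect
#'   pi pulse and reproduces the textbook recovery factor `1 - 2 exp(-tau/T1)`.
#' @return An object of class `"ir_scheme"`.
#' @export
ir_scheme <- function(tau1_list, inversion_efficiency = 1) {
  if (length(tau1_list) == 0) stop("`tau1_list` must be nonempty",
                                   call. = FALSE)
  if (any(!is.finite(tau1_list)) || any(tau1_list < 0)) {
    stop("`tau1_list` delays must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(tau1_list, strictly = TRUE)) {
    stop("`tau1_list` must be strictly increasing", call. = FALSE)
  }
  check_finite_scalar(inversion_efficiency, "inversion_efficiency")
  if (inversion_efficiency <= 0 || inversion_efficiency > 1) {
    stop("`inversion_efficiency` must be in (0, 1]", call. = FALSE)
  }
  structure(list(tau1_list = as.numeric(tau1_list),
                 inversion_efficiency = inversion_efficiency),
            class = "ir_scheme")
}

#' CPMG spin-echo delay scheme
#'
#' Total echo delays `Delta = m * tau2` with integral echo counts m: every
#' requested delay must be a multiple of the interpulse interval to within
#' 1e-9 relative tolerance.
#'
#' @param delta_list Total spin-echo delays in seconds, sorted increasing.
#' @param tau2_s Interpulse interval tau2 in seconds (> 0, default 200e-6).
#' @return An object of class `"cpmg_scheme"`.
#' @export
cpmg_scheme <- function(delta_list, tau2_s = 200e-6) {
  check_positive_scalar(tau2_s, "tau2_s")
  if (length(delta_list) == 0) stop("`delta_list` must be nonempty",
                                    call. = FALSE)
  if (any(!is.finite(delta_list)) || any(delta_list < 0)) {
    stop("`delta_list` delays must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(delta_list, strictly = TRUE)) {
    stop("`delta_list` must be strictly increasing", call. = FALSE)
  }
  m <- delta_list / tau2_s
  bad <- abs(m - round(m)) > 1e-9 * pmax(1, m)
  if (any(bad)) {
    stop(sprintf("delta values not integer multiples of tau2 = %g s: %s",
                 tau2_s, paste(delta_list[bad], collapse = ", ")),
         call. = FALSE)
  }
  structure(list(delta_list = as.numeric(delta_list), tau2_s = tau2_s,
                 m_list = as.integer(round(m))),
            class = "cpmg_scheme")
}

#' Real-time chunked (pure-shift) acquisition parameters
#'
#' The acquisition window of total length `t1 = n_chunks * chunk_duration_s`
#' is cut into a half chunk, `n_chunks - 1` full chunks, and a final half
#' chunk, with a homodecoupling element between consecutive chunks. J
#' evolution is refocused at every chunk midpoint (including t1 = 0 and
#' t1 = t1max for the half chunks).
#'
#' @param n_chunks Number of chunks n (integer >= 2).
#' @param chunk_duration_s Full-chunk length in seconds (default 0.02).
#' @param spectral_width_hz Sampling bandwidth in Hz; the dwell time
#'   `1/spectral_width_hz` must divide `chunk_duration_s` to 1e-9 relative.
#' @param per_element_loss Multiplicative amplitude retention per decoupling
#'   element, in (0, 1]; 1 = lossless (default).
#' @return An object of class `"zs_acquisition"` with derived field `t1_s`.
#' @examples
#' zs_acquisition(40, 0.02, 2000)  # t1 = 0.8 s
#' @export
zs_acquisition <- function(n_chunks, chunk_duration_s = 0.02,
                           spectral_width_hz, per_element_loss = 1) {
  if (!is.numeric(n_chunks) || length(n_chunks) != 1L || n_chunks < 2 ||
      n_chunks != round(n_chunks)) {
    stop("`n_chunks` must be an integer >= 2", call. = FALSE)
  }
  check_positive_scalar(chunk_duration_s, "chunk_duration_s")
  check_positive_scalar(spectral_width_hz, "spectral_width_hz")
  check_finite_scalar(per_element_loss, "per_element_loss")
  if (per_element_loss <= 0 || per_element_loss > 1) {
    stop("`per_element_loss` must be in (0, 1]", call. = FALSE)
  }
  pts <- chunk_duration_s * spectral_width_hz
  if (abs(pts - round(pts)) > 1e-9 * pts) {
    stop("dwell time 1/spectral_width_hz must divide chunk_duration_s",
         call. = FALSE)
  }
  structure(list(n_chunks = as.integer(n_chunks),
                 chunk_duration_s = chunk_duration_s,
                 spectral_width_hz = spectral_width_hz,
                 per_element_loss = per_element_loss,
                 t1_s = n_chunks * chunk_duration_s),
            class = "zs_acquisition")
}

#' Inversion-recovery amplitude factor
#'
#' `1 - (1 + efficiency) * exp(-tau1 / T1)`; with efficiency 1 this is the
#' ideal recovery factor `1 - 2 exp(-R1 tau1)` following a perfect inversion.
#'
#' @param tau1 Recovery delay in seconds (>= 0), vectorized.
#' @param t1_relax Longitudinal relaxation time in seconds (> 0).
#' @param efficiency Inversion efficiency in (0, 1].
#' @return Dimensionless signed amplitude factor(s) in [-efficiency, 1).
#' @export
ir_recovery_factor <- function(tau1, t1_relax, efficiency = 1) {
  check_positive_scalar(t1_relax, "t1_relax")
  if (any(!is.finite(tau1)) || any(tau1 < 0)) {
    stop("`tau1` must be finite and >= 0", call. = FALSE)
  }
  if (efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  }
  1 - (1 + efficiency) * exp(-tau1 / t1_relax)
}

#' CPMG amplitude decay factor
#'
#' `exp(-Delta / T2)`. Static offsets (chemical shift and field
#' inhomogeneity) are refocused by the echo train, and J modulation is
#' suppressed in the short-interval limit tau2 << 1/J, so only the intrinsic
#' transverse decay survives.
#'
#' @param delta Total spin-echo delay in seconds (>= 0), vectorized.
#' @param t2_relax Transverse relaxation time in seconds (> 0).
#' @return Decay factor(s) in (0, 1].
#' @export
cpmg_decay_factor <- function(delta, t2_relax) {
  check_positive_scalar(t2_relax, "t2_relax")
  if (any(!is.finite(delta)) || any(delta < 0)) {
    stop("`delta` must be finite and >= 0", call. = FALSE)
  }
  exp(-delta / t2_relax)
}

# Resolve a per-site weight spec (scalar, or named vector by site label)
# into one numeric weight per site, in system order.
resolve_weights <- function(system, weights) {
  labels <- site_labels(system)
  if (length(weights) == 1L && is.null(names(weights))) {
    return(rep(as.numeric(weights), length(labels)))
  }
  if (is.null(names(weights)) && length(weights) == length(labels)) {
    return(as.numeric(weights))
  }
  if (!all(labels %in% names(weights))) {
    stop("`weights` must be a scalar, an unnamed vector matching the number of sites, or a vector named by site label",
         call. = FALSE)
  }
  as.numeric(weights[labels])
}

#' Simulate a conventional (fully coupled, full-volume) FID
#'
#' Sums damped complex exponentials over all sites, their first-order
#' multiplet lines, and all z isochromats:
#' `s(t) = sum_sites n_eq w_s sum_lines a_l <exp(i 2 pi (nu_s + d_l + dz) t)>_z exp(-t/T2_s)`.
#' Frequencies are relative to the carrier. The whole sample volume
#' contributes (no slice selection), so field inhomogeneity broadens every
#' line by the full spread of the profile.
#'
#' @param system A [spin_system()].
#' @param field A [field_model()].
#' @param weights Per-site relaxation amplitude factor: scalar, or numeric
#'   vector named by site label (e.g. from [ir_recovery_factor()]).
#' @param duration Acquisition length in seconds (> 0).
#' @param spectral_width_hz Sampling bandwidth in Hz (> 0).
#' @return Complex FID sampled at `1/spectral_width_hz` from t = 0.
#' @export
simulate_conventional_fid <- function(system, field, weights, duration,
                                      spectral_width_hz) {
  check_positive_scalar(duration, "duration")
  check_positive_scalar(spectral_width_hz, "spectral_width_hz")
  w <- resolve_weights(system, weights)
  n <- round(duration * spectral_width_hz)
  if (n < 1) stop("duration shorter than one dwell time", call. = FALSE)
  t <- (seq_len(n) - 1) / spectral_width_hz

  # inhomogeneity kernel: isochromat-averaged phase factor, same for all sites
  zoff <- inhomogeneity_offset(field, z_grid(field))
  kern <- complex(real = rep(0, n), imaginary = rep(0, n))
  for (dz in zoff) kern <- kern + exp(2i * pi * dz * t)
  kern <- kern / length(zoff)

  s <- complex(real = rep(0, n))
  for (k in seq_along(system$spins)) {
    site <- system$spins[[k]]
    nu <- (site$shift_ppm - field$carrier_ppm) * field$spectrometer_mhz
    lines <- multiplet_pattern(site, system)
    lf <- complex(real = rep(0, n))
    for (j in seq_len(nrow(lines))) {
      lf <- lf + lines$intensity[j] * exp(2i * pi * lines$offset_hz[j] * t)
    }
    s <- s + site$n_equivalent * w[k] *
      exp((2i * pi * nu - 1 / site$t2_s) * t) * lf
  }
  s * kern
}

# Segment index and J-refocusing midpoint for every time point of a chunked
# acquisition: half chunk, (n-1) full chunks, half chunk; midpoints at
# 0, tau_c, 2 tau_c, ..., n tau_c.
chunk_segments <- function(t, n_chunks, chunk_duration_s) {
  tc <- chunk_duration_s
  edges <- c(tc / 2 + tc * (0:(n_chunks - 1)))
  idx <- findInterval(t, edges) + 1L        # segment 1 .. n_chunks + 1
  mids <- c(0, tc * seq_len(n_chunks - 1), n_chunks * tc)
  list(index = idx, midpoint = mids[idx])
}

#' Simulate a real-time Zangger-Sterk pure-shift FID
#'
#' Closed-form chunked-acquisition signal: within chunk k the J coupling to
#' each partner contributes `cos(pi J (t1 - t_mid(k)))^n_partner`, refocused
#' (factor 1) at the chunk midpoint, while the chemical-shift phase
#' `exp(i 2 pi nu t1)` and T2 decay run continuously across chunks -- the
#' homodecoupling property. Each site is scaled by its slice volume fraction,
#' and field inhomogeneity enters only as the residual offset at the slice
#' center. The first and last chunks are half-length so their refocusing
#' midpoints fall at t1 = 0 and t1 = t1max.
#'
#' @param system A [spin_system()].
#' @param field A [field_model()] with `g4_gauss_per_cm > 0`.
#' @param zs A [zs_acquisition()].
#' @param pulse A [slice_pulse()].
#' @param weights Per-site relaxation amplitude factor (see
#'   [simulate_conventional_fid()]).
#' @return Complex FID of length `t1_s * spectral_width_hz`.
#' @export
simulate_zs_pureshift_fid <- function(system, field, zs, pulse, weights) {
  w <- resolve_weights(system, weights)
  n <- round(zs$t1_s * zs$spectral_width_hz)
  t <- (seq_len(n) - 1) / zs$spectral_width_hz
  seg <- chunk_segments(t, zs$n_chunks, zs$chunk_duration_s)
  loss <- zs$per_element_loss^(seg$index - 1L)

  s <- complex(real = rep(0, n))
  for (k in seq_along(system$spins)) {
    site <- system$spins[[k]]
    nu <- (site$shift_ppm - field$carrier_ppm) * field$spectrometer_mhz
    geom <- slice_geometry(field, pulse, nu)
    if (!geom$inside) {
      warning(sprintf(
        "site '%s': slice center %.3g cm falls outside the sample; site contributes no signal",
        site$label, nu / (field$gamma_hz_per_gauss * field$g4_gauss_per_cm)),
        call. = FALSE)
      next
    }
    dz <- inhomogeneity_offset(field, geom$slice_center_cm)
    jmod <- rep(1, n)
    for (cp in system$couplings) {
      partner <- if (cp$site_a == site$label) cp$site_b
                 else if (cp$site_b == site$label) cp$site_a
                 else next
      np <- site_by_label(system, partner)$n_equivalent
      jmod <- jmod * cos(pi * cp$j_hz * (t - seg$midpoint))^np
    }
    s <- s + geom$slice_fraction * site$n_equivalent * w[k] *
      exp((2i * pi * (nu + dz) - 1 / site$t2_s) * t) * jmod * loss
  }
  s
}

new_relaxation_series <- function(delays, fids, mode, experiment, scheme,
                                  field, zs, pulse, duration,
                                  spectral_width_hz) {
  stopifnot(length(delays) == length(fids))
  structure(
    list(delays = delays, fids = fids, mode = mode, experiment = experiment,
         meta = list(scheme = scheme, field = field, zs = zs, pulse = pulse,
                     duration_s = duration,
                     spectral_width_hz = spectral_width_hz,
                     carrier_ppm = field$carrier_ppm,
                     spectrometer_mhz = field$spectrometer_mhz)),
    class = "relaxation_series"
  )
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf(
    "<relaxation_series> %s / %s mode: %d delays (%g .. %g s), %d points per FID\n",
    x$experiment, x$mode, length(x$delays), min(x$delays), max(x$delays),
    length(x$fids[[1]])))
  invisible(x)
}

run_relaxation_experiment <- function(system, field, delays, weight_fun,
                                      experiment, mode, zs, pulse, duration,
                                      spectral_width_hz) {
  mode <- match.arg(mode, c("conventional", "zs"))
  if (mode == "zs" || is.null(duration) || is.null(spectral_width_hz)) {
    if (!inherits(zs, "zs_acquisition")) {
      stop("a zs_acquisition() is required (it also supplies the default duration and spectral width for conventional mode)",
           call. = FALSE)
    }
  }
  if (is.null(duration)) duration <- zs$t1_s
  if (is.null(spectral_width_hz)) spectral_width_hz <- zs$spectral_width_hz
  if (mode == "zs" && is.null(pulse)) {
    stop("zs mode requires a slice_pulse()", call. = FALSE)
  }
  t1s <- vapply(system$spins, `[[`, numeric(1), "t1_s")
  t2s <- vapply(system$spins, `[[`, numeric(1), "t2_s")
  fids <- lapply(delays, function(d) {
    w <- weight_fun(d, t1s, t2s)
    names(w) <- site_labels(system)
    if (mode == "zs") {
      simulate_zs_pureshift_fid(system, field, zs, pulse, w)
    } else {
      simulate_conventional_fid(system, field, w, duration, spectral_width_hz)
    }
  })
  new_relaxation_series(delays, fids, mode, experiment, NULL, field, zs,
                        pulse, duration, spectral_width_hz)
}

#' Run an arrayed inversion-recovery experiment
#'
#' One FID per recovery delay, each site weighted by
#' [ir_recovery_factor()] with its own T1. `mode` selects conventional
#' full-volume synthesis or real-time ZS pure-shift synthesis.
#'
#' @param system A [spin_system()].
#' @param field A [field_model()].
#' @param scheme An [ir_scheme()].
#' @param mode `"conventional"` or `"zs"`.
#' @param zs A [zs_acquisition()]; also supplies the default acquisition
#'   duration and spectral width for conventional mode, keeping the two modes
#'   comparable bin-for-bin.
#' @param pulse A [slice_pulse()] (required for `mode = "zs"`).
#' @param duration,spectral_width_hz Conventional-mode overrides.
#' @return A `"relaxation_series"` with one FID per tau1.
#' @export
run_ir_experiment <- function(system, field, scheme,
                              mode = c("conventional", "zs"), zs = NULL,
                              pulse = NULL, duration = NULL,
                              spectral_width_hz = NULL) {
  stopifnot(inherits(scheme, "ir_scheme"))
  ser <- run_relaxation_experiment(
    system, field, scheme$tau1_list,
    function(d, t1s, t2s) {
      1 - (1 + scheme$inversion_efficiency) * exp(-d / t1s)
    },
    "IR", match.arg(mode), zs, pulse, duration, spectral_width_hz)
  ser$meta$scheme <- scheme
  ser
}

#' Run an arrayed CPMG experiment
#'
#' One FID per total spin-echo delay, each site weighted by
#' [cpmg_decay_factor()] with its own T2.
#'
#' @inheritParams run_ir_experiment
#' @param scheme A [cpmg_scheme()].
#' @return A `"relaxation_series"` with one FID per Delta.
#' @export
run_cpmg_experiment <- function(system, field, scheme,
                                mode = c("conventional", "zs"), zs = NULL,
                                pulse = NULL, duration = NULL,
                                spectral_width_hz = NULL) {
  stopifnot(inherits(scheme, "cpmg_scheme"))
  ser <- run_relaxation_experiment(
    system, field, scheme$delta_list,
    function(d, t1s, t2s) exp(-d / t2s),
    "CPMG", match.arg(mode), zs, pulse, duration, spectral_width_hz)
  ser$meta$scheme <- scheme
  ser
}
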