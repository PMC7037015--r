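new_fit_result <- function(model, t_fit_s = NA_real_, t_stderr_s = NA_real_,
                           amplitude = NA_real_, efficiency_fit = NA_real_,
                           residual_rms = NA_real_, n_points = 0L,
                           converged = FALSE, boot_stderr_s = NA_real_) {
  structure(
    list(model = model, t_fit_s = t_fit_s, t_stderr_s = t_stderr_s,
         amplitude = amplitude, efficiency_fit = efficiency_fit,
         residual_rms = residual_rms, n_points = as.integer(n_points),
         converged = converged, boot_stderr_s = boot_stderr_s),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  lab <- if (x$model == "IR") "T1" else "T2"
  if (x$converged) {
    cat(sprintf("<fit_result %s> %s = %.4g +/- %.2g s (I0 = %.4g, rms %.3g, n = %d)\n",
                x$model, lab, x$t_fit_s, x$t_stderr_s, x$amplitude,
                x$residual_rms, x$n_points))
    if (x$model == "IR" && is.finite(x$efficiency_fit)) {
      cat(sprintf("  inversion efficiency %.4g\n", x$efficiency_fit))
    }
  } else {
    cat(sprintf("<fit_result %s> not converged (n = %d)\n", x$model,
                x$n_points))
  }
  invisible(x)
}

check_fit_input <- function(delays, intensities, min_points) {
  if (length(delays) != length(intensities)) {
    stop("`delays` and `intensities` must have the same length",
         call. = FALSE)
  }
  if (any(!is.finite(delays)) || any(!is.finite(intensities))) {
    stop("fit inputs must be finite", call. = FALSE)
  }
  if (length(delays) < min_points) {
    stop(sprintf("need at least %d points for this model, got %d",
                 min_points, length(delays)), call. = FALSE)
  }
  ord <- order(delays)
  list(d = as.numeric(delays)[ord], y = as.numeric(intensities)[ord])
}

# tau at which an IR curve crosses zero, linearly interpolated between the
# delays bracketing the sign change; an exact zero datum wins directly.
ir_null_delay <- function(d, y) {
  z <- which(y == 0)
  if (length(z)) return(d[z[1]])
  sc <- which(y[-length(y)] * y[-1] < 0)
  if (!length(sc)) return(NA_real_)
  i <- sc[1]
  d[i] - y[i] * (d[i + 1] - d[i]) / (y[i + 1] - y[i])
}

asymptotic_stderr <- function(fit, par) {
  tryCatch(summary(fit)$coefficients[par, "Std. Error"],
           error = function(e) NA_real_)
}

boot_refit <- function(n_boot, d, fitted_vals, resid, refit) {
  if (n_boot <= 0) return(NA_real_)
  est <- vapply(seq_len(n_boot), function(b) {
    yb <- fitted_vals + sample(resid, length(resid), replace = TRUE)
    tryCatch(refit(yb), error = function(e) NA_real_)
  }, numeric(1))
  stats::sd(est, na.rm = TRUE)
}

#' Fit the inversion-recovery model
#'
#' Nonlinear least squares of `I(tau) = I0 * (1 - (1 + w) * exp(-tau/T1))`
#' to signed peak heights. By default the inversion efficiency w is a free
#' parameter (3-parameter fit); `fix_efficiency = TRUE` pins w = 1, the
#' ideal-inversion 2-parameter form. On noiseless ideal data the two give
#' identical T1. The reported uncertainty is the asymptotic standard error
#' (residual-scaled Jacobian covariance); an optional residual bootstrap is
#' available for comparison.
#'
#' @param delays Recovery delays tau1 in seconds.
#' @param intensities Signed real peak heights, one per delay.
#' @param fix_efficiency Pin w = 1 instead of fitting it.
#' @param n_boot Number of residual-bootstrap refits (0 = off).
#' @return A `"fit_result"`; `converged = FALSE` (never an exception) when
#'   the solver fails or the data are degenerate.
#' @export
fit_ir <- function(delays, intensities, fix_efficiency = FALSE, n_boot = 0) {
  inp <- check_fit_input(delays, intensities,
                         min_points = if (fix_efficiency) 2L else 3L)
  d <- inp$d; y <- inp$y
  n <- length(d)
  if (diff(range(y)) == 0) return(new_fit_result("IR", n_points = n))

  tnull <- ir_null_delay(d, y)
  t1_0 <- if (is.finite(tnull) && tnull > 0) tnull / log(2) else
    stats::median(d)
  i0_0 <- y[n]
  if (i0_0 == 0) i0_0 <- max(abs(y))
  dat <- data.frame(d = d, y = y)
  fit <- tryCatch({
    if (fix_efficiency) {
      minpack.lm::nlsLM(y ~ I0 * (1 - 2 * exp(-d / T1)), data = dat,
                        start = list(I0 = i0_0, T1 = t1_0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ I0 * (1 - (1 + w) * exp(-d / T1)), data = dat,
                        start = list(I0 = i0_0, T1 = t1_0, w = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(new_fit_result("IR", n_points = n))

  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  boot <- boot_refit(n_boot, d, stats::fitted(fit), res, function(yb) {
    db <- data.frame(d = d, y = yb)
    f <- if (fix_efficiency) {
      minpack.lm::nlsLM(y ~ I0 * (1 - 2 * exp(-d / T1)), data = db,
                        start = as.list(cf))
    } else {
      minpack.lm::nlsLM(y ~ I0 * (1 - (1 + w) * exp(-d / T1)), data = db,
                        start = as.list(cf))
    }
    stats::coef(f)[["T1"]]
  })
  new_fit_result("IR",
                 t_fit_s = cf[["T1"]],
                 t_stderr_s = asymptotic_stderr(fit, "T1"),
                 amplitude = cf[["I0"]],
                 efficiency_fit = if (fix_efficiency) 1 else cf[["w"]],
                 residual_rms = sqrt(mean(res^2)),
                 n_points = n,
                 converged = isTRUE(fit$convInfo$isConv) && cf[["T1"]] > 0,
                 boot_stderr_s = boot)
}

#' Fit the CPMG mono-exponential decay model
#'
#' Nonlinear least squares of `I(Delta) = I0 * exp(-Delta/T2)`. Starting
#' values come from a log-linear regression on the points above 5% of the
#' maximum intensity. Scale-invariant: rescaling the intensities rescales
#' I0 and leaves T2 unchanged.
#'
#' @param delays Total spin-echo delays Delta in seconds.
#' @param intensities Peak heights, one per delay (positive-dominant).
#' @param n_boot Number of residual-bootstrap refits (0 = off).
#' @return A `"fit_result"`; `converged = FALSE` on degenerate data.
#' @export
fit_cpmg <- function(delays, intensities, n_boot = 0) {
  inp <- check_fit_input(delays, intensities, min_points = 2L)
  d <- inp$d; y <- inp$y
  n <- length(d)
  if (max(y) <= 0 || diff(range(y)) == 0) {
    return(new_fit_result("CPMG", n_points = n))
  }
  sel <- which(y > 0.05 * max(y))
  t2_0 <- NA_real_
  if (length(sel) >= 2) {
    ll <- stats::lm(log(y[sel]) ~ d[sel])
    sl <- stats::coef(ll)[[2]]
    if (is.finite(sl) && sl < 0) t2_0 <- -1 / sl
  }
  if (!is.finite(t2_0) || t2_0 <= 0) t2_0 <- stats::median(d)
  dat <- data.frame(d = d, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-d / T2), data = dat,
                      start = list(I0 = max(y), T2 = t2_0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(new_fit_result("CPMG", n_points = n))

  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  boot <- boot_refit(n_boot, d, stats::fitted(fit), res, function(yb) {
    db <- data.frame(d = d, y = yb)
    stats::coef(minpack.lm::nlsLM(y ~ I0 * exp(-d / T2), data = db,
                                  start = as.list(cf)))[["T2"]]
  })
  new_fit_result("CPMG",
                 t_fit_s = cf[["T2"]],
                 t_stderr_s = asymptotic_stderr(fit, "T2"),
                 amplitude = cf[["I0"]],
                 residual_rms = sqrt(mean(res^2)),
                 n_points = n,
                 converged = isTRUE(fit$convInfo$isConv) && cf[["T2"]] > 0,
                 boot_stderr_s = boot)
}

fit_tracked_table <- function(tab, fit_fun, ...) {
  cols <- setdiff(names(tab), "delay_s")
  pos <- as.numeric(sub("^ppm_", "", cols))
  fits <- lapply(cols, function(cn) fit_fun(tab$delay_s, tab[[cn]], ...))
  data.frame(
    position_ppm = pos,
    t_fit_s = vapply(fits, `[[`, numeric(1), "t_fit_s"),
    t_stderr_s = vapply(fits, `[[`, numeric(1), "t_stderr_s"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
}

#' Per-peak T1/T2 table from an IR + CPMG series pair
#'
#' Picks reference peaks on the most intense member of each series, tracks
#' signed heights across both arrays, fits the IR and CPMG models per peak,
#' and joins the results by peak position. The output mirrors the usual
#' per-proton relaxation table: chemical shift, T1 +/- sigma, T2 +/- sigma.
#'
#' @param ir_series A `"relaxation_series"` with `experiment == "IR"`.
#' @param cpmg_series A `"relaxation_series"` with `experiment == "CPMG"`.
#' @param min_height_fraction Peak-picking threshold (see [pick_peaks()]).
#' @param lb_hz,zero_fill Reconstruction parameters used for both series.
#' @param match_tol_ppm Join tolerance on peak positions (default 0.02 ppm).
#'   Peaks present in only one series are kept with NA in the other columns
#'   and reported in a warning, never dropped silently.
#' @param fix_efficiency Passed to [fit_ir()].
#' @return Data frame with columns `position_ppm`, `t1_s`, `t1_stderr_s`,
#'   `t2_s`, `t2_stderr_s`, sorted by descending ppm.
#' @export
relaxation_table <- function(ir_series, cpmg_series,
                             min_height_fraction = 0.05, lb_hz = 0,
                             zero_fill = 2L, match_tol_ppm = 0.02,
                             fix_efficiency = FALSE) {
  stopifnot(inherits(ir_series, "relaxation_series"),
            inherits(cpmg_series, "relaxation_series"))
  if (ir_series$experiment != "IR" || cpmg_series$experiment != "CPMG") {
    stop("expected an IR series and a CPMG series, in that order",
         call. = FALSE)
  }
  pk_ir <- reference_peaks(ir_series, min_height_fraction, lb_hz, zero_fill)
  pk_cp <- reference_peaks(cpmg_series, min_height_fraction, lb_hz,
                           zero_fill)
  empty <- data.frame(position_ppm = numeric(0), t1_s = numeric(0),
                      t1_stderr_s = numeric(0), t2_s = numeric(0),
                      t2_stderr_s = numeric(0))
  if (nrow(pk_ir) == 0 && nrow(pk_cp) == 0) return(empty)

  ft_ir <- fit_tracked_table(
    track_intensities(ir_series, pk_ir, lb_hz, zero_fill), fit_ir,
    fix_efficiency = fix_efficiency)
  ft_cp <- fit_tracked_table(
    track_intensities(cpmg_series, pk_cp, lb_hz, zero_fill), fit_cpmg)

  used_cp <- logical(nrow(ft_cp))
  rows <- lapply(seq_len(nrow(ft_ir)), function(i) {
    p <- ft_ir$position_ppm[i]
    j <- if (nrow(ft_cp)) which.min(abs(ft_cp$position_ppm - p)) else
      integer(0)
    if (length(j) && abs(ft_cp$position_ppm[j] - p) <= match_tol_ppm &&
        !used_cp[j]) {
      used_cp[j] <<- TRUE
      data.frame(position_ppm = p, t1_s = ft_ir$t_fit_s[i],
                 t1_stderr_s = ft_ir$t_stderr_s[i],
                 t2_s = ft_cp$t_fit_s[j], t2_stderr_s = ft_cp$t_stderr_s[j])
    } else {
      data.frame(position_ppm = p, t1_s = ft_ir$t_fit_s[i],
                 t1_stderr_s = ft_ir$t_stderr_s[i],
                 t2_s = NA_real_, t2_stderr_s = NA_real_)
    }
  })
  out <- do.call(rbind, c(rows, list(empty)))
  if (any(!used_cp)) {
    extra <- ft_cp[!used_cp, , drop = FALSE]
    out <- rbind(out, data.frame(position_ppm = extra$position_ppm,
                                 t1_s = NA_real_, t1_stderr_s = NA_real_,
                                 t2_s = extra$t_fit_s,
                                 t2_stderr_s = extra$t_stderr_s))
  }
  unmatched <- sum(is.na(out$t1_s)) + sum(is.na(out$t2_s))
  if (unmatched > 0) {
    warning(sprintf("%d peak(s) present in only one series (NA in the other columns)",
                    sum(is.na(out$t1_s) | is.na(out$t2_s))), call. = FALSE)
  }
  out <- out[order(-out$position_ppm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
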