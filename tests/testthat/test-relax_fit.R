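paper_tau1 <- c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32)
paper_delta <- c(0.025, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8)

test_that("noiseless IR data round-trip through the fit exactly", {
  y <- 2.5 * (1 - 2 * exp(-paper_tau1 / 4.99))
  fit <- fit_ir(paper_tau1, y)
  expect_true(fit$converged)
  expect_equal(fit$t_fit_s, 4.99, tolerance = 1e-6)
  expect_equal(fit$amplitude, 2.5, tolerance = 1e-6)
  expect_equal(fit$efficiency_fit, 1, tolerance = 1e-5)
  expect_lt(fit$t_stderr_s, 1e-6)
  # pinning the efficiency gives the same answer on ideal data
  fit2 <- fit_ir(paper_tau1, y, fix_efficiency = TRUE)
  expect_equal(fit2$t_fit_s, fit$t_fit_s, tolerance = 1e-8)
})

test_that("the fitted IR curve passes through zero at T1 ln 2", {
  d <- c(0.5, log(2), 2)
  y <- 1 - 2 * exp(-d)       # T1 = 1, I0 = 1
  fit <- fit_ir(d, y)
  at_null <- fit$amplitude *
    (1 - (1 + fit$efficiency_fit) * exp(-log(2) / fit$t_fit_s))
  expect_lt(abs(at_null), 1e-9)
})

test_that("asymptotic stderr agrees with the residual bootstrap to 3x", {
  set.seed(42)
  y <- 1 * (1 - 2 * exp(-paper_tau1 / 2.5)) + rnorm(10, sd = 0.01)
  fit <- fit_ir(paper_tau1, y, n_boot = 200)
  expect_true(fit$converged)
  expect_gt(fit$t_stderr_s / fit$boot_stderr_s, 1 / 3)
  expect_lt(fit$t_stderr_s / fit$boot_stderr_s, 3)
})

test_that("noiseless CPMG data round-trip through the fit exactly", {
  y <- 3.1 * exp(-paper_delta / 2.77)
  fit <- fit_cpmg(paper_delta, y)
  expect_true(fit$converged)
  expect_equal(fit$t_fit_s, 2.77, tolerance = 1e-6)
  expect_lt(fit$t_stderr_s, 1e-6)

  # two exact points: closed-form identity T2 = (d2-d1)/log(y1/y2)
  d2 <- c(0.4, 1.2)
  y2 <- 0.8 * exp(-d2 / 0.9)
  f2 <- fit_cpmg(d2, y2)
  expect_equal(f2$t_fit_s, diff(d2) / log(y2[1] / y2[2]), tolerance = 1e-9)
})

test_that("fit_cpmg is scale invariant", {
  y <- exp(-paper_delta / 1.3)
  f1 <- fit_cpmg(paper_delta, y)
  f2 <- fit_cpmg(paper_delta, 1e6 * y)
  expect_equal(f2$t_fit_s, f1$t_fit_s, tolerance = 1e-9)
  expect_equal(f2$amplitude / f1$amplitude, 1e6, tolerance = 1e-9)
})

test_that("degenerate fit inputs fail softly or loudly as appropriate", {
  expect_false(fit_cpmg(paper_delta, rep(0, 10))$converged)
  expect_false(fit_ir(paper_tau1, rep(0.3, 10))$converged)
  expect_error(fit_ir(c(1, 2), c(0.1, 0.2)), "at least 3")
  expect_error(fit_cpmg(1.5, 0.4), "at least 2")
  expect_error(fit_ir(c(1, 2, 3), c(1, 2)), "same length")
  expect_error(fit_cpmg(c(1, 2), c(NA, 1)), "finite")
})

test_that("end-to-end parameter recovery over a relaxation-time grid", {
  # synthesis -> reconstruction -> tracking -> fit, noiseless, pure-shift
  # mode, relative error < 1e-3 for T from 0.1 to 10 s
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 1,
                   g4_gauss_per_cm = 0.56)
  zs <- zs_acquisition(10, 0.02, 2000)
  pl <- slice_pulse(16.2e-3)
  for (T in c(0.1, 0.3, 1, 3, 10)) {
    sys <- spin_system(list(spin("a", 1.2, t1_s = T, t2_s = T)))
    ir <- run_ir_experiment(sys, f,
                            ir_scheme(T * c(0.1, 0.3, 0.7, 1.5, 3)),
                            mode = "zs", zs = zs, pulse = pl)
    delt <- round(T * c(0.05, 0.15, 0.4, 1, 2.5) / 2e-4) * 2e-4
    cp <- run_cpmg_experiment(sys, f, cpmg_scheme(delt),
                              mode = "zs", zs = zs, pulse = pl)
    ti <- track_intensities(ir, reference_peaks(ir))
    tc <- track_intensities(cp, reference_peaks(cp))
    expect_equal(fit_ir(ti$delay_s, ti[[2]])$t_fit_s, T,
                 tolerance = 1e-3)
    expect_equal(fit_cpmg(tc$delay_s, tc[[2]])$t_fit_s, T,
                 tolerance = 1e-3)
  }
})

test_that("a many-site singlet system round-trips through the full table", {
  sys <- quinine_system()
  sc <- acquisition_schemes("quinine")
  # longer conventional acquisition: lets every line decay fully so that
  # truncation ripple does not leak between close neighbours
  ir <- run_ir_experiment(sys, sc$field, sc$ir, mode = "conventional",
                          zs = sc$zs, duration = 4)
  cp <- run_cpmg_experiment(sys, sc$field, sc$cpmg, mode = "conventional",
                            zs = sc$zs, duration = 4)
  tab <- relaxation_table(ir, cp)
  truth <- as.data.frame(sys)
  expect_equal(nrow(tab), nrow(truth))
  for (i in seq_len(nrow(tab))) {
    j <- which.min(abs(truth$shift_ppm - tab$position_ppm[i]))
    expect_equal(tab$t1_s[i], truth$t1_s[j], tolerance = 1e-3)
    expect_equal(tab$t2_s[i], truth$t2_s[j], tolerance = 1e-3)
  }
})

test_that("noisy fits are seed-reproducible and unbiased on average", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 1)
  sys <- spin_system(list(spin("a", 1.2, t1_s = 1, t2_s = 0.6)))
  zs <- zs_acquisition(5, 0.02, 2000)
  cp <- run_cpmg_experiment(sys, f,
                            cpmg_scheme(c(0.05, 0.15, 0.4, 0.8, 1.6)),
                            mode = "conventional", zs = zs)
  pk <- reference_peaks(cp)
  one_fit <- function(seed, sigma = 0.02) {
    noisy <- add_noise(cp, noise_model(sigma, seed))
    ti <- track_intensities(noisy, pk)
    fit_cpmg(ti$delay_s, ti[[2]])$t_fit_s
  }
  # bit-for-bit reproducibility under a fixed seed
  expect_identical(one_fit(11), one_fit(11))

  ests <- vapply(1:100, one_fit, numeric(1))
  sem <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.6), 2 * sem)
})
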