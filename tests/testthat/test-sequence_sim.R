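test_that("relaxation amplitude factors match their closed forms", {
  # ideal inversion: -1 at tau = 0, null at T1 ln 2, saturates to 1
  expect_equal(ir_recovery_factor(0, 3), -1)
  expect_equal(ir_recovery_factor(3 * log(2), 3), 0)
  expect_equal(ir_recovery_factor(100, 1), 1, tolerance = 1e-12)
  expect_equal(ir_recovery_factor(0.0625, 4.99), -0.97511,
               tolerance = 1e-5)
  # imperfect inversion starts at -efficiency
  expect_equal(ir_recovery_factor(0, 3, efficiency = 0.9), -0.9)

  expect_equal(cpmg_decay_factor(0, 2), 1)
  expect_equal(cpmg_decay_factor(2 * log(2), 2), 0.5)
  expect_equal(cpmg_decay_factor(12.8, 2.77), 0.00984, tolerance = 1e-3)

  expect_error(ir_recovery_factor(1, 0), "> 0")
  expect_error(cpmg_decay_factor(1, -2), "> 0")
})

test_that("scheme constructors enforce their grid invariants", {
  expect_error(ir_scheme(numeric(0)), "nonempty")
  expect_error(ir_scheme(c(1, 0.5)), "increasing")
  expect_error(ir_scheme(c(0.5, 1), inversion_efficiency = 0), "0, 1")
  expect_error(cpmg_scheme(c(0.025, 0.0251), tau2_s = 200e-6),
               "integer multiples")
  expect_equal(cpmg_scheme(c(0.025, 0.05), 200e-6)$m_list, c(125L, 250L))
  expect_error(zs_acquisition(1, 0.02, 2000), "n_chunks")
  expect_error(zs_acquisition(40, 0.02, 1995), "divide")
  expect_equal(zs_acquisition(40, 0.02, 2000)$t1_s, 0.8)
})

test_that("conventional FID is the analytic damped sinusoid", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 1)
  sys <- spin_system(list(spin("a", 1.3, t1_s = 4, t2_s = 0.7)))
  sw <- 1000
  fid <- simulate_conventional_fid(sys, f, 1, 0.5, sw)
  t <- (seq_along(fid) - 1) / sw
  ref <- exp((2i * pi * 150 - 1 / 0.7) * t)   # 0.3 ppm x 500 MHz = 150 Hz
  expect_equal(fid, ref, tolerance = 1e-12)
  # linearity in the relaxation weight: IR at tau1 = 0 negates the signal
  expect_equal(simulate_conventional_fid(sys, f, -1, 0.5, sw), -ref,
               tolerance = 1e-12)
  expect_error(simulate_conventional_fid(sys, f, 1, -1, sw), "> 0")
})

test_that("an AX pair yields two doublets split by J", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 2)
  sys <- spin_system(list(spin("A", 2.4, 3, 2), spin("X", 1.6, 3, 2)),
                     list(coupling("A", "X", 7)))
  fid <- simulate_conventional_fid(sys, f, 1, 4, 1000)
  sp <- fid_to_spectrum(fid, 1000, 500, 2, zero_fill = 4)
  pk <- pick_peaks(sp, 0.2)
  expect_equal(nrow(pk), 4)
  hz <- sort(pk$position_ppm * 500)
  expect_equal(hz[2] - hz[1], 7, tolerance = 0.05)   # X doublet
  expect_equal(hz[4] - hz[3], 7, tolerance = 0.05)   # A doublet
  expect_equal(mean(hz[3:4]), 1200, tolerance = 0.05)
})

test_that("pure-shift FID with J = 0 equals slice_fraction x conventional", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 2.2,
                   g4_gauss_per_cm = 0.56)
  sys <- spin_system(list(spin("a", 3.42, 4.99, 2.77, 2)))
  zs <- zs_acquisition(40, 0.02, 2000)
  pl <- slice_pulse(16.2e-3)
  fz <- simulate_zs_pureshift_fid(sys, f, zs, pl, 1)
  fc <- simulate_conventional_fid(sys, f, 1, zs$t1_s, 2000)
  frac <- slice_geometry(f, pl, (3.42 - 2.2) * 500)$slice_fraction
  expect_equal(fz, frac * fc, tolerance = 1e-12)
})

test_that("J modulation is refocused at every chunk midpoint", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 2,
                   g4_gauss_per_cm = 0.56)
  sys_j <- spin_system(list(spin("A", 2.2, 3, 2), spin("X", 1.7, 3, 2)),
                       list(coupling("A", "X", 11)))
  sys_0 <- spin_system(list(spin("A", 2.2, 3, 2), spin("X", 1.7, 3, 2)))
  zs <- zs_acquisition(8, 0.02, 2000)
  pl <- slice_pulse(16.2e-3)
  fj <- simulate_zs_pureshift_fid(sys_j, f, zs, pl, 1)
  f0 <- simulate_zs_pureshift_fid(sys_0, f, zs, pl, 1)
  # full-chunk midpoints k * tau_c land on the sampling grid
  mids <- 0.02 * (1:7)
  idx <- round(mids * 2000) + 1
  expect_equal(fj[idx], f0[idx], tolerance = 1e-12)
  # and t1 = 0 (midpoint of the leading half chunk)
  expect_equal(fj[1], f0[1], tolerance = 1e-12)
})

test_that("chunking sidebands appear at multiples of 1/chunk_duration", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 2,
                   g4_gauss_per_cm = 0.56)
  sys <- spin_system(list(spin("A", 2.25, 3, 1.5), spin("X", 1.55, 3, 1.5)),
                     list(coupling("A", "X", 9)))
  sys0 <- spin_system(list(spin("A", 2.25, 3, 1.5), spin("X", 1.55, 3, 1.5)))
  pl <- slice_pulse(16.2e-3)
  nu_a <- 2.25 * 500  # absolute Hz position of site A
  for (tc in c(0.01, 0.02, 0.04)) {
    zs <- zs_acquisition(round(0.8 / tc), tc, 2000)
    # the J-modulation artifact alone: coupled minus J = 0 reference
    fid <- simulate_zs_pureshift_fid(sys, f, zs, pl, 1) -
           simulate_zs_pureshift_fid(sys0, f, zs, pl, 1)
    sp <- fid_to_spectrum(fid, 2000, 500, 2, zero_fill = 2)
    m <- Mod(sp$values)
    amp_at <- function(hz, win = 3) max(m[abs(sp$axis_hz - hz) < win])
    # the first sideband sits at nu +/- 1/tc and towers over the spectrum
    # between the parent and the sideband
    for (s in c(-1, 1)) {
      expect_gt(amp_at(nu_a + s / tc), 5 * amp_at(nu_a + s * 0.5 / tc))
      win <- abs(sp$axis_hz - (nu_a + s / tc)) < 0.25 / tc
      peak_hz <- sp$axis_hz[win][which.max(m[win])]
      expect_equal(peak_hz, nu_a + s / tc, tolerance = 2 / (1 / tc))
    }
  }
})

test_that("signals are linear in site amplitude and relaxation weight", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 1,
                   g4_gauss_per_cm = 0.56)
  mk <- function(neq) spin_system(list(spin("a", 1.2, 2, 1, neq)))
  zs <- zs_acquisition(4, 0.02, 2000)
  pl <- slice_pulse(16.2e-3)
  f1 <- simulate_zs_pureshift_fid(mk(1), f, zs, pl, 1)
  f3 <- simulate_zs_pureshift_fid(mk(3), f, zs, pl, 1)
  expect_equal(f3, 3 * f1, tolerance = 1e-12)
  expect_equal(simulate_zs_pureshift_fid(mk(1), f, zs, pl, 0.37),
               0.37 * f1, tolerance = 1e-12)
})

test_that("arrayed experiments weight each site by its own relaxation", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 1)
  sys <- spin_system(list(spin("a", 1.2, t1_s = 0.1, t2_s = 0.5)))
  zs <- zs_acquisition(4, 0.02, 2000)

  # saturated IR: all delays >> T1 give identical FIDs
  sat <- run_ir_experiment(sys, f, ir_scheme(c(5, 6, 7)),
                           mode = "conventional", zs = zs)
  expect_lt(max(Mod(sat$fids[[1]] - sat$fids[[3]])) /
              max(Mod(sat$fids[[1]])), 1e-6)

  # CPMG peak amplitude decreases monotonically with Delta
  cp <- run_cpmg_experiment(sys, f, cpmg_scheme(c(0.1, 0.4, 1.2, 3.2)),
                            mode = "conventional", zs = zs)
  amps <- vapply(cp$fids, function(x) max(Mod(x)), numeric(1))
  expect_true(all(diff(amps) < 0))

  # IR series changes sign between the delays bracketing T1 ln 2
  sysb <- spin_system(list(spin("a", 1.2, t1_s = 1, t2_s = 0.5)))
  ir <- run_ir_experiment(sysb, f, ir_scheme(c(0.2, 0.5, 1.0, 2, 5)),
                          mode = "conventional", zs = zs)
  first_pt <- vapply(ir$fids, function(x) Re(x[1]), numeric(1))
  crossing <- which(first_pt[-5] * first_pt[-1] < 0)
  expect_length(crossing, 1)
  tn <- log(2)  # T1 ln 2 = 0.693 s
  expect_true(ir$delays[crossing] < tn && tn < ir$delays[crossing + 1])

  expect_error(run_ir_experiment(sys, f, ir_scheme(numeric(0)),
                                 mode = "conventional", zs = zs))
})

test_that("a slice outside the sample contributes nothing, with a warning", {
  f <- field_model(spectrometer_mhz = 500, carrier_ppm = 0,
                   g4_gauss_per_cm = 0.56)
  # 5 ppm from the carrier: z = 2500/2384 cm > L/2
  sys <- spin_system(list(spin("far", 5, 2, 1)))
  zs <- zs_acquisition(4, 0.02, 2000)
  expect_warning(
    fid <- simulate_zs_pureshift_fid(sys, f, zs, slice_pulse(16.2e-3), 1),
    "outside the sample")
  expect_equal(max(Mod(fid)), 0)
})
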