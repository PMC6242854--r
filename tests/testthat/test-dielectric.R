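test_that("complex permittivity follows eps*eps0 - j sigma/omega", {
  # zero conductivity: purely real
  m <- dielectric_material(78, 0)
  expect_equal(complex_permittivity(m, 123), complex(real = 78 * eps0, imaginary = 0))

  # plasma at 1 kHz: loss term sigma/omega dominates the real part
  p <- complex_permittivity(blood_plasma(), 1e3)
  expect_equal(Re(p), 78 * eps0)
  expect_equal(Im(p), -0.06 / (2 * pi * 1e3), tolerance = 1e-12)
  expect_gt(abs(Im(p)) / Re(p), 1e3)

  # high-frequency limit: loss vanishes
  expect_lt(abs(Im(complex_permittivity(blood_plasma(), 1e15))), 1e-17)

  expect_error(complex_permittivity(blood_plasma(), 0), "positive")
  expect_error(complex_permittivity(blood_plasma(), -5), "positive")
})

test_that("Clausius-Mossotti factor matches identity, printed and limit cases", {
  f <- 1e3
  em <- complex_permittivity(blood_plasma(), f)
  expect_equal(clausius_mossotti(em, em), 0 + 0i)

  # blood cell in plasma below 10 kHz: strong nDEP, Re about -0.5
  for (fr in c(1e3, 5e3, 1e4)) {
    fcm <- clausius_mossotti(complex_permittivity(blood_cell_material(), fr),
                             complex_permittivity(blood_plasma(), fr))
    expect_equal(Re(fcm), -0.5, tolerance = 0.01)
  }

  # conductivity-dominated limit as omega -> 0
  lim <- oracle_fcm_lowfreq(1.0e-6, 60e-3)
  fcm_lo <- clausius_mossotti(complex_permittivity(blood_cell_material(), 1e-3),
                              complex_permittivity(blood_plasma(), 1e-3))
  expect_equal(Re(fcm_lo), lim, tolerance = 1e-9)

  expect_error(clausius_mossotti(2 + 0i, -1 + 0i), "degenerate")
})

test_that("Re(f_CM) stays within [-0.5, 1] for random passive materials", {
  set.seed(42)
  n <- 500
  for (i in seq_len(n)) {
    mp <- dielectric_material(runif(1, 1, 1000), 10^runif(1, -8, 1))
    mm <- dielectric_material(runif(1, 1, 1000), 10^runif(1, -8, 1))
    fr <- 10^runif(1, 0, 9)
    re <- Re(clausius_mossotti(complex_permittivity(mp, fr),
                               complex_permittivity(mm, fr)))
    expect_gte(re, -0.5 - 1e-12)
    expect_lte(re, 1 + 1e-12)
  }
})

test_that("core-shell mixing collapses to the homogeneous limits", {
  core <- dielectric_material(60, 0.5)
  shell <- dielectric_material(5, 1e-7)
  f <- 1e5

  # shell material identical to core: homogeneous collapse
  same <- shelled_particle(3e-6, 3.5e-6, core, core)
  expect_equal(effective_shell_permittivity(same, f),
               complex_permittivity(core, f), tolerance = 1e-12)

  # vanishing shell: recovers the core
  thin <- shelled_particle(3.5e-6 * (1 - 1e-9), 3.5e-6, core, shell)
  expect_equal(effective_shell_permittivity(thin, f),
               complex_permittivity(core, f), tolerance = 1e-6)

  # dominant shell: recovers the shell
  thick <- shelled_particle(3.5e-13, 3.5e-6, core, shell)
  expect_equal(effective_shell_permittivity(thick, f),
               complex_permittivity(shell, f), tolerance = 1e-6)

  expect_error(shelled_particle(4e-6, 3e-6, core, shell), "r_inner")
  expect_error(shelled_particle(-1e-6, 3e-6, core, shell), "r_inner")
})

test_that("cm_spectrum equals the manual composition and finds sign crossovers", {
  freqs <- 10^seq(1, 9, length.out = 40)

  # oracle equivalence: spectrum == clausius_mossotti o complex_permittivity
  sp <- cm_spectrum(blood_cell_material(), blood_plasma(), freqs)
  manual <- vapply(freqs, function(f)
    Re(clausius_mossotti(complex_permittivity(blood_cell_material(), f),
                         complex_permittivity(blood_plasma(), f))), 0)
  expect_equal(sp$re_fcm, manual, tolerance = 1e-14)

  # blood cell in plasma over 10 Hz - 10 kHz: flat near -0.5, no crossover
  lo <- cm_spectrum(blood_cell_material(), blood_plasma(),
                    10^seq(1, 4, length.out = 20))
  expect_true(all(abs(lo$re_fcm + 0.5) < 0.01))
  expect_true(is.na(lo$sign_crossover))

  # particle identical to medium: all zeros
  z <- cm_spectrum(blood_plasma(), blood_plasma(), freqs)
  expect_true(all(z$re_fcm == 0))

  # conductive particle in a high-permittivity medium: pDEP at low
  # frequency, nDEP at high frequency, so a crossover must be found
  part <- dielectric_material(10, 0.1)
  med <- dielectric_material(80, 0.01)
  x <- cm_spectrum(part, med, freqs)
  expect_false(is.na(x$sign_crossover))
  at_cross <- Re(clausius_mossotti(
    complex_permittivity(part, x$sign_crossover),
    complex_permittivity(med, x$sign_crossover)))
  expect_equal(at_cross, 0, tolerance = 1e-6)

  # swapping conductivities flips the sign of the low-frequency value,
  # matching the conductivity-limit oracle
  expect_equal(sign(x$re_fcm[1]), sign(oracle_fcm_lowfreq(0.1, 0.01)))
  expect_gt(x$re_fcm[1], 0)
  y <- cm_spectrum(dielectric_material(10, 0.01), dielectric_material(80, 0.1),
                   freqs)
  expect_lt(y$re_fcm[1], 0)

  expect_error(cm_spectrum(part, med, numeric(0)), "non-empty")
  expect_error(cm_spectrum(part, med, c(10, 5)), "increasing")
})
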