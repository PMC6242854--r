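test_that("gamma factor is the bounded odd tanh form", {
  expect_equal(gamma_factor(0), 0)
  # frozen hand-arithmetic values (k_B T / e about 25.5 mV at 296.15 K)
  expect_equal(gamma_factor(-10.8e-3), -0.10544, tolerance = 1e-3)
  expect_equal(gamma_factor(-13.825e-3), -0.13466, tolerance = 1e-3)
  expect_equal(gamma_factor(10.8e-3), -gamma_factor(-10.8e-3))
  z <- seq(-0.5, 0.5, by = 0.05)
  expect_true(all(abs(gamma_factor(z)) < 1))
  expect_error(gamma_factor(1e-3, temperature_T = -1), "positive")
})

test_that("van der Waals force matches A d / 12 h^2 and its scalings", {
  expect_equal(van_der_waals_force(7e-6, 0.5e-9, 5e-21), 1.1667e-8,
               tolerance = 1e-3)
  expect_equal(van_der_waals_force(14e-6, 0.5e-9),
               2 * van_der_waals_force(7e-6, 0.5e-9))
  expect_lt(van_der_waals_force(7e-6, 1), 1e-25)
  expect_error(van_der_waals_force(7e-6, 0), "singular")
})

test_that("EDL force has the screened exponential form", {
  p0 <- adhesion_params(zeta_particle = 0)
  expect_equal(edl_force(7e-6, 0.5e-9, p0), 0)
  # frozen hand-arithmetic value at the defaults
  expect_equal(edl_force(7e-6, 0.5e-9), 6.595e-10, tolerance = 1e-3)
  # decay constant kappa: ratio over one Debye length is exactly e
  p <- adhesion_params()
  h <- 2e-9
  expect_equal(edl_force(7e-6, h, p) / edl_force(7e-6, h + 1 / p$debye_kappa, p),
               exp(1), tolerance = 1e-12)
})

test_that("adhesive force conventions combine the two terms correctly", {
  p0 <- adhesion_params(zeta_particle = 0, zeta_wall = 0)
  h <- 1e-9
  expect_equal(adhesive_force(7e-6, h, p0),
               van_der_waals_force(7e-6, h))
  expect_equal(adhesive_force(7e-6, h, p0, convention = "signed"),
               van_der_waals_force(7e-6, h))
  # short-range divergence: h = 0.3 nm beats h = 3 nm by far more than 10x
  expect_gt(adhesive_force(7e-6, 0.3e-9) / adhesive_force(7e-6, 3e-9), 10)
  # literal-sum minus signed equals twice the EDL term
  p <- adhesion_params()
  expect_equal(adhesive_force(7e-6, h, p) -
                 adhesive_force(7e-6, h, p, convention = "signed"),
               2 * edl_force(7e-6, h, p), tolerance = 1e-12)
  expect_error(adhesive_force(7e-6, h, p, convention = "mean"), "arg")
})

test_that("IDT field gradient scales with V^2 and decays with height", {
  fm <- field_model(voltage_amplitude = 20)
  expect_equal(field_gradient(field_model(voltage_amplitude = 0), c(0, 1e-6)),
               c(0, 0))
  vr <- 20 / sqrt(2)
  expect_equal(field_gradient(fm, 0),
               (vr / fm$electrode_gap_g)^2 * 4 * pi / fm$electrode_pitch_p)
  expect_equal(field_gradient(field_model(voltage_amplitude = 40), 1e-6),
               4 * field_gradient(fm, 1e-6))
  h <- seq(0, 20e-6, length.out = 30)
  expect_true(all(diff(field_gradient(fm, h)) < 0))
})

test_that("DEP force is cubic in radius with sign following Re(f_CM)", {
  g <- 1e18
  expect_equal(dep_force(3.5e-6, 0, g), 0)
  expect_equal(dep_force(7e-6, -0.5, g), 8 * dep_force(3.5e-6, -0.5, g))
  # nDEP: negative Re(f_CM) gives a repulsive (negative) force
  expect_lt(dep_force(3.5e-6, -0.5, g), 0)
  expect_gt(dep_force(3.5e-6, 0.9, g), 0)
})

test_that("force balance finds the crossover and the protected regime", {
  h_grid <- 10^seq(-11, -7, length.out = 120)

  # no drive: adhesion always wins, no crossover
  fb0 <- force_balance(7e-6, field_model(voltage_amplitude = 0), h_grid = h_grid)
  expect_true(is.na(fb0$crossover_h))
  expect_false(fb0$protected)

  # calibrated defaults: RBC protected at 20 V, sub-micron debris is not
  fb20 <- force_balance(7e-6, field_model(voltage_amplitude = 20), h_grid = h_grid)
  expect_true(fb20$protected)
  fb_debris <- force_balance(0.5e-6, field_model(voltage_amplitude = 20),
                             h_grid = h_grid)
  expect_false(fb_debris$protected)

  # crossover shifts to shorter distance as the voltage rises
  xs <- vapply(c(10, 15, 20, 30), function(v)
    force_balance(7e-6, field_model(voltage_amplitude = v),
                  h_grid = h_grid)$crossover_h, 0)
  expect_true(all(is.finite(xs)))
  expect_true(all(diff(xs) < 0))

  # bisection agrees with a dense-grid argmin oracle to within a grid cell
  dense <- 10^seq(-11, -7, length.out = 4000)
  fbd <- force_balance(7e-6, field_model(voltage_amplitude = 20), h_grid = dense)
  argmin <- dense[which.min(abs(fbd$f_adh - fbd$f_dep))]
  i <- findInterval(fbd$crossover_h, dense)
  expect_lte(abs(match(argmin, dense) - i), 1)

  expect_error(force_balance(7e-6, h_grid = numeric(0)), "non-empty")
})

test_that("protected-diameter threshold is unique and voltage-monotone", {
  thr <- vapply(c(10, 15, 20, 30), function(v)
    protected_diameter_threshold(field_model(voltage_amplitude = v)), 0)
  expect_true(all(is.finite(thr)))
  expect_true(all(diff(thr) <= 0))
  # calibration: about 1 um at 20 V (the DEP force cannot protect debris)
  expect_gt(thr[3], 0.5e-6)
  expect_lt(thr[3], 2e-6)
  expect_warning(
    out <- protected_diameter_threshold(field_model(voltage_amplitude = 20),
                                        re_fcm = 0),
    "no protected-diameter threshold")
  expect_true(is.na(out))
})

test_that("bench-unit quantities round-trip to the SI values used by the forces", {
  expect_equal(parse_quantity("5 zJ"), 5e-21)
  expect_equal(parse_quantity("0.159 nm^-1"), 0.159e9)
  expect_equal(parse_quantity("-10.8 mV"), -10.8e-3)
  expect_equal(parse_quantity("7 um"), 7e-6)
  p <- adhesion_params(hamaker_A = parse_quantity("5 zJ"),
                       debye_kappa = parse_quantity("0.159 nm^-1"),
                       zeta_particle = parse_quantity("-10.8 mV"),
                       zeta_wall = parse_quantity("-13.825 mV"))
  expect_equal(adhesive_force(parse_quantity("7 um"), 0.5e-9, p),
               adhesive_force(7e-6, 0.5e-9), tolerance = 1e-12)
})
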