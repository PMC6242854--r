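test_that("branch entry probability implements margination over the flow split", {
  # plasma tracer: probability equals the flow fraction exactly
  expect_equal(branch_entry_probability(7e-6, "plasma", 0.02), 0.02)
  # perfect cell-free layer: zero weight means zero entry
  expect_equal(branch_entry_probability(7e-6, "core", 0.02,
                                        class_weights = c(core = 0, wall = 0)), 0)
  # larger cells enter less (size-dependent margination)
  d <- seq(2e-6, 15e-6, length.out = 20)
  p <- branch_entry_probability(d, "core", 0.02)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(branch_entry_probability(7e-6, "core", 1.2), "flow_fraction")
})

test_that("capture rule compares adhesion against the DEP window", {
  f20 <- field_model(voltage_amplitude = 20)
  f0 <- field_model(voltage_amplitude = 0)
  # at 20 V an RBC approaching to 10 nm is repelled, not captured
  expect_false(capture_rule(7e-6, 1e-8 * 0.99, f20))
  # without drive, anything inside the capture distance sticks
  expect_true(capture_rule(7e-6, 1e-8 * 0.99, f0))
  expect_false(capture_rule(7e-6, 1.1e-8, f0))   # outside the capture distance
  # sub-micron debris is not protected even at full drive
  expect_true(capture_rule(0.5e-6, 0.5e-9, f20))
})

test_that("lysis is a thresholded overvoltage hazard", {
  expect_equal(lysis_probability(20, 100), 0)
  expect_equal(lysis_probability(0, 100), 0)
  expect_gt(lysis_probability(25, 3.4), 0)
  # longer exposure (slower flow) lyses more
  expect_gt(lysis_probability(30, 10), lysis_probability(30, 1))
  expect_gt(lysis_probability(30, 3.4), lysis_probability(25, 3.4))
  set.seed(1)
  expect_false(any(lysis_rule(20, 100, n = 1000)))
  expect_error(lysis_probability(-1, 1), "nonnegative")
})

test_that("clog updates narrow the branch until the clog criterion", {
  b <- new_branch_state(15e-6)
  expect_equal(b$effective_width, 15e-6)
  expect_false(b$clogged)
  b1 <- clog_update(b, 7e-6, time = 1)
  expect_equal(b1$effective_width, 8e-6)
  expect_equal(b1$capture_multiplier, 3)
  expect_false(b1$clogged)
  b2 <- clog_update(b1, 7e-6, time = 2)
  expect_equal(b2$effective_width, 1e-6)
  expect_true(b2$clogged)            # below the smallest cell diameter
  expect_equal(b2$clog_time, 2)
  expect_error(clog_update(b2, 7e-6), "clogged")
})

test_that("stronger aggregation clogs the network faster", {
  pop <- tiny_population(5, volume_ul = 0.006)
  n_clogged <- vapply(c(1, 4), function(af) {
    ctl <- sim_control(aggregation_factor = af)
    out <- simulate_separation(pop, voltage = 0, duration = 30, seed = 5,
                               control = ctl)
    sum(out$branches$clogged)
  }, 0)
  expect_gt(n_clogged[2], n_clogged[1])
})

test_that("simulation conserves every species and reproduces bitwise", {
  pop <- tiny_population(3)
  a <- simulate_separation(pop, voltage = 15, duration = 20, seed = 9)
  b <- simulate_separation(pop, voltage = 15, duration = 20, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$branches, b$branches)
  expect_identical(a$cells$fate, b$cells$fate)
  expect_true(conservation_holds(a))

  # a different seed gives a different trajectory (same totals at inlet)
  c2 <- simulate_separation(pop, voltage = 15, duration = 20, seed = 10)
  expect_identical(c2$counts[, "inlet"], a$counts[, "inlet"])
})

test_that("an empty population yields zero counts everywhere", {
  empty <- structure(
    data.frame(species = character(), diameter = numeric(),
               lateral = character(), stringsAsFactors = FALSE),
    haematocrit_pct = 25, volume_ul = 0.001,
    class = c("cell_population", "data.frame"))
  out <- simulate_separation(empty, voltage = 20, duration = 5, seed = 1)
  expect_true(all(out$counts == 0))
  expect_true(conservation_holds(out))
})

test_that("lysed cells become debris that re-enters transport", {
  pop <- tiny_population(4)
  out <- simulate_separation(pop, voltage = 30, duration = 20, seed = 4)
  lysed <- sum(out$counts[c("RBC", "WBC", "PLT"), "lysed"])
  expect_gt(lysed, 0)
  expect_equal(out$counts["debris", "inlet"], lysed)
  expect_true(conservation_holds(out))
  # no lysis at or below the threshold voltage
  out20 <- simulate_separation(pop, voltage = 20, duration = 20, seed = 4)
  expect_equal(sum(out20$counts[, "lysed"]), 0)
})

test_that("invalid simulation inputs fail loudly", {
  pop <- tiny_population(1)
  expect_error(simulate_separation(pop, duration = 0, seed = 1), "positive")
  expect_error(simulate_separation(pop, dt = -1, seed = 1), "positive")
  expect_error(simulate_separation(pop, duration = 10), "seed")
})
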