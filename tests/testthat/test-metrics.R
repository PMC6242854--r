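test_that("cell loss, purity and yield reproduce the defining arithmetic", {
  expect_equal(cell_loss(100, 50, 50), 0)
  expect_equal(cell_loss(100, 50, 12), 38)
  expect_equal(cell_loss(100, 0, 0), 100)
  expect_error(cell_loss(0, 1, 1), "positive")

  expect_equal(purity_efficiency(5e6, 0), 100)
  expect_equal(purity_efficiency(5e6, 5e6), 0)
  expect_equal(purity_efficiency(5e6, 1.4e5), 97.2)
  expect_error(purity_efficiency(0, 1), "positive")

  expect_equal(plasma_yield(25, 25, 0), 0)     # no concentration change
  expect_equal(plasma_yield(25, 45, 0), 59.2593, tolerance = 1e-5)
  # H_p = H_i: algebraic cancellation gives exactly 100%
  expect_equal(plasma_yield(25, 45, 25), 100)
  expect_error(plasma_yield(25, 30, 30), "degenerate")
  expect_error(plasma_yield(100, 45, 0), "< 100")
})

test_that("statistics agree with the independent one-line oracles", {
  set.seed(11)
  for (i in 1:100) {
    tab <- random_count_table()
    rep <- suppressWarnings(performance_report(tab))
    for (r in seq_len(nrow(tab))) {
      expect_equal(rep$cell_loss_pct[r],
                   oracle_loss(tab$c_in[r], tab$c_blood_out[r], tab$c_plasma_out[r]),
                   tolerance = 1e-12)
      expect_equal(rep$purity_efficiency_pct[r],
                   oracle_purity(tab$c_in[r], tab$c_plasma_out[r]),
                   tolerance = 1e-12)
    }
    expect_equal(attr(rep, "plasma_yield_pct"),
                 oracle_yield(attr(tab, "h_in"), attr(tab, "h_blood_out"),
                              attr(tab, "h_plasma_out")),
                 tolerance = 1e-12)
  }
})

test_that("monotonicity: purity falls with C_p, yield rises with H_o", {
  cp <- seq(0, 1e6, length.out = 20)
  expect_true(all(diff(purity_efficiency(5e6, cp)) < 0))
  ho <- seq(26, 60, length.out = 20)
  expect_true(all(diff(plasma_yield(25, ho, 5)) > 0))
})

test_that("report flags out-of-range values instead of clipping them", {
  tab <- count_table("RBC", c_in = 100, c_blood_out = 90, c_plasma_out = 30)
  expect_warning(rep <- performance_report(tab), "outside")
  expect_equal(rep$cell_loss_pct[1], -20)      # reported, not clipped
  expect_true(rep$out_of_range[1])
})

test_that("aggregate row sums concentrations and flow weighting works", {
  tab <- count_table(c("RBC", "PLT"), c_in = c(100, 50),
                     c_blood_out = c(60, 30), c_plasma_out = c(10, 5),
                     q_in = 1, q_blood_out = 0.7, q_plasma_out = 0.3)
  rep <- performance_report(tab)
  agg <- rep[rep$species == "all", ]
  expect_equal(agg$cell_loss_pct, oracle_loss(150, 90, 15))
  fw <- performance_report(tab, flow_weighted = TRUE)
  expect_equal(fw$cell_loss_pct[fw$species == "all"],
               (1 - (90 * 0.7 + 15 * 0.3) / 150) * 100)
  tab2 <- count_table("RBC", 100, 60, 10)
  expect_error(performance_report(tab2, flow_weighted = TRUE), "flow")
})
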