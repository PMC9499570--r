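test_that("the logical error model has its threshold identities", {
  expect_equal(logical_error_rate(0.01 - 1e-15, 3), 0.1, tolerance = 1e-10)
  expect_equal(logical_error_rate(1e-3, 1), 0.01)
  expect_equal(logical_error_rate(1e-3, 29), 1e-16)
  expect_error(logical_error_rate(1e-3, 4), "odd")
  expect_error(logical_error_rate(0.6, 3), "p_phys")
})

test_that("factory models behave physically", {
  f <- factory_model("AutoCCZ", 19, 31, 1e-3)
  expect_gt(f$footprint, 0)
  expect_gt(f$period_cycles, 0)
  expect_true(f$p_out >= 0 && f$p_out < 1)
  # larger distances distill better
  f2 <- factory_model("AutoCCZ", 23, 35, 1e-3)
  expect_lt(f2$p_out, f$p_out)
  ft <- factory_model("T15to1", 19, 31, 1e-3)
  expect_true(ft$p_out >= 0 && ft$p_out < 1)
  expect_error(factory_model("AutoCCZ", 4, 31, 1e-3), "odd")
})

test_that("evaluate_config implements the adopted layout and bottleneck", {
  hw <- hardware_assumptions(p_phys = 1e-3, cycle_time = 1e-6,
                             reaction_time = 1e-5, n_factories = 4L)
  # hand-built factory producing one Toffoli per 4 cycles in aggregate:
  # period 4 cycles per factory x 4 factories -> 1 Toffoli per microsecond
  fac <- structure(list(kind = "AutoCCZ", d1 = 19L, d2 = 31L, p_phys = 1e-3,
                        footprint = 0, period_cycles = 4, p_out = 0),
                   class = "factory_model")
  cfg <- surface_code_config(29, fac, 4L)
  est <- evaluate_config(cfg, hw, logical_qubits = 1000, toffoli_count = 3.6e9)
  expect_equal(est$runtime_hours, 1, tolerance = 1e-12)
  # zero-footprint factories: qubits = 1.5 * Q * 2 (d+1)^2
  expect_equal(est$physical_qubits, 1.5 * 1000 * 2 * 30^2)
  expect_equal(est$spacetime_volume, est$physical_qubits * 3600)

  # doubling factories halves runtime in the bottleneck regime
  cfg8 <- surface_code_config(29, fac, 8L)
  est8 <- evaluate_config(cfg8, hw, 1000, 3.6e9)
  expect_equal(est8$runtime_hours, 0.5, tolerance = 1e-12)

  # the optional reaction-time floor binds when factories are fast enough
  fac_fast <- structure(list(kind = "AutoCCZ", d1 = 19L, d2 = 31L,
                             p_phys = 1e-3, footprint = 0,
                             period_cycles = 1, p_out = 0),
                        class = "factory_model")
  est_fast <- evaluate_config(surface_code_config(29, fac_fast, 64L), hw,
                              1000, 1e6, reaction_floor = TRUE)
  expect_equal(est_fast$runtime_hours, 1e6 * hw$reaction_time / 3600)
})

test_that("failure probabilities stay in [0, 1] and are deterministic", {
  hw <- hardware_assumptions(p_phys = 1e-3)
  fac <- factory_model("AutoCCZ", 15, 23, 1e-3)
  for (d in c(3, 15, 29)) {
    cfg <- surface_code_config(d, fac, 4L)
    e1 <- evaluate_config(cfg, hw, 500, 1e9)
    e2 <- evaluate_config(cfg, hw, 500, 1e9)
    expect_identical(e1, e2)
    expect_true(e1$p_fail_total >= 0 && e1$p_fail_total <= 1)
    expect_gt(e1$spacetime_volume, 0)
  }
})

test_that("the optimizer equals exhaustive search on small grids", {
  hw <- hardware_assumptions(p_phys = 1e-3)
  grid <- list(d_data = c(25L, 27L, 29L), d1 = c(13L, 15L),
               d2 = c(21L, 25L, 29L), kind = "AutoCCZ")
  # grid has 3 x 2 x 3 = 18 <= 200 configurations
  best <- optimize_config(hw, 800, 5e8, grid)
  # brute force, written independently of the optimizer's loop order
  cands <- list()
  for (dd in grid$d_data) for (d1 in grid$d1) for (d2 in grid$d2) {
    if (d2 <= d1) next
    est <- evaluate_config(
      surface_code_config(dd, factory_model("AutoCCZ", d1, d2, hw$p_phys),
                          hw$n_factories), hw, 800, 5e8)
    if (est$p_fail_total <= 0.1) cands[[length(cands) + 1]] <- est
  }
  vols <- vapply(cands, `[[`, numeric(1), "spacetime_volume")
  expect_equal(best$spacetime_volume, min(vols))
  expect_lte(best$p_fail_total, 0.1)
})

test_that("optimized resources are monotone in the physical error rate", {
  prev <- NULL
  for (p in c(1e-3, 1e-4, 1e-5)) {
    est <- optimize_config(hardware_assumptions(p_phys = p), 1000, 1e9)
    expect_lte(est$p_fail_total, 0.1)
    if (!is.null(prev)) {
      expect_lte(est$physical_qubits, prev$physical_qubits)
      expect_lte(est$runtime_hours, prev$runtime_hours)
      expect_lte(est$config$d_data, prev$config$d_data)
    }
    prev <- est
  }
})

test_that("infeasible grids raise a typed error carrying the best failure", {
  hw <- hardware_assumptions(p_phys = 1e-3)
  grid <- list(d_data = 3L, d1 = 7L, d2 = 15L, kind = "AutoCCZ")
  err <- tryCatch(optimize_config(hw, 1e5, 1e12, grid),
                  qrechem_infeasible = function(e) e)
  expect_s3_class(err, "qrechem_infeasible")
  expect_true(is.finite(err$best_p_fail))
})
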