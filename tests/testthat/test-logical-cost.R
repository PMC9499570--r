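test_that("phase-estimation iteration counts follow ceil(pi lambda / 2 eps)", {
  expect_equal(pe_iterations(pi, pi / 2), 4)
  expect_equal(pe_iterations(1, 1e12), 1)
  expect_equal(pe_iterations(100, 1e-3), 157080)
  expect_error(pe_iterations(-1, 1e-3), "positive")
  expect_error(pe_iterations(1, 0), "positive")
})

test_that("walk-step costs depend on the factorization, not on lambda", {
  s1 <- walk_step_cost("THC", 10, list(M = 47))
  # lambda enters only through the iteration count; the step is untouched
  s2 <- walk_step_cost("THC", 10, list(M = 47))
  expect_identical(s1, s2)
  expect_error(walk_step_cost("SF", 10, list(M = 5)), "inconsistent")
  expect_error(walk_step_cost("THC", 10, list(M = 5),
                              list(b_coeff = 0, b_rot = 20)), "bit widths")
})

test_that("walk-step costs match the frozen cost-model fixtures", {
  # regression guard: values computed by this cost model at first release
  s <- walk_step_cost("THC", 10, list(M = 47))
  expect_equal(s$toffoli_per_step, 1312)
  expect_equal(s$logical_qubits, 474)
  expect_equal(s$gamma, 1598)
  s <- walk_step_cost("SF", 10, list(L = 50))
  expect_equal(s$toffoli_per_step, 725)
  expect_equal(s$logical_qubits, 260)
  expect_equal(s$gamma, 2750)
  s <- walk_step_cost("DF", 10, list(leaf_ranks = rep(8L, 50)))
  expect_equal(s$toffoli_per_step, 1898)
  expect_equal(s$logical_qubits, 470)
  expect_equal(s$gamma, 4400)
})

test_that("SF steps are cheaper but THC needs fewer qubits at scale", {
  # the qualitative Toffoli/space ordering of the factorization schemes
  a <- walk_step_cost("SF", 16, list(L = 136))
  b <- walk_step_cost("THC", 16, list(M = 75))
  expect_lt(a$toffoli_per_step, b$toffoli_per_step)
  expect_lt(b$logical_qubits, a$logical_qubits)
})

test_that("resource estimates compose iteration and step counts exactly", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    h <- synthesize_hamiltonian(n, sample(2:6, 1), seed = 400 + i)
    f <- single_factorize(h, tol = 0)
    res <- estimate_resources(h, f)
    expect_equal(res$toffoli_total, res$iterations * res$toffoli_per_step)
    expect_true(res$iterations >= 1 && res$iterations == round(res$iterations))
    expect_gt(res$logical_qubits, 0)
  }
})

test_that("halving the phase-estimation budget doubles the iterations", {
  h <- synthesize_hamiltonian(4, 3, seed = 3)
  f <- single_factorize(h, tol = 0)
  r1 <- estimate_resources(h, f, precision_budget(eps_pea = 1e-3))
  r2 <- estimate_resources(h, f, precision_budget(eps_pea = 5e-4))
  expect_lte(abs(r2$iterations - 2 * r1$iterations), 1)
  expect_identical(r1$toffoli_per_step, r2$toffoli_per_step)
})

test_that("the full SF pipeline matches its frozen regression fixture", {
  h <- synthesize_hamiltonian(6, 10, seed = 314)
  res <- estimate_resources(h, single_factorize(h, tol = 0))
  expect_equal(res$lambda_val, 15.9733792647, tolerance = 1e-8)
  expect_equal(res$iterations, 25091)
  expect_equal(res$toffoli_per_step, 221)
  expect_equal(res$logical_qubits, 136)
  expect_equal(res$toffoli_total, 25091 * 221)
})

test_that("log-log fits recover exact and noisy power laws", {
  N <- c(4, 8, 16, 32)
  fit <- fit_scaling(data.frame(N = N, value = 2 * N^3))
  expect_equal(fit$exponent, 3, tolerance = 1e-10)
  expect_equal(fit$prefactor, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  fit0 <- fit_scaling(data.frame(N = N, value = rep(7, 4)))
  expect_equal(fit0$exponent, 0, tolerance = 1e-12)

  set.seed(11)
  N8 <- seq(6, 20, by = 2)
  noisy <- 3 * N8^2.5 * exp(rnorm(8, sd = 0.05))
  fitn <- fit_scaling(data.frame(N = N8, value = noisy))
  expect_lt(abs(fitn$exponent - 2.5), 0.15)

  expect_error(fit_scaling(data.frame(N = c(1, 2), value = c(-1, 2))),
               "positive")
  expect_error(fit_scaling(data.frame(N = c(2, 2), value = c(1, 2))),
               "distinct")
})
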