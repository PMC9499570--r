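test_that("single factorization recovers the exact Cholesky rank", {
  h <- synthesize_hamiltonian(4, 3, seed = 7)
  sf <- single_factorize(h, tol = 1e-10)
  expect_identical(sf$n_vectors, 3L)
  expect_lt(frob(reconstruct_eri(sf) - h$eri), 1e-9)
  for (L in sf$vectors) expect_equal(L, t(L), tolerance = 1e-10)
})

test_that("tol = 0 single factorization reconstructs exactly", {
  for (s in 1:3) {
    h <- synthesize_hamiltonian(4, 6, seed = 60 + s)
    sf <- single_factorize(h, tol = 0)
    expect_lt(frob(reconstruct_eri(sf) - h$eri), 1e-10)
  }
})

test_that("single factorization argument contract is enforced", {
  h <- synthesize_hamiltonian(3, 2, seed = 1)
  expect_error(single_factorize(h), "exactly one")
  expect_error(single_factorize(h, tol = 0, n_vectors = 2), "exactly one")
  bad <- h; bad$eri <- -bad$eri
  expect_error(single_factorize(bad, tol = 0), "semidefinite")
})

test_that("pivoted Cholesky route reconstructs like the eigen route", {
  h <- synthesize_hamiltonian(4, 3, seed = 17)
  sc <- single_factorize(h, tol = 0, method = "cholesky")
  expect_lt(frob(reconstruct_eri(sc) - h$eri), 1e-9)
})

test_that("SF reconstruction error is non-increasing in retained rank", {
  # the ordered-truncation property, on many seeded instances
  for (s in 1:20) {
    h <- synthesize_hamiltonian(4, 5, seed = 700 + s)
    errs <- vapply(1:5, function(k) {
      frob(reconstruct_eri(single_factorize(h, n_vectors = k)) - h$eri)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-12))
  }
})

test_that("double factorization with zero cutoff is a refactorization identity", {
  h <- synthesize_hamiltonian(4, 4, seed = 33)
  sf <- single_factorize(h, tol = 0)
  df <- double_factorize(sf, leaf_tol = 0)
  expect_equal(df$leaf_ranks, rep(4L, sf$n_vectors))
  expect_equal(df$avg_rank, mean(df$leaf_ranks))
  # each leaf reconstructs its vector elementwise
  for (l in seq_along(sf$vectors)) {
    L_rec <- df$leaves[[l]]$U %*% (df$leaves[[l]]$f * t(df$leaves[[l]]$U))
    expect_lt(max(abs(L_rec - sf$vectors[[l]])), 1e-10)
    # eigenvectors orthonormal
    U <- df$leaves[[l]]$U
    expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-10)
  }
  expect_lt(frob(reconstruct_eri(df) - reconstruct_eri(sf)), 1e-10)
})

test_that("leaf truncation counts and errors follow the dropped eigenvalues", {
  # leaf with eigenvalues {1.0, 0.5, 1e-9} at cutoff 1e-6 has rank 2
  U <- random_orthogonal(3, seed = 5)
  f <- c(1.0, 0.5, 1e-9)
  L <- U %*% (f * t(U))
  sf <- structure(list(vectors = list(sym2(L)), n_vectors = 1L,
                       weights = 1, n_orb = 3L, method = "eigen"),
                  class = "sf_factorization")
  df <- double_factorize(sf, leaf_tol = 1e-6)
  expect_identical(df$leaf_ranks, 2L)

  # Frobenius error of a truncated leaf = sqrt(sum of squared dropped f)
  f2 <- c(2.0, -0.8, 0.3, 0.05)
  U4 <- random_orthogonal(4, seed = 6)
  L4 <- sym2(U4 %*% (f2 * t(U4)))
  sf4 <- structure(list(vectors = list(L4), n_vectors = 1L, weights = 1,
                        n_orb = 4L, method = "eigen"),
                   class = "sf_factorization")
  df4 <- double_factorize(sf4, leaf_tol = 0.2)
  L_rec <- df4$leaves[[1]]$U %*% (df4$leaves[[1]]$f * t(df4$leaves[[1]]$U))
  expect_equal(frob(L_rec - L4), sqrt(0.05^2), tolerance = 1e-10)
})

test_that("reconstructions satisfy the 8-fold permutational symmetry", {
  h <- synthesize_hamiltonian(4, 3, seed = 77)
  sf <- single_factorize(h, n_vectors = 2)
  df <- double_factorize(single_factorize(h, tol = 0), leaf_tol = 0.05)
  thc <- thc_factorize(h, rank = 3, seed = 2, max_iter = 300, n_restarts = 1)
  for (f in list(sf, df, thc)) {
    e <- reconstruct_eri(f)
    expect_lt(max(abs(e - aperm(e, c(2, 1, 3, 4)))), 1e-10)
    expect_lt(max(abs(e - aperm(e, c(1, 2, 4, 3)))), 1e-10)
    expect_lt(max(abs(e - aperm(e, c(3, 4, 1, 2)))), 1e-10)
  }
})

test_that("DF reconstruction error is non-increasing as the cutoff tightens", {
  for (s in 1:5) {
    h <- synthesize_hamiltonian(4, 5, seed = 900 + s)
    sf <- single_factorize(h, tol = 0)
    errs <- vapply(c(0.5, 0.1, 0.01, 0), function(tol) {
      frob(reconstruct_eri(double_factorize(sf, leaf_tol = tol)) - h$eri)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-12))
  }
})
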