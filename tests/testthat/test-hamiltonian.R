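test_that("synthetic Hamiltonians are seeded-deterministic and valid", {
  h1 <- synthesize_hamiltonian(4, 3, seed = 7)
  h2 <- synthesize_hamiltonian(4, 3, seed = 7)
  expect_identical(h1$eri, h2$eri)
  expect_identical(h1$h1, h2$h1)
  expect_false(identical(h1$eri, synthesize_hamiltonian(4, 3, seed = 8)$eri))

  # generator output passes every type invariant for many random triples
  set.seed(99)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    r <- sample(1:6, 1)
    h <- synthesize_hamiltonian(n, r, seed = 1000L + i)
    expect_silent(validate_hamiltonian(h))
    expect_true(h$n_alpha >= 0 && h$n_alpha <= n)
    expect_true(h$n_beta >= 0 && h$n_beta <= n)
  }
  expect_error(synthesize_hamiltonian(0, 1, 1), "n_orb")
  expect_error(synthesize_hamiltonian(3, 0, 1), "cholesky_rank")
})

test_that("generator ERI supermatrix rank equals the requested Cholesky rank", {
  h <- synthesize_hamiltonian(4, 3, seed = 7)
  ev <- eigen(eri_matrix(h$eri), symmetric = TRUE, only.values = TRUE)$values
  expect_lte(sum(ev > 1e-10), 3L)
  expect_equal(sum(ev > 1e-10), 3L)  # random vectors are independent a.s.
})

test_that("FCIDUMP write/read roundtrip is the identity", {
  h <- synthesize_hamiltonian(5, 4, seed = 21, e_core = 1.25)
  tf <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(h, tf)
  hr <- read_fcidump(tf)
  expect_equal(hr$eri, h$eri, tolerance = 1e-12)
  expect_equal(hr$h1, h$h1, tolerance = 1e-12)
  expect_equal(hr$e_core, h$e_core)
  expect_identical(hr$n_alpha, h$n_alpha)
  expect_identical(hr$n_beta, h$n_beta)

  # deterministic bytes
  tf2 <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(h, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("FCIDUMP reader populates symmetry orbits and handles core energy", {
  tf <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END",
               "0.7 1 1 1 1"), tf)
  h <- read_fcidump(tf)
  expect_equal(h$eri[1, 1, 1, 1], 0.7)
  expect_equal(sum(h$eri != 0), 1L)
  expect_identical(c(h$n_alpha, h$n_beta), c(1L, 1L))

  # a single stored (12|11) populates (21|11), (11|12), (11|21)
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END",
               "0.3 1 2 1 1"), tf)
  h <- read_fcidump(tf)
  expect_equal(h$eri[1, 2, 1, 1], 0.3)
  expect_equal(h$eri[2, 1, 1, 1], 0.3)
  expect_equal(h$eri[1, 1, 1, 2], 0.3)
  expect_equal(h$eri[1, 1, 2, 1], 0.3)
  expect_equal(sum(h$eri != 0), 4L)

  # zero Hamiltonian: exactly the core-energy line
  hz <- active_space_hamiltonian(2, 1, 1, 1.5, matrix(0, 2, 2),
                                 array(0, rep(2, 4)))
  write_fcidump(hz, tf)
  body <- readLines(tf)
  body <- body[!grepl("&|ORBSYM|ISYM", body)]
  expect_length(body, 1L)
  expect_match(body, " 0 +0 +0 +0$")
  expect_equal(read_fcidump(tf)$e_core, 1.5)
})

test_that("FCIDUMP reader rejects malformed input", {
  tf <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c(" &FCI NELEC=2,MS2=0,", " &END", "0.7 1 1 1 1"), tf)
  expect_error(read_fcidump(tf), "NORB")
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END", "0.7 3 1 1 1"), tf)
  expect_error(read_fcidump(tf), "out of range")
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END",
               "0.7 1 2 1 1", "0.8 2 1 1 1"), tf)
  expect_error(read_fcidump(tf), "contradictory")
  writeLines(c("no header here", "0.7 1 1 1 1"), tf)
  expect_error(read_fcidump(tf), "header")
  writeLines(c(" &FCI NORB=1,NELEC=2,MS2=0,", " &END",
               "(0.7,0.1) 1 1 1 1"), tf)
  expect_error(read_fcidump(tf), "complex")
})

test_that("exact_spectrum matches closed forms in degenerate limits", {
  # one spatial orbital: E(1,1) = -2t + U
  t0 <- 0.7; U <- 0.3
  h <- active_space_hamiltonian(1, 1, 1, 0, matrix(-t0, 1, 1),
                                array(U, c(1, 1, 1, 1)))
  expect_equal(exact_spectrum(h, 1, 1)$energies, -2 * t0 + U)

  # non-interacting limit: sector energies are sums of h1 eigenvalue subsets
  set.seed(12)
  h1m <- sym2(matrix(rnorm(9), 3))
  hz <- active_space_hamiltonian(3, 1, 1, 0, h1m, array(0, rep(3, 4)))
  e1 <- eigen(h1m, symmetric = TRUE)$values
  expect_equal(exact_spectrum(hz, 1, 1)$energies,
               sort(as.vector(outer(e1, e1, "+"))), tolerance = 1e-10)
  expect_equal(exact_spectrum(hz, 2, 0)$energies,
               sort(colSums(utils::combn(e1, 2))), tolerance = 1e-10)
})

test_that("exact_spectrum agrees with an independent Fock-space construction", {
  h <- synthesize_hamiltonian(3, 2, seed = 11)
  jw <- jw_sector_spectra(h)
  for (sa in 0:2) for (sb in 0:2) {
    idx <- which(jw$na == sa & jw$nb == sb)
    eF <- sort(eigen(jw$H[idx, idx, drop = FALSE], symmetric = TRUE,
                     only.values = TRUE)$values)
    eS <- exact_spectrum(h, sa, sb)$energies
    expect_length(eS, length(idx))
    expect_equal(eS, eF, tolerance = 1e-10)
  }
})

test_that("exact_spectrum is invariant under orthogonal orbital rotations", {
  for (s in 1:3) {
    h <- synthesize_hamiltonian(3, 2, seed = 40 + s)
    U <- random_orthogonal(3, seed = 50 + s)
    hr <- rotate_integrals(h, U)
    expect_equal(exact_spectrum(hr, 1, 1)$energies,
                 exact_spectrum(h, 1, 1)$energies, tolerance = 1e-8)
    expect_equal(exact_spectrum(hr, 2, 1)$energies,
                 exact_spectrum(h, 2, 1)$energies, tolerance = 1e-8)
  }
})

test_that("exact_spectrum refuses combinatorially large systems", {
  h <- synthesize_hamiltonian(9, 2, seed = 1)
  expect_error(exact_spectrum(h, 4, 4), "n_orb <= 8")
})

test_that("hamiltonian validation catches broken invariants", {
  h <- synthesize_hamiltonian(3, 2, seed = 2)
  bad <- h; bad$h1[1, 2] <- bad$h1[1, 2] + 1e-6
  expect_error(validate_hamiltonian(bad), "symmetric")
  bad <- h; bad$eri[1, 2, 3, 1] <- bad$eri[1, 2, 3, 1] + 1e-6
  expect_error(validate_hamiltonian(bad), "symmetry")
  bad <- h; bad$eri <- -bad$eri
  expect_error(validate_hamiltonian(bad), "semidefinite")
  expect_error(active_space_hamiltonian(2, 3, 1, 0, matrix(0, 2, 2),
                                        array(0, rep(2, 4))), "electron counts")
})
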