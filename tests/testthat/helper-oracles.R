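# Shared fixtures and independent oracles for the test suite.

sym2 <- function(m) (m + t(m)) / 2

# ---- independent Fock-space oracle (Jordan-Wigner ladder operators) ----
# Builds annihilation operators over 2N spin orbitals as dense
# 2^(2N) x 2^(2N) matrices, assembles the second-quantized Hamiltonian
# directly, and exposes per-sector spectra.  Completely independent of
# the package's Slater-Condon code path.
jw_annihilators <- function(n_so) {
  I2 <- diag(2); Z <- diag(c(1, -1)); am <- matrix(c(0, 0, 1, 0), 2, 2)
  lapply(seq_len(n_so), function(k) {
    m <- 1
    for (j in seq_len(n_so)) m <- kronecker(m, if (j < k) Z else if (j == k) am else I2)
    m
  })
}

jw_sector_spectra <- function(h) {
  n <- h$n_orb; n_so <- 2L * n
  a <- jw_annihilators(n_so); ad <- lapply(a, t)
  D <- 2^n_so
  so <- function(p, s) 2L * p - s        # s = 1 alpha, 0 beta
  H <- matrix(0, D, D)
  for (p in 1:n) for (q in 1:n) if (h$h1[p, q] != 0) for (s in c(1L, 0L))
    H <- H + h$h1[p, q] * ad[[so(p, s)]] %*% a[[so(q, s)]]
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (s2 in 1:n) {
    v <- h$eri[p, q, r, s2]
    if (v == 0) next
    for (s in c(1L, 0L)) for (t in c(1L, 0L))
      H <- H + 0.5 * v * ad[[so(p, s)]] %*% ad[[so(r, t)]] %*%
        a[[so(s2, t)]] %*% a[[so(q, s)]]
  }
  occ <- matrix(0L, D, n_so)
  for (k in seq_len(n_so))
    occ[, k] <- rep(rep(c(0L, 1L), each = 2^(n_so - k)), length.out = D)
  na <- rowSums(occ[, seq(1, n_so, by = 2), drop = FALSE])
  nb <- rowSums(occ[, seq(2, n_so, by = 2), drop = FALSE])
  list(H = H, na = na, nb = nb)
}

# ---- fixture: Hamiltonian whose closed-shell Fock matrix is diagonal ----
# With F diagonal the semicanonical MP2 equals bare second-order
# perturbation theory (no single-excitation contribution), so it can be
# checked against an FCI-based oracle.
mk_diagfock <- function(n, n_occ, seed, scale = 0.2) {
  h0 <- synthesize_hamiltonian(n, 2, seed)
  eri <- h0$eri * scale
  occ <- seq_len(n_occ)
  G <- matrix(0, n, n)
  for (i in occ) G <- G + 2 * eri[, , i, i] - eri[, i, i, ]
  h1 <- diag(seq(-1.5, 1.5, length.out = n)) - sym2(G)
  active_space_hamiltonian(n, n_occ, n_occ, 0, sym2(h1), eri)
}

# second-order correlation energy from the FCI oracle: scale the
# two-electron fluctuation by g (keeping the Fock operator fixed) and
# extract the g^2 coefficient of E0(g) - E_ref(g) by Richardson
# extrapolation over two small couplings.
pt2_oracle <- function(h, n_occ, gs = c(1e-3, 2e-3)) {
  occ <- seq_len(n_occ)
  G <- matrix(0, h$n_orb, h$n_orb)
  for (i in occ) G <- G + 2 * h$eri[, , i, i] - h$eri[, i, i, ]
  e2 <- vapply(gs, function(g) {
    hg <- active_space_hamiltonian(h$n_orb, n_occ, n_occ, 0,
                                   sym2(h$h1 + (1 - g) * G), g * h$eri)
    J <- matrix(0, h$n_orb, h$n_orb); K <- J
    for (i in occ) { J <- J + hg$eri[, , i, i]; K <- K + hg$eri[, i, i, ] }
    eref <- 2 * sum(diag(hg$h1)[occ]) + sum((2 * J - K)[cbind(occ, occ)])
    e0 <- min(exact_spectrum(hg, n_occ, n_occ)$energies)
    (e0 - eref) / g^2
  }, numeric(1))
  (gs[2] * e2[1] - gs[1] * e2[2]) / (gs[2] - gs[1])
}

# ---- fixture: ERI tensor planted exactly from known THC factors ----
plant_thc_hamiltonian <- function(n, M, seed) {
  set.seed(seed)
  chi <- matrix(rnorm(n * M), n, M)
  chi <- sweep(chi, 2, sqrt(colSums(chi^2)), "/")
  A <- matrix(rnorm(M * M), M)
  zeta <- crossprod(A) / M
  P <- matrix(0, n * n, M)
  for (mu in seq_len(M)) P[, mu] <- as.vector(tcrossprod(chi[, mu]))
  V <- sym2(P %*% zeta %*% t(P))
  eri <- array(V, rep(n, 4))
  active_space_hamiltonian(n, n %/% 2 + n %% 2, n %/% 2, 0,
                           diag(seq(-1, 1, length.out = n)), eri)
}

frob <- function(x) sqrt(sum(x^2))

# random orthogonal matrix from a seeded QR
random_orthogonal <- function(n, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n)))
}
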