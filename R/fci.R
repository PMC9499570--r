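# Brute-force full configuration interaction over Slater determinants.
#
# Spin orbitals are numbered 1..2N with alpha = 2p-1 and beta = 2p for
# spatial orbital p.  A determinant is the sorted integer vector of its
# occupied spin orbitals; matrix elements follow the Slater-Condon rules
# with phase factors from the positions of the differing spin orbitals in
# the maximally coincident ordering.

so_spatial <- function(so) (so + 1L) %/% 2L
so_spin <- function(so) so %% 2L  # 1 = alpha, 0 = beta

# antisymmetrized two-electron integral <ij||kl> over spin orbitals
# <ij|kl> = (ik|jl) * [s(i)=s(k)] * [s(j)=s(l)]  (chemist (pq|rs) input)
tei_anti <- function(eri, i, j, k, l) {
  d <- 0
  if (so_spin(i) == so_spin(k) && so_spin(j) == so_spin(l))
    d <- d + eri[so_spatial(i), so_spatial(k), so_spatial(j), so_spatial(l)]
  if (so_spin(i) == so_spin(l) && so_spin(j) == so_spin(k))
    d <- d - eri[so_spatial(i), so_spatial(l), so_spatial(j), so_spatial(k)]
  d
}

slater_condon <- function(d1, d2, h1, eri) {
  in2 <- d1 %in% d2
  excl1 <- d1[!in2]
  n_diff <- length(excl1)
  if (n_diff > 2L) return(0)
  excl2 <- d2[!(d2 %in% d1)]
  common <- d1[in2]
  if (n_diff == 0L) {
    e <- sum(h1[cbind(so_spatial(d1), so_spatial(d1))])
    for (a in seq_along(d1)) for (b in seq_along(d1)) {
      if (a < b) e <- e + tei_anti(eri, d1[a], d1[b], d1[a], d1[b])
    }
    return(e)
  }
  sgn <- function(det, orbs) (-1)^sum(match(orbs, det) - 1L)
  if (n_diff == 1L) {
    i <- excl1; a <- excl2
    s <- sgn(d1, i) * sgn(d2, a)
    e <- if (so_spin(i) == so_spin(a)) h1[so_spatial(i), so_spatial(a)] else 0
    for (j in common) e <- e + tei_anti(eri, i, j, a, j)
    return(s * e)
  }
  i <- min(excl1); j <- max(excl1)
  a <- min(excl2); b <- max(excl2)
  s <- sgn(d1, c(i, j)) * sgn(d2, c(a, b))
  s * tei_anti(eri, i, j, a, b)
}

enumerate_determinants <- function(n_orb, n_alpha, n_beta) {
  combs <- function(k, spin_off) {
    if (k == 0L) return(list(integer(0)))
    m <- utils::combn(n_orb, k)
    lapply(seq_len(ncol(m)), function(i) 2L * m[, i] - spin_off)
  }
  alphas <- combs(n_alpha, 1L)
  betas <- combs(n_beta, 0L)
  dets <- vector("list", length(alphas) * length(betas))
  idx <- 1L
  for (a in alphas) for (b in betas) {
    dets[[idx]] <- sort(c(a, b))
    idx <- idx + 1L
  }
  dets
}

#' Exact spectrum of an active-space Hamiltonian in a particle sector
#'
#' Enumerates all Slater determinants with the requested `(n_alpha,
#' n_beta)` occupation, builds the dense Hamiltonian matrix by the
#' Slater-Condon rules, and diagonalizes it.  This is a deliberately
#' simple brute-force oracle for validating factorization norms and
#' perturbative surrogates; it refuses systems with more than 8 spatial
#' orbitals.
#'
#' @param h An `asham` object with `n_orb <= 8`.
#' @param n_alpha,n_beta Electron counts of the sector (defaults: the
#'   counts stored on `h`).
#' @param include_core Add `e_core` to every eigenvalue?  Default
#'   `FALSE`.
#' @return A list of class `fci_spectrum` with elements `sector`
#'   (integer vector `(n_alpha, n_beta)`) and `energies` (ascending
#'   eigenvalues, Hartree).
#' @export
exact_spectrum <- function(h, n_alpha = h$n_alpha, n_beta = h$n_beta,
                           include_core = FALSE) {
  stopifnot(inherits(h, "asham"))
  if (h$n_orb > 8L)
    stop("exact_spectrum is limited to n_orb <= 8 (combinatorial blow-up)")
  if (n_alpha < 0 || n_beta < 0 || n_alpha > h$n_orb || n_beta > h$n_orb)
    stop("invalid particle sector")
  dets <- enumerate_determinants(h$n_orb, n_alpha, n_beta)
  nd <- length(dets)
  H <- matrix(0, nd, nd)
  for (r in seq_len(nd)) {
    for (c in r:nd) {
      v <- slater_condon(dets[[r]], dets[[c]], h$h1, h$eri)
      H[r, c] <- v
      H[c, r] <- v
    }
  }
  vals <- if (nd == 1L) H[1, 1] else
    eigen(H, symmetric = TRUE, only.values = TRUE)$values
  energies <- sort(vals)
  if (include_core) energies <- energies + h$e_core
  structure(list(sector = c(n_alpha = as.integer(n_alpha),
                            n_beta = as.integer(n_beta)),
                 energies = energies),
            class = "fci_spectrum")
}

#' @export
print.fci_spectrum <- function(x, ...) {
  cat(sprintf("FCI spectrum, sector (%d alpha, %d beta): %d states\n",
              x$sector[1], x$sector[2], length(x$energies)))
  cat(sprintf("  E0 = %.10f Ha, Emax = %.10f Ha\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Spectral radius of the (shift-free) Hamiltonian over all sectors
#'
#' Maximum of `max(|E_min|, |E_max|)` over every particle sector, with
#' an optional scalar added to each eigenvalue first (used for the
#' block-encoding shift when checking lambda bounds).
#'
#' @param h An `asham` object (small).
#' @param shift Scalar added to every eigenvalue before taking absolute
#'   values (default 0).
#' @return The spectral radius (Hartree).
#' @export
spectral_radius_all_sectors <- function(h, shift = 0) {
  rad <- 0
  for (na in 0:h$n_orb) for (nb in 0:h$n_orb) {
    e <- exact_spectrum(h, na, nb)$energies + shift
    rad <- max(rad, max(abs(e)))
  }
  rad
}
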