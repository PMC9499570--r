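#' Active-space electronic-structure Hamiltonian
#'
#' Container for an active-space Hamiltonian in the spatial-orbital
#' representation: a scalar core energy, a symmetric one-body integral
#' matrix `h1`, and the two-electron repulsion integral (ERI) tensor in
#' chemist notation `(pq|rs)` with 8-fold permutational symmetry.  All
#' energies are in Hartree.  Orbital indices are 1-based throughout.
#'
#' @param n_orb Number of spatial orbitals N.
#' @param n_alpha,n_beta Electron counts per spin channel.
#' @param e_core Scalar core-energy offset (Hartree).
#' @param h1 Symmetric `N x N` one-body integral matrix (Hartree).
#' @param eri `N x N x N x N` two-electron tensor, chemist notation
#'   `(pq|rs)` (Hartree).
#' @param multiplicity Spin multiplicity 2S+1; defaults to
#'   `n_alpha - n_beta + 1`.
#' @param validate Check the class invariants (symmetries,
#'   positive-semidefiniteness of the `(pq),(rs)` supermatrix)?  Default
#'   `TRUE`.
#'
#' @return An object of class `asham` (a list with the fields above).
#' @export
active_space_hamiltonian <- function(n_orb, n_alpha, n_beta, e_core, h1, eri,
                                     multiplicity = n_alpha - n_beta + 1L,
                                     validate = TRUE) {
  n_orb <- as.integer(n_orb)
  stopifnot(n_orb >= 1L, is.matrix(h1), all(dim(h1) == n_orb),
            length(dim(eri)) == 4L, all(dim(eri) == n_orb))
  if (n_alpha < 0 || n_beta < 0 || n_alpha > n_orb || n_beta > n_orb)
    stop("electron counts must lie in [0, n_orb]")
  h <- structure(list(n_orb = n_orb,
                      n_alpha = as.integer(n_alpha),
                      n_beta = as.integer(n_beta),
                      multiplicity = as.integer(multiplicity),
                      e_core = as.numeric(e_core),
                      h1 = h1, eri = eri),
                 class = "asham")
  if (validate) validate_hamiltonian(h)
  h
}

#' Validate an active-space Hamiltonian
#'
#' Checks the `asham` invariants: `h1` symmetric to 1e-12, the ERI tensor
#' 8-fold permutationally symmetric to 1e-12, and the `N^2 x N^2`
#' supermatrix `V[(pq),(rs)] = (pq|rs)` positive semidefinite
#' (eigenvalues >= -1e-10 relative to its largest eigenvalue scale).
#'
#' @param h An `asham` object.
#' @param tol_sym Symmetry tolerance.
#' @param tol_psd PSD tolerance on eigenvalues.
#' @return `h`, invisibly.  Errors if an invariant fails.
#' @export
validate_hamiltonian <- function(h, tol_sym = 1e-12, tol_psd = 1e-10) {
  stopifnot(inherits(h, "asham"))
  scale1 <- max(1, max(abs(h$h1)))
  if (max(abs(h$h1 - t(h$h1))) > tol_sym * scale1)
    stop("h1 is not symmetric")
  V <- eri_matrix(h$eri)
  scale2 <- max(1, max(abs(V)))
  if (max(abs(V - t(V))) > tol_sym * scale2)
    stop("eri violates (pq|rs) = (rs|pq) symmetry")
  # (pq|rs) = (qp|rs): compare against index-swapped tensor
  e <- h$eri
  if (max(abs(e - aperm(e, c(2, 1, 3, 4)))) > tol_sym * scale2)
    stop("eri violates (pq|rs) = (qp|rs) symmetry")
  if (max(abs(e - aperm(e, c(1, 2, 4, 3)))) > tol_sym * scale2)
    stop("eri violates (pq|rs) = (pq|sr) symmetry")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_psd * max(1, max(abs(ev))))
    stop("ERI supermatrix is not positive semidefinite")
  invisible(h)
}

#' @export
print.asham <- function(x, ...) {
  cat(sprintf("Active-space Hamiltonian: %d orbitals, (%d alpha, %d beta) electrons\n",
              x$n_orb, x$n_alpha, x$n_beta))
  cat(sprintf("  multiplicity 2S+1 = %d, core energy %.8f Ha\n",
              x$multiplicity, x$e_core))
  cat(sprintf("  |h1|_max = %.4g, |(pq|rs)|_max = %.4g Ha\n",
              max(abs(x$h1)), max(abs(x$eri))))
  invisible(x)
}

#' ERI tensor as its N^2 x N^2 supermatrix
#'
#' Reshapes `(pq|rs)` into the symmetric matrix `V` with composite row
#' index `(pq)` and column index `(rs)`.  Column-major composite
#' indexing: row `p + (q-1) N`.
#'
#' @param eri Four-index ERI array.
#' @return An `N^2 x N^2` matrix.
#' @export
eri_matrix <- function(eri) {
  n <- dim(eri)[1]
  dim(eri) <- c(n * n, n * n)
  eri
}

#' @rdname eri_matrix
#' @param V Supermatrix as produced by [eri_matrix()].
#' @export
matrix_eri <- function(V) {
  n <- as.integer(round(sqrt(nrow(V))))
  stopifnot(n * n == nrow(V), nrow(V) == ncol(V))
  dim(V) <- c(n, n, n, n)
  V
}

symmetrize <- function(m) (m + t(m)) / 2

# Evaluate fn() under a temporary seeded RNG state, restoring the caller's.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Generate a synthetic chemistry-like active-space Hamiltonian
#'
#' Builds a seeded random Hamiltonian whose two-electron tensor has the
#' positive-semidefinite low-rank structure of real electron-repulsion
#' integrals: `eri = sum_l L(l) (x) L(l)` with symmetric Cholesky-style
#' vectors `L(l)` whose weights decay exponentially with `l`, emulating
#' the spectral decay of pivoted-Cholesky factors of molecular ERIs.
#' The one-body matrix is a ladder of orbital energies spanning
#' `[-2, 2]` Hartree plus weak symmetric random coupling, so that
#' closed-shell references built on the leading orbitals generically have
#' a positive HOMO-LUMO gap.
#'
#' @param n_orb Number of spatial orbitals (>= 1).
#' @param cholesky_rank Number of rank-one symmetric factors (>= 1).
#' @param seed Integer seed; the same seed reproduces the Hamiltonian
#'   exactly.
#' @param n_alpha,n_beta Electron counts stored on the result (default:
#'   half filling, alpha gets the remainder).
#' @param e_core Core energy (default 0).
#' @param decay Exponential decay rate of the Cholesky-vector weights
#'   (default 0.25 per vector).
#' @param coupling Standard deviation of the off-diagonal one-body
#'   coupling (default 0.05 Hartree).
#'
#' @return An `asham` object satisfying all class invariants by
#'   construction.
#' @export
synthesize_hamiltonian <- function(n_orb, cholesky_rank, seed,
                                   n_alpha = NULL, n_beta = NULL,
                                   e_core = 0,
                                   decay = 0.25, coupling = 0.05) {
  n_orb <- as.integer(n_orb)
  cholesky_rank <- as.integer(cholesky_rank)
  if (n_orb < 1L) stop("n_orb must be >= 1")
  if (cholesky_rank < 1L) stop("cholesky_rank must be >= 1")
  if (is.null(n_beta)) n_beta <- n_orb %/% 2L
  if (is.null(n_alpha)) n_alpha <- n_orb - n_orb %/% 2L

  with_seed(seed, function() {
    diagv <- if (n_orb == 1L) 0 else seq(-2, 2, length.out = n_orb)
    h1 <- diag(diagv, n_orb) +
      symmetrize(matrix(stats::rnorm(n_orb^2, sd = coupling), n_orb))
    eri <- array(0, rep(n_orb, 4))
    vecs <- vector("list", cholesky_rank)
    for (l in seq_len(cholesky_rank)) {
      L <- exp(-decay * (l - 1)) *
        symmetrize(matrix(stats::rnorm(n_orb^2, sd = 1 / n_orb), n_orb))
      vecs[[l]] <- L
      eri <- eri + outer(L, L)
    }
    active_space_hamiltonian(n_orb, n_alpha, n_beta, e_core, h1, eri,
                             validate = FALSE)
  })
}

#' Rotate one- and two-body integrals by an orbital transformation
#'
#' Applies `h1 -> U' h1 U` and the corresponding four-index
#' transformation of the ERI tensor.  `U` need not be orthogonal, but
#' spectra are preserved only when it is.
#'
#' @param h An `asham` object.
#' @param U `N x N` transformation matrix (columns are new orbitals).
#' @return A new `asham` with rotated integrals.
#' @export
rotate_integrals <- function(h, U) {
  stopifnot(inherits(h, "asham"), all(dim(U) == h$n_orb))
  n <- h$n_orb
  h1r <- t(U) %*% h$h1 %*% U
  # (pq|rs) -> sum over all four indices; do it one mode at a time
  e <- h$eri
  for (mode in 1:4) {
    e <- apply_mode(e, U, mode, n)
  }
  active_space_hamiltonian(h$n_orb, h$n_alpha, h$n_beta, h$e_core,
                           symmetrize(h1r), e, h$multiplicity,
                           validate = FALSE)
}

# contract U into one mode of a 4-index tensor: out[..i..] = sum_j U[j,i] e[..j..]
apply_mode <- function(e, U, mode, n) {
  perm <- c(mode, setdiff(1:4, mode))
  ep <- aperm(e, perm)
  dim(ep) <- c(n, n^3)
  ep <- t(U) %*% ep
  dim(ep) <- rep(n, 4)
  aperm(ep, order(perm))
}
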