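#' Single factorization (Cholesky-style) of the two-electron tensor
#'
#' Decomposes the ERI supermatrix `V[(pq),(rs)]` by symmetric
#' eigendecomposition into `eri = sum_l L(l) (x) L(l)` with symmetric
#' `N x N` vectors `L(l) = sqrt(w_l) reshape(v_l)`, ordered by decreasing
#' eigenvalue weight.  The retained set is either the minimal prefix
#' whose Frobenius truncation error meets `tol`, or exactly `n_vectors`.
#' A pivoted-Cholesky route is available behind `method = "cholesky"`;
#' the eigendecomposition is the default for its deterministic ordering.
#'
#' @param h An `asham` object.
#' @param tol Frobenius reconstruction-error threshold (give exactly one
#'   of `tol` / `n_vectors`).  `tol = 0` keeps every numerically nonzero
#'   eigenvalue (exact reconstruction).
#' @param n_vectors Number of vectors to retain.
#' @param psd_tol Relative tolerance on negative eigenvalues of `V`
#'   before the tensor is declared non-PSD.
#' @param method `"eigen"` (default) or `"cholesky"` (pivoted Cholesky).
#' @return An object of class `sf_factorization`: list with `vectors`
#'   (list of symmetric matrices), `n_vectors`, `weights` (retained
#'   eigenvalues for the eigen route), `n_orb`, `method`.
#' @export
single_factorize <- function(h, tol = NULL, n_vectors = NULL,
                             psd_tol = 1e-10, method = c("eigen", "cholesky")) {
  stopifnot(inherits(h, "asham"))
  method <- match.arg(method)
  if (is.null(tol) == is.null(n_vectors))
    stop("give exactly one of tol / n_vectors")
  n <- h$n_orb
  V <- eri_matrix(h$eri)

  if (method == "cholesky") {
    ch <- suppressWarnings(chol(V, pivot = TRUE))
    rank <- attr(ch, "rank")
    piv <- attr(ch, "pivot")
    Lfull <- matrix(0, n * n, rank)
    Lfull[piv, ] <- t(ch[seq_len(rank), , drop = FALSE])
    w <- colSums(Lfull^2)
    vecs_all <- lapply(seq_len(rank), function(l)
      symmetrize(matrix(Lfull[, l], n, n)))
    weights <- w
  } else {
    ed <- eigen(V, symmetric = TRUE)
    ev <- ed$values
    if (min(ev) < -psd_tol * max(1, max(abs(ev))))
      stop("ERI supermatrix is not positive semidefinite")
    keep <- which(ev > 1e-14 * max(abs(ev), .Machine$double.eps))
    weights <- ev[keep]
    vecs_all <- lapply(keep, function(l)
      symmetrize(sqrt(ev[l]) * matrix(ed$vectors[, l], n, n)))
  }
  rank <- length(vecs_all)
  if (!is.null(n_vectors)) {
    nv <- min(as.integer(n_vectors), rank)
  } else {
    # Frobenius error of dropping tail l > nv is sqrt(sum of squared tail weights)
    tail_err <- sqrt(rev(cumsum(rev(weights^2))))
    tail_err <- c(tail_err[-1], 0)  # error after keeping 1..l
    nv <- if (tol <= 0) rank else min(which(tail_err <= tol))
  }
  structure(list(vectors = vecs_all[seq_len(nv)],
                 n_vectors = nv,
                 weights = weights[seq_len(nv)],
                 n_orb = n, method = method),
            class = "sf_factorization")
}

#' Double factorization: eigendecomposed Cholesky leaves
#'
#' Eigendecomposes each single-factorization vector `L(l)` and drops
#' eigenpairs with `|f| < leaf_tol`, recording the per-leaf second ranks
#' `Xi_l` and their mean `Xi`.
#'
#' @param sf An `sf_factorization`.
#' @param leaf_tol Absolute eigenvalue threshold (default 0: keep all).
#' @return An object of class `df_factorization`: `leaves` (list of
#'   `list(f = eigenvalues, U = eigenvector matrix columns)`),
#'   `leaf_ranks`, `avg_rank`, `n_orb`.
#' @export
double_factorize <- function(sf, leaf_tol = 0) {
  stopifnot(inherits(sf, "sf_factorization"))
  leaves <- lapply(sf$vectors, function(L) {
    ed <- eigen(symmetrize(L), symmetric = TRUE)
    keep <- which(abs(ed$values) >= leaf_tol & ed$values != 0)
    if (leaf_tol <= 0) keep <- seq_along(ed$values)
    list(f = ed$values[keep],
         U = ed$vectors[, keep, drop = FALSE])
  })
  leaf_ranks <- vapply(leaves, function(lf) length(lf$f), integer(1))
  structure(list(leaves = leaves,
                 leaf_ranks = leaf_ranks,
                 avg_rank = mean(leaf_ranks),
                 n_orb = sf$n_orb),
            class = "df_factorization")
}

#' Reconstruct the ERI tensor from a factorization
#'
#' Inverse of the compression: SF sums `L(l) (x) L(l)`, DF re-expands the
#' truncated leaves first, THC contracts `(pq|rs) = sum_{mu,nu}
#' chi_p,mu chi_q,mu zeta_mu,nu chi_r,nu chi_s,nu`.  The output always
#' satisfies the 8-fold permutational symmetry.
#'
#' @param f An `sf_factorization`, `df_factorization`, or
#'   `thc_factorization`.
#' @return A four-index ERI array.
#' @export
reconstruct_eri <- function(f) {
  if (inherits(f, "sf_factorization")) {
    n <- f$n_orb
    out <- array(0, rep(n, 4))
    for (L in f$vectors) out <- out + outer(L, L)
    return(out)
  }
  if (inherits(f, "df_factorization")) {
    n <- f$n_orb
    out <- array(0, rep(n, 4))
    for (lf in f$leaves) {
      L <- lf$U %*% (lf$f * t(lf$U))
      L <- symmetrize(L)
      out <- out + outer(L, L)
    }
    return(out)
  }
  if (inherits(f, "thc_factorization")) {
    P <- khatri_rao_sym(f$chi)            # N^2 x M, rows (pq)
    V <- P %*% f$zeta %*% t(P)
    return(matrix_eri(symmetrize(V)))
  }
  stop("unknown factorization type")
}

# columnwise symmetric Khatri-Rao: P[(p,q), mu] = chi[p,mu] * chi[q,mu]
khatri_rao_sym <- function(chi) {
  n <- nrow(chi); m <- ncol(chi)
  P <- matrix(0, n * n, m)
  for (mu in seq_len(m)) P[, mu] <- as.vector(tcrossprod(chi[, mu]))
  P
}

#' Qubitization L1 norm (lambda) of a factorized Hamiltonian
#'
#' Computes the one- and two-body contributions to the qubitization
#' normalization `lambda`, the L1 norm of the Hamiltonian coefficients
#' in the factorized representation.  The one-body part uses the
#' effective matrix `T'_pq = h1_pq - (1/2) sum_r (pr|rq) + sum_r (pq|rr)`
#' (the shifted-number-operator convention of qubitized walk
#' constructions), diagonalized before taking the L1 norm of its
#' eigenvalues.  Two-body conventions: SF `(1/4) sum_l (sum_pq
#' |L(l)_pq|)^2`; DF `(1/4) sum_l (sum_m |f(l,m)|)^2`; THC `(1/2)
#' sum_{mu,nu} |zeta_mu,nu|` with unit-norm `chi` columns (the scale is
#' absorbed into `zeta` first).
#'
#' @param h The `asham` the factorization was built from.
#' @param f An `sf_factorization`, `df_factorization`, or
#'   `thc_factorization` (dimensions must match `h`).
#' @return A list of class `lambda_report`: `lambda_total`,
#'   `lambda_one_body`, `lambda_two_body`, `method`.
#' @export
lambda_norm <- function(h, f) {
  stopifnot(inherits(h, "asham"))
  n <- h$n_orb
  nf <- if (inherits(f, "df_factorization") || inherits(f, "sf_factorization") ||
            inherits(f, "thc_factorization")) f$n_orb else
    stop("unknown factorization type")
  if (nf != n) stop("factorization dimension does not match Hamiltonian")
  Tp <- effective_one_body(h)
  lambda_1 <- sum(abs(eigen(Tp, symmetric = TRUE, only.values = TRUE)$values))
  if (inherits(f, "sf_factorization")) {
    lambda_2 <- 0.25 * sum(vapply(f$vectors,
                                  function(L) sum(abs(L))^2, numeric(1)))
    method <- "SF"
  } else if (inherits(f, "df_factorization")) {
    lambda_2 <- 0.25 * sum(vapply(f$leaves,
                                  function(lf) sum(abs(lf$f))^2, numeric(1)))
    method <- "DF"
  } else {
    nrm <- normalize_thc(f)
    lambda_2 <- 0.5 * sum(abs(nrm$zeta))
    method <- "THC"
  }
  structure(list(lambda_total = lambda_1 + lambda_2,
                 lambda_one_body = lambda_1,
                 lambda_two_body = lambda_2,
                 method = method),
            class = "lambda_report")
}

#' @export
print.lambda_report <- function(x, ...) {
  cat(sprintf("lambda (%s): total %.6f = one-body %.6f + two-body %.6f Ha\n",
              x$method, x$lambda_total, x$lambda_one_body, x$lambda_two_body))
  invisible(x)
}

#' Effective one-body matrix entering the qubitization one-body lambda
#'
#' `T'_pq = h1_pq - (1/2) sum_r (pr|rq) + sum_r (pq|rr)`.
#'
#' @param h An `asham` object.
#' @return A symmetric `N x N` matrix.
#' @export
effective_one_body <- function(h) {
  n <- h$n_orb
  exch <- matrix(0, n, n)
  coul <- matrix(0, n, n)
  for (r in seq_len(n)) {
    exch <- exch + h$eri[, r, r, ]
    coul <- coul + h$eri[, , r, r]
  }
  symmetrize(h$h1 - 0.5 * exch + coul)
}

#' Scalar identity shift of the block-encoded Hamiltonian
#'
#' Under the shifted-number-operator rearrangement used for
#' [lambda_norm()] (spin-summed excitation operators shifted by their
#' half-filling expectation), the operator actually block-encoded equals
#' the bare one- plus two-body Hamiltonian plus
#' `(1/2) sum_pr (pp|rr) - tr(T')` times the identity.  Tests of the
#' spectral bound `lambda >= ||H_encoded||` must add this shift to the
#' bare FCI eigenvalues.
#'
#' @param h An `asham` object.
#' @return The scalar shift (Hartree).
#' @export
encoding_shift <- function(h) {
  n <- h$n_orb
  s <- 0
  for (p in seq_len(n)) for (r in seq_len(n)) s <- s + h$eri[p, p, r, r]
  0.5 * s - sum(diag(effective_one_body(h)))
}

#' Scalar shift between the bare Hamiltonian and the block-encoded one
#'
#' For SF and DF the squared one-body factors entering the two-body
#' part are positive operators; the walk construction encodes each
#' `W_l^2` recentred by half its coefficient bound, which subtracts
#' exactly `lambda_two_body` from the encoded operator.  THC encodes
#' products of distinct unit-norm factors and carries no such
#' recentring.  The returned scalar `c` satisfies
#' `H_encoded = H + c * I`, so `lambda_total >= max |E + c|` over the
#' FCI spectrum `E` of the bare Hamiltonian -- the bound the tests
#' assert.
#'
#' @param h An `asham` object.
#' @param f The factorization whose lambda convention is being checked.
#' @return The scalar shift `c` (Hartree).
#' @export
encoded_operator_shift <- function(h, f) {
  lam <- lambda_norm(h, f)
  base <- encoding_shift(h)
  if (lam$method %in% c("SF", "DF")) base - lam$lambda_two_body else base
}
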