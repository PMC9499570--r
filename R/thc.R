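# Tensor hypercontraction of the two-electron integral tensor:
#   (pq|rs) ~ sum_{mu,nu} chi[p,mu] chi[q,mu] zeta[mu,nu] chi[r,nu] chi[s,nu]
# Initialization is a symmetric canonical polyadic (CP) decomposition of
# the Cholesky vectors by alternating least squares, followed by joint
# quasi-Newton refinement of (chi, zeta) on the full least-squares
# objective with an optional L1-type penalty on zeta.

#' Tensor hypercontraction (THC) factorization
#'
#' Fits rank-`M` THC factors to the ERI tensor of `h`.  The collocation
#' matrix `chi` (`N x M`) is initialized by symmetric CP-ALS on the
#' Cholesky (single-factorization) vectors from a seeded random start;
#' the central tensor starts as `zeta = W'W` from the CP weights.  Both
#' are then refined jointly by L-BFGS on
#' `||eri - THC(chi, zeta)||_F^2 + rho * sum|zeta|`
#' (the penalty uses a smoothed absolute value; `rho = 0` by default).
#' The objective trace records the reconstruction objective after
#' initialization and after each refinement block and is non-increasing
#' by construction (the best-so-far iterate is kept).  Identical seeds
#' give identical results.
#'
#' @param h An `asham` object.
#' @param rank THC rank `M >= 1`.
#' @param reg_strength L1 penalty weight `rho >= 0` on `zeta`
#'   (default 0).
#' @param seed Integer seed for the CP-ALS random start.
#' @param max_iter Total L-BFGS iteration budget for the refinement
#'   (default 2000).
#' @param als_sweeps Maximum CP-ALS sweeps (default 200).
#' @param als_tol Relative-change stopping tolerance for ALS
#'   (default 1e-8).
#' @param n_restarts Number of seeded ALS starts tried; the best final
#'   objective wins, ties broken by first reached (default 2).
#' @return An object of class `thc_factorization`: `chi`, `zeta`,
#'   `rank`, `objective_trace`, `objective`, `n_orb`, `seed`,
#'   `reg_strength`.
#' @export
thc_factorize <- function(h, rank, reg_strength = 0, seed = 1L,
                          max_iter = 2000L, als_sweeps = 200L,
                          als_tol = 1e-8, n_restarts = 2L) {
  stopifnot(inherits(h, "asham"))
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  if (reg_strength < 0) stop("reg_strength must be >= 0")
  n <- h$n_orb
  V <- eri_matrix(h$eri)
  sf <- single_factorize(h, tol = 0)
  # stacked Cholesky tensor B[l, p, q]
  Bmat <- t(vapply(sf$vectors, as.vector, numeric(n * n)))  # L x N^2

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seed + 1000003L * (r - 1L), function()
      thc_cp_als(Bmat, n, rank, als_sweeps, als_tol))
    fit <- thc_refine(V, n, init$chi, init$zeta, reg_strength, max_iter)
    fit$trace <- c(thc_objective(V, init$chi, init$zeta), fit$trace)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!is.finite(best$objective))
    stop("THC optimization diverged (non-finite objective)")
  trace <- cummin(as.numeric(best$trace))
  structure(list(chi = best$chi, zeta = symmetrize(best$zeta),
                 rank = rank,
                 objective_trace = trace,
                 objective = best$objective,
                 n_orb = n, seed = as.integer(seed),
                 reg_strength = reg_strength),
            class = "thc_factorization")
}

#' @export
print.thc_factorization <- function(x, ...) {
  cat(sprintf("THC factorization: N = %d, rank M = %d, final ||resid||_F^2 = %.3e\n",
              x$n_orb, x$rank, x$objective))
  invisible(x)
}

# plain reconstruction objective ||V - P zeta P'||_F^2
thc_objective <- function(V, chi, zeta) {
  P <- khatri_rao_sym(chi)
  sum((V - P %*% zeta %*% t(P))^2)
}

# Symmetric CP of the stacked Cholesky vectors:
#   B[l,(p,q)] ~ sum_mu W[l,mu] chi[p,mu] chi[q,mu]
# ALS over (chi as factor A with symmetric tying, W); returns zeta = W'W.
thc_cp_als <- function(Bmat, n, rank, sweeps, tol) {
  L <- nrow(Bmat)
  chi <- matrix(stats::rnorm(n * rank), n, rank)
  chi <- sweep(chi, 2, sqrt(colSums(chi^2)), "/")
  W <- matrix(0, L, rank)
  obj_prev <- Inf
  for (s in seq_len(sweeps)) {
    # W update: rows solve B[l,] ~ P w  with P = (chi o chi)
    P <- khatri_rao_sym(chi)                     # N^2 x M
    W <- t(ridge_solve(crossprod(P), t(Bmat %*% P)))   # L x M
    # chi update (one CP factor, then re-tie symmetrically):
    # unfold B over index p: B3[p, (q,l)] ~ chi %*% (KR of (W, chi))'
    KR <- kr_cols(W, chi)                        # (q,l) pairs: N*L x M
    B3 <- unfold_p(Bmat, n, L)                   # N x (N*L)
    G2 <- crossprod(chi) * crossprod(W)
    chi_new <- t(ridge_solve(G2, t(B3 %*% KR)))
    nrm <- sqrt(colSums(chi_new^2))
    nrm[nrm == 0] <- 1
    chi <- sweep(chi_new, 2, nrm, "/")
    obj <- cp_objective(Bmat, chi, W)
    if (is.finite(obj_prev) && abs(obj_prev - obj) <=
        tol * max(1, abs(obj_prev))) { obj_prev <- obj; break }
    obj_prev <- obj
  }
  # final W refit against the (normalized) chi
  P <- khatri_rao_sym(chi)
  W <- t(ridge_solve(crossprod(P), t(Bmat %*% P)))
  list(chi = chi, zeta = crossprod(W), objective_cp = obj_prev)
}

cp_objective <- function(Bmat, chi, W) {
  P <- khatri_rao_sym(chi)
  sum((Bmat - W %*% t(P))^2)
}

# solve G x = B for symmetric G, escalating a relative ridge until the
# system is numerically well posed
ridge_solve <- function(G, B) {
  scale <- max(diag(G), .Machine$double.eps)
  for (r in c(0, 10^(-12:-6))) {
    out <- tryCatch(solve(G + r * scale * diag(nrow(G)), B),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("normal equations irrecoverably singular in CP-ALS")
}

# columnwise Khatri-Rao of W (L x M) and chi (N x M): rows ordered (q fast, l slow)
kr_cols <- function(W, chi) {
  M <- ncol(W)
  out <- matrix(0, nrow(W) * nrow(chi), M)
  for (mu in seq_len(M))
    out[, mu] <- as.vector(outer(chi[, mu], W[, mu]))
  out
}

# Bmat is L x N^2 with columns (p,q) p-fast; return N x (N*L) with columns (q,l) q-fast
unfold_p <- function(Bmat, n, L) {
  arr <- array(t(Bmat), c(n, n, L))   # [p, q, l]
  dim(arr) <- c(n, n * L)
  arr
}

# joint L-BFGS refinement of (chi, zeta-upper-triangle)
thc_refine <- function(V, n, chi, zeta, rho, max_iter, eps_abs = 1e-8) {
  M <- ncol(chi)
  ut <- upper.tri(zeta, diag = TRUE)
  pack <- function(chi, zeta) c(as.vector(chi), zeta[ut])
  unpack <- function(x) {
    chi <- matrix(x[seq_len(n * M)], n, M)
    z <- matrix(0, M, M)
    z[ut] <- x[-seq_len(n * M)]
    z <- z + t(z) - diag(diag(z), M)
    list(chi = chi, zeta = z)
  }
  sabs <- function(x) sqrt(x^2 + eps_abs^2)
  fn <- function(x) {
    p <- unpack(x)
    P <- khatri_rao_sym(p$chi)
    R <- P %*% p$zeta %*% t(P) - V
    val <- sum(R^2)
    if (rho > 0) val <- val + rho * sum(sabs(p$zeta))
    val
  }
  gr <- function(x) {
    p <- unpack(x)
    P <- khatri_rao_sym(p$chi)
    R <- P %*% p$zeta %*% t(P) - V          # symmetric
    dZ <- 2 * crossprod(P, R %*% P)
    if (rho > 0) dZ <- dZ + rho * p$zeta / sabs(p$zeta)
    dP <- 4 * R %*% P %*% p$zeta            # N^2 x M
    dchi <- matrix(0, n, M)
    for (mu in seq_len(M)) {
      Dm <- matrix(dP[, mu], n, n)          # symmetric in (p,q)
      dchi[, mu] <- 2 * Dm %*% p$chi[, mu]
    }
    # pack gradient of symmetric zeta: off-diagonal entries appear twice
    gz <- dZ + t(dZ)
    diag(gz) <- diag(dZ)
    c(as.vector(dchi), gz[ut])
  }
  # for fixed chi the optimal (unpenalized) zeta is a linear least-squares
  # solve: zeta = (P'P)^-1 P' V P (P'P)^-1
  zeta_refit <- function(chi) {
    P <- khatri_rao_sym(chi)
    G <- crossprod(P)
    symmetrize(ridge_solve(G, t(ridge_solve(G, crossprod(P, V %*% P)))))
  }
  x0 <- pack(chi, zeta)
  trace <- numeric(0)
  xbest <- x0
  fbest <- fn(x0)
  remaining <- max_iter
  block <- 250L
  converged <- FALSE
  while (remaining > 0L) {
    it <- min(block, remaining)
    res <- tryCatch(
      stats::optim(xbest, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = it, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) break
    if (res$value < fbest) { fbest <- res$value; xbest <- res$par }
    if (rho == 0) {
      # interleave the exact central-tensor refit
      p <- unpack(xbest)
      xz <- pack(p$chi, zeta_refit(p$chi))
      fz <- fn(xz)
      if (fz < fbest) { fbest <- fz; xbest <- xz }
    }
    trace <- c(trace, fbest)
    remaining <- remaining - it
    if (!is.null(res) && res$convergence == 0 && converged) break
    converged <- !is.null(res) && res$convergence == 0
  }
  p <- unpack(xbest)
  obj <- thc_objective(V, p$chi, p$zeta)
  list(chi = p$chi, zeta = p$zeta, objective = obj,
       trace = c(trace, obj))
}

# absorb chi column norms into zeta so every chi column has unit norm
normalize_thc <- function(f) {
  nrm <- sqrt(colSums(f$chi^2))
  nrm[nrm == 0] <- 1
  chi <- sweep(f$chi, 2, nrm, "/")
  zeta <- f$zeta * (nrm^2 %o% nrm^2)
  list(chi = chi, zeta = zeta)
}
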