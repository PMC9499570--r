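# Logical-resource estimation for phase estimation with qubitized
# quantum walk operators.  Per-step Toffoli and logical-qubit costs are
# an itemized model of the standard walk-operator construction:
# QROM coefficient lookups with the ceil(G/2^k) + b (2^k - 1)
# lookup/uncompute trade-off, alias-sampling state preparation,
# controlled register swaps, programmed Givens basis rotations (DF/THC),
# and the qubitization reflection.

#' Phase-estimation iteration count
#'
#' Number of applications of the qubitized walk operator needed to
#' resolve an eigenphase of the walk operator (eigenvalues
#' `exp(+/- i arccos(E / lambda))`) to energy error `eps_pea`:
#' `ceiling(pi * lambda / (2 * eps_pea))`.
#'
#' @param lambda_val Qubitization norm lambda (Hartree, > 0).
#' @param eps_pea Phase-estimation energy budget (Hartree, > 0).
#' @return Integer-valued iteration count (as numeric to allow counts
#'   beyond 2^31).
#' @export
pe_iterations <- function(lambda_val, eps_pea) {
  if (!is.finite(lambda_val) || lambda_val <= 0)
    stop("lambda_val must be positive")
  if (!is.finite(eps_pea) || eps_pea <= 0) stop("eps_pea must be positive")
  max(1, ceiling(pi * lambda_val / (2 * eps_pea)))
}

#' Precision budget for qubitized phase estimation
#'
#' The total error is additive between the phase-estimation resolution,
#' coefficient rounding in the QROM oracles, and the integral-truncation
#' error of the factorization; this record carries the split.
#'
#' @param eps_pea Phase-estimation share (Hartree), default 1e-3.
#' @param eps_qrom Coefficient-rounding share, default 1e-4.
#' @param eps_trunc Integral-truncation share (governed by the 1 mHa
#'   rank-selection criterion), default 1e-3.
#' @param eps_total Total budget; default the sum of the shares.
#' @return A list of class `precision_budget`.
#' @export
precision_budget <- function(eps_pea = 1e-3, eps_qrom = 1e-4,
                             eps_trunc = 1e-3,
                             eps_total = eps_pea + eps_qrom + eps_trunc) {
  stopifnot(eps_pea > 0, eps_qrom > 0, eps_trunc > 0)
  if (eps_pea + eps_qrom + eps_trunc > eps_total * (1 + 1e-12))
    stop("error shares exceed eps_total")
  structure(list(eps_total = eps_total, eps_pea = eps_pea,
                 eps_qrom = eps_qrom, eps_trunc = eps_trunc),
            class = "precision_budget")
}

#' Default QROM bit widths
#'
#' `b_coeff`: bits of the alias-sampling keep probability (coefficient
#' rounding); `b_rot`: bits per programmed rotation angle.  Recorded in
#' every [logical_resources] output.
#' @export
default_bit_params <- function() list(b_coeff = 10L, b_rot = 20L)

# minimal Toffoli cost of a QROM lookup of n_items entries of b output
# bits, using the select-swap trade-off ceil(n/2^k) + b (2^k - 1)
qrom_lookup <- function(n_items, b) {
  stopifnot(n_items >= 1, b >= 1)
  kmax <- max(0L, ceiling(log2(n_items)))
  ks <- 0:kmax
  cost <- ceiling(n_items / 2^ks) + b * (2^ks - 1)
  k <- ks[which.min(cost)]
  list(toffolis = min(cost), k = k, ancilla = b * 2^k)
}

# uncomputation of a QROM lookup: output bits measured out, phase fixup
# lookup of one bit; trade-off ceil(n/2^k) + 2^k
qrom_unlookup <- function(n_items) {
  kmax <- max(0L, ceiling(log2(n_items)))
  ks <- 0:kmax
  cost <- ceiling(n_items / 2^ks) + 2^ks
  min(cost)
}

#' Per-step walk-operator cost
#'
#' Itemized Toffoli and logical-qubit cost of one application of the
#' qubitized walk operator for a given factorization method.  The
#' coefficient count Gamma is `L N(N+1)/2` for SF (unique `(pq)` pairs
#' per Cholesky vector), `sum_l Xi_l` coefficients plus `sum_l Xi_l * N`
#' rotation angles for DF, and `M(M+1)/2` central-tensor entries plus
#' `N * M` collocation angles for THC.
#'
#' @param method `"SF"`, `"DF"`, or `"THC"`.
#' @param n_orb Spatial orbital count N.
#' @param rank_params For SF, `list(L = <vector count>)`; for DF,
#'   `list(leaf_ranks = <integer vector Xi_l>)`; for THC,
#'   `list(M = <THC rank>)`.
#' @param bit_params List with `b_coeff`, `b_rot` (see
#'   [default_bit_params()]).
#' @return A list with `toffoli_per_step`, `logical_qubits`,
#'   `components` (named itemization), `gamma` (stored coefficient
#'   count).
#' @export
walk_step_cost <- function(method = c("SF", "DF", "THC"), n_orb, rank_params,
                           bit_params = default_bit_params()) {
  method <- match.arg(method)
  n <- as.integer(n_orb)
  b_c <- as.integer(bit_params$b_coeff)
  b_r <- as.integer(bit_params$b_rot)
  if (b_c < 1L || b_r < 1L) stop("bit widths must be >= 1")

  ok <- switch(method,
    SF = !is.null(rank_params$L) && length(rank_params$L) == 1L &&
      rank_params$L >= 1,
    DF = !is.null(rank_params$leaf_ranks) &&
      length(rank_params$leaf_ranks) >= 1L &&
      all(rank_params$leaf_ranks >= 0) && sum(rank_params$leaf_ranks) >= 1,
    THC = !is.null(rank_params$M) && length(rank_params$M) == 1L &&
      rank_params$M >= 1)
  if (!isTRUE(ok)) stop("rank_params inconsistent with method")
  gamma_coeff <- switch(method,
    SF = rank_params$L * n * (n + 1) / 2,
    DF = sum(rank_params$leaf_ranks),
    THC = rank_params$M * (rank_params$M + 1) / 2)
  idx_bits <- max(1L, ceiling(log2(gamma_coeff)))
  # alias sampling output: keep probability + alt index + sign bit
  b_out <- b_c + idx_bits + 1L

  lk <- qrom_lookup(gamma_coeff, b_out)
  prep <- lk$toffolis + b_c + idx_bits + 3L * idx_bits
  unprep <- qrom_unlookup(gamma_coeff) + b_c + idx_bits

  swaps <- 4L * ceiling(n / 2)

  rot <- 0; rot_anc <- 0; gamma_rot <- 0
  if (method == "DF") {
    gamma_rot <- sum(rank_params$leaf_ranks) * n
    rlk <- qrom_lookup(sum(rank_params$leaf_ranks), n * b_r)
    rot <- 2 * (rlk$toffolis + 2 * n * (b_r - 2)) + 2 * qrom_unlookup(sum(rank_params$leaf_ranks))
    rot_anc <- rlk$ancilla
  } else if (method == "THC") {
    gamma_rot <- rank_params$M * n
    rlk <- qrom_lookup(rank_params$M, n * b_r)
    rot <- 2 * (rlk$toffolis + 2 * n * (b_r - 2)) + 2 * qrom_unlookup(rank_params$M)
    rot_anc <- rlk$ancilla
  }

  reflect <- idx_bits + 1L

  toffoli <- ceiling(prep + unprep + swaps + rot + reflect)
  qubits <- ceiling(
    2 * n +                # system register (spin orbitals)
    2 * idx_bits + b_c +   # index + alt-index + keep registers
    max(lk$ancilla, rot_anc) +   # dominant QROM workspace (reused)
    (if (method == "SF") 0 else n * b_r) +  # rotation-angle data register
    b_r +                  # phase-gradient resource
    2)                     # qubitization control/flag
  list(toffoli_per_step = toffoli,
       logical_qubits = qubits,
       components = list(prepare = prep, unprepare = unprep,
                         swaps = swaps, rotations = rot,
                         reflection = reflect),
       gamma = gamma_coeff + gamma_rot)
}

#' Logical resources for one (Hamiltonian, factorization, budget) triple
#'
#' Composes [lambda_norm()], [pe_iterations()], and [walk_step_cost()].
#'
#' @param h An `asham` object.
#' @param f A factorization of `h`.
#' @param budget A [precision_budget()].
#' @param bit_params See [default_bit_params()].
#' @return A list of class `logical_resources`: `method`, `lambda_val`,
#'   `iterations`, `toffoli_per_step`, `toffoli_total`,
#'   `logical_qubits`, `bit_params`, `gamma`, `components`, `budget`.
#' @export
estimate_resources <- function(h, f, budget = precision_budget(),
                               bit_params = default_bit_params()) {
  lam <- lambda_norm(h, f)
  rank_params <- if (inherits(f, "sf_factorization")) list(L = f$n_vectors)
    else if (inherits(f, "df_factorization")) list(leaf_ranks = f$leaf_ranks)
    else list(M = f$rank)
  step <- walk_step_cost(lam$method, h$n_orb, rank_params, bit_params)
  iters <- pe_iterations(lam$lambda_total, budget$eps_pea)
  structure(list(method = lam$method,
                 lambda_val = lam$lambda_total,
                 iterations = iters,
                 toffoli_per_step = step$toffoli_per_step,
                 toffoli_total = iters * step$toffoli_per_step,
                 logical_qubits = step$logical_qubits,
                 bit_params = bit_params,
                 gamma = step$gamma,
                 components = step$components,
                 budget = budget),
            class = "logical_resources")
}

#' @export
print.logical_resources <- function(x, ...) {
  cat(sprintf("Logical resources (%s): lambda %.4f Ha, %s iterations\n",
              x$method, x$lambda_val, format(x$iterations, big.mark = ",")),
      sprintf("  %s Toffolis (%s per step), %d logical qubits\n",
              format(x$toffoli_total, big.mark = ","),
              format(x$toffoli_per_step, big.mark = ","), x$logical_qubits))
  invisible(x)
}

#' Power-law fit on a log-log scale
#'
#' Ordinary least squares of `log(value)` on `log(N)`:
#' `value ~ prefactor * N^exponent`.
#'
#' @param points Data frame or matrix with columns `(N, value)`, both
#'   positive; at least two distinct abscissae.
#' @return A list of class `scaling_fit`: `exponent`, `prefactor`,
#'   `r_squared`, `points`.
#' @export
fit_scaling <- function(points) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("N", "value")
  if (any(pts$N <= 0) || any(pts$value <= 0))
    stop("fit_scaling needs positive abscissae and values")
  if (length(unique(pts$N)) < 2L)
    stop("fit_scaling needs at least two distinct abscissae")
  fit <- stats::lm(log(value) ~ log(N), data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(pts$value) - mean(log(pts$value)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 prefactor = unname(exp(stats::coef(fit)[1])),
                 r_squared = max(0, min(1, r2)),
                 points = pts),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: value ~ %.4g * N^%.4f (R^2 = %.4f, %d points)\n",
              x$prefactor, x$exponent, x$r_squared, nrow(x$points)))
  invisible(x)
}
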