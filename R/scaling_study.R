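#' Toffoli and logical-qubit scaling study across system sizes
#'
#' Runs the full lambda + logical-resource estimate for SF, DF, and THC
#' on a family of synthetic Hamiltonians of increasing orbital count at
#' fixed filling, and fits the empirical power laws of total Toffoli
#' count and logical qubit count versus N on the log-log scale.  Study
#' conditions: Cholesky rank `5 N` (a realistic Cholesky-to-orbital
#' ratio for molecular integrals), THC rank `M = round(4.7 N)` (the
#' generic rank-per-orbital multiplier), and weak L1 regularization of
#' the THC central tensor.
#'
#' @param n_orbs Orbital counts (default `c(6, 8, 10, 12, 14)`).
#' @param seed Base seed; instance `i` uses `seed + i`.
#' @param thc_multiplier THC rank per orbital (default 4.7).
#' @param cholesky_per_orb Cholesky vectors per orbital (default 5).
#' @param reg_strength THC L1 penalty (default 1e-4).
#' @param budget A [precision_budget()].
#' @param thc_max_iter,thc_als_sweeps THC optimization budgets.
#' @return A list with `points` (data frame: N, method, lambda,
#'   toffoli_total, logical_qubits) and `fits` (per-method
#'   [fit_scaling()] results for Toffolis and qubits).
#' @export
scaling_study <- function(n_orbs = c(6L, 8L, 10L, 12L, 14L), seed = 1L,
                          thc_multiplier = 4.7, cholesky_per_orb = 5L,
                          reg_strength = 1e-4,
                          budget = precision_budget(),
                          thc_max_iter = 1500L, thc_als_sweeps = 150L) {
  rows <- list()
  for (i in seq_along(n_orbs)) {
    n <- n_orbs[i]
    h <- synthesize_hamiltonian(n, cholesky_per_orb * n, seed + i)
    sf <- single_factorize(h, tol = 0)
    df <- double_factorize(sf, leaf_tol = 1e-8)
    thc <- thc_factorize(h, rank = round(thc_multiplier * n),
                         reg_strength = reg_strength, seed = seed + i,
                         max_iter = thc_max_iter,
                         als_sweeps = thc_als_sweeps, n_restarts = 1L)
    for (f in list(sf, df, thc)) {
      res <- estimate_resources(h, f, budget)
      rows[[length(rows) + 1L]] <- data.frame(
        N = n, method = res$method, lambda = res$lambda_val,
        toffoli_total = res$toffoli_total,
        logical_qubits = res$logical_qubits)
    }
  }
  points <- do.call(rbind, rows)
  fits <- list()
  for (m in unique(points$method)) {
    sub <- points[points$method == m, ]
    fits[[m]] <- list(
      toffoli = fit_scaling(sub[, c("N", "toffoli_total")]),
      qubits = fit_scaling(sub[, c("N", "logical_qubits")]))
  }
  list(points = points, fits = fits)
}
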