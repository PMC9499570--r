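# Surface-code physical compilation: logical error model, magic-state
# factory models (two-level AutoCCZ distillation and 15-to-1 T
# factories), space accounting with 50% routing overhead, runtime under
# the factory bottleneck, and spacetime-volume configuration
# optimization subject to a >= 90% total success probability.

#' Hardware assumptions for surface-code compilation
#'
#' @param p_phys Physical per-gate error rate (0 < p < 0.5).
#' @param cycle_time Seconds per surface-code cycle (default 1e-6, the
#'   1 microsecond cycle of the adopted timing model).
#' @param reaction_time Control-system reaction time in seconds
#'   (default 1e-5).
#' @param n_factories Number of magic-state factories (default 4).
#' @return A list of class `hardware_assumptions`.
#' @export
hardware_assumptions <- function(p_phys = 1e-3, cycle_time = 1e-6,
                                 reaction_time = 1e-5, n_factories = 4L) {
  if (!(p_phys > 0 && p_phys < 0.5)) stop("p_phys must lie in (0, 0.5)")
  if (p_phys > 0.005)
    warning("p_phys above 0.5% is at or beyond the surface-code threshold regime")
  stopifnot(cycle_time > 0, reaction_time > 0, n_factories >= 1)
  structure(list(p_phys = p_phys, cycle_time = cycle_time,
                 reaction_time = reaction_time,
                 n_factories = as.integer(n_factories)),
            class = "hardware_assumptions")
}

#' Logical error rate of a distance-d surface-code patch
#'
#' Standard empirical fit `p_L = A (p_phys / p_th)^((d+1)/2)` per
#' logical qubit per code cycle, with `A = 0.1` and threshold
#' `p_th = 1%`.
#'
#' @param p_phys Physical per-gate error rate.
#' @param d Odd positive code distance.
#' @return Per-logical-qubit, per-cycle failure rate.
#' @export
logical_error_rate <- function(p_phys, d) {
  if (!(p_phys > 0 && p_phys < 0.5)) stop("p_phys must lie in (0, 0.5)")
  if (any(d < 1 | d %% 2 != 1)) stop("code distance must be odd and >= 1")
  0.1 * (p_phys / 0.01)^((d + 1) / 2)
}

# physical qubits of one logical data patch (two tiles of (d+1)^2)
physical_per_logical <- function(d) 2 * (d + 1)^2

#' Magic-state factory model
#'
#' Parameterizes a factory by its level-1/level-2 code distances.  The
#' AutoCCZ factory produces one CCZ (Toffoli-equivalent) state per
#' period; its output error follows the two-level distillation cascade
#' (15-to-1 at level 1, error `35 e^3`; CCZ assembly at level 2, error
#' `28 e^2`) plus the topological error of the factory footprint.  The
#' `T15to1` model is a two-level 15-to-1 T-state pipeline costed per
#' Toffoli (four T states per CCZ).
#'
#' @param kind `"AutoCCZ"` or `"T15to1"`.
#' @param d1,d2 Odd level-1 and level-2 code distances.
#' @param p_phys Physical error rate the factory is evaluated at.
#' @return A list of class `factory_model`: `kind`, `d1`, `d2`,
#'   `footprint` (physical qubits), `period_cycles` (cycles per Toffoli
#'   output), `p_out` (failure probability per Toffoli output).
#' @export
factory_model <- function(kind = c("AutoCCZ", "T15to1"), d1, d2, p_phys) {
  kind <- match.arg(kind)
  if (d1 %% 2 != 1 || d2 %% 2 != 1 || d1 < 3 || d2 < 3)
    stop("factory distances must be odd and >= 3")
  unit_err <- function(cells, d) cells * logical_error_rate(p_phys, d)
  # level-0: injected physical T states at half the level-1 distance
  d0 <- max(1, 2 * (d1 %/% 4) + 1)
  e0 <- p_phys + unit_err(100, d0)
  e1 <- 35 * e0^3 + unit_err(1100, d1)
  if (kind == "AutoCCZ") {
    p_out <- 28 * e1^2 + unit_err(1000, d2)
    t1_depth <- 5.75 * d1 / d2
    depth <- ceiling(5 + t1_depth)
    t1_per_ccz <- ceiling(4 * t1_depth / 5)
    width <- ceiling(2 * (8 * d1 / d2) + 3 + 2 * d1 / d2)
    height <- ceiling(max(6, (4 * d1 / d2) * ceiling(t1_per_ccz / 2)))
    footprint <- width * height * physical_per_logical(d2)
    period <- depth * d2
  } else {
    # two-level 15-to-1: level-2 distills T from level-1 T states;
    # four T states per Toffoli
    e2 <- 35 * e1^3 + unit_err(1100, d2)
    p_out <- 4 * e2
    footprint <- 16 * 2 * physical_per_logical(d2)  # 4x4 logical patch block
    period <- 4 * ceiling(5.75 * d2)
  }
  structure(list(kind = kind, d1 = as.integer(d1), d2 = as.integer(d2),
                 p_phys = p_phys,
                 footprint = as.numeric(footprint),
                 period_cycles = as.numeric(period),
                 p_out = min(1, p_out)),
            class = "factory_model")
}

#' Surface-code configuration
#'
#' @param d_data Odd data-qubit code distance.
#' @param factory A [factory_model()].
#' @param n_factories Factory count.
#' @return A list of class `surface_code_config`.
#' @export
surface_code_config <- function(d_data, factory, n_factories) {
  if (d_data %% 2 != 1 || d_data < 3) stop("d_data must be odd and >= 3")
  stopifnot(inherits(factory, "factory_model"), n_factories >= 1)
  structure(list(d_data = as.integer(d_data), factory = factory,
                 n_factories = as.integer(n_factories)),
            class = "surface_code_config")
}

#' Evaluate a surface-code configuration
#'
#' Deterministic physical cost of running `toffoli_count` Toffolis on
#' `logical_qubits` data qubits under configuration `cfg`:
#' * `physical_qubits = ceil(1.5 * (Q * 2 (d+1)^2 + n_f * footprint))`
#'   (50% routing overhead on data plus factories),
#' * `runtime = T * period * cycle_time / n_f` (factory bottleneck);
#'   with `reaction_floor = TRUE` this is floored by
#'   `T * reaction_time`, the limit when every Toffoli sits on one
#'   sequential measurement-dependency chain (off by default: the
#'   catalyzed CCZ fixups decouple consecutive Toffolis from the
#'   reaction loop),
#' * `p_fail_total = 1 - (1 - p_out)^T (1 - p_L)^(Q * cycles)`.
#'
#' @param cfg A [surface_code_config()].
#' @param hw A [hardware_assumptions()] (its factory count is superseded
#'   by `cfg$n_factories`).
#' @param logical_qubits Logical data qubit count Q.
#' @param toffoli_count Total Toffoli count T.
#' @param reaction_floor Apply the sequential reaction-time floor?
#'   Default `FALSE`.
#' @return A list of class `physical_estimate`: `physical_qubits`,
#'   `runtime_hours`, `p_fail_total`, `spacetime_volume`
#'   (qubit-seconds), `config`.
#' @export
evaluate_config <- function(cfg, hw, logical_qubits, toffoli_count,
                            reaction_floor = FALSE) {
  stopifnot(inherits(cfg, "surface_code_config"),
            inherits(hw, "hardware_assumptions"),
            logical_qubits > 0, toffoli_count > 0)
  Q <- logical_qubits; Tn <- toffoli_count
  nf <- cfg$n_factories
  fac <- cfg$factory
  phys <- ceiling(1.5 * (Q * physical_per_logical(cfg$d_data) +
                         nf * fac$footprint))
  runtime <- Tn * fac$period_cycles * hw$cycle_time / nf
  if (reaction_floor) runtime <- max(runtime, Tn * hw$reaction_time)
  cycles <- runtime / hw$cycle_time
  pL <- logical_error_rate(hw$p_phys, cfg$d_data)
  # complement via logs to stay accurate at tiny rates
  log_succ <- Tn * log1p(-min(fac$p_out, 1 - 1e-15)) +
    Q * cycles * log1p(-min(pL, 1 - 1e-15))
  p_fail <- -expm1(log_succ)
  structure(list(physical_qubits = phys,
                 runtime_hours = runtime / 3600,
                 p_fail_total = min(1, max(0, p_fail)),
                 spacetime_volume = phys * runtime,
                 config = cfg),
            class = "physical_estimate")
}

#' @export
print.physical_estimate <- function(x, ...) {
  cat(sprintf("Physical estimate: %s qubits, %.2f h, P(fail) = %.4f\n",
              format(x$physical_qubits, big.mark = ","), x$runtime_hours,
              x$p_fail_total),
      sprintf("  config: d_data = %d, %s factory (d1 = %d, d2 = %d) x %d\n",
              x$config$d_data, x$config$factory$kind, x$config$factory$d1,
              x$config$factory$d2, x$config$n_factories))
  invisible(x)
}

#' Default configuration search grid
#'
#' Odd distances: data `3..51`, factory level-1 `7..25`, level-2
#' `15..41` (level-2 forced above level-1).
#' @export
default_grid_spec <- function() {
  list(d_data = seq(3L, 51L, by = 2L),
       d1 = seq(7L, 25L, by = 2L),
       d2 = seq(15L, 41L, by = 2L),
       kind = "AutoCCZ")
}

#' Optimize the surface-code configuration
#'
#' Exhaustive search of the (d_data, d1, d2) grid for the feasible
#' configuration (`p_fail_total <= p_fail_max`, default 0.1, i.e. >= 90%
#' success) with minimal spacetime volume; ties broken by fewer physical
#' qubits, then smaller `d_data`.
#'
#' @param hw A [hardware_assumptions()].
#' @param logical_qubits Logical data qubit count Q.
#' @param toffoli_count Total Toffoli count T.
#' @param grid_spec List with vectors `d_data`, `d1`, `d2` and factory
#'   `kind`; see [default_grid_spec()].
#' @param p_fail_max Feasibility bound on total failure probability.
#' @return The optimal `physical_estimate`.  Errors (with the
#'   best-found failure probability in the message) if no grid point is
#'   feasible.
#' @export
optimize_config <- function(hw, logical_qubits, toffoli_count,
                            grid_spec = default_grid_spec(),
                            p_fail_max = 0.1) {
  stopifnot(inherits(hw, "hardware_assumptions"))
  best <- NULL
  best_pfail <- Inf
  for (d1 in grid_spec$d1) for (d2 in grid_spec$d2) {
    if (d2 <= d1) next
    fac <- factory_model(grid_spec$kind, d1, d2, hw$p_phys)
    for (dd in grid_spec$d_data) {
      cfg <- surface_code_config(dd, fac, hw$n_factories)
      est <- evaluate_config(cfg, hw, logical_qubits, toffoli_count)
      best_pfail <- min(best_pfail, est$p_fail_total)
      if (est$p_fail_total > p_fail_max) next
      if (is.null(best) ||
          est$spacetime_volume < best$spacetime_volume ||
          (est$spacetime_volume == best$spacetime_volume &&
           (est$physical_qubits < best$physical_qubits ||
            (est$physical_qubits == best$physical_qubits &&
             cfg$d_data < best$config$d_data)))) {
        best <- est
      }
    }
  }
  if (is.null(best)) {
    cond <- structure(class = c("qrechem_infeasible", "error", "condition"),
                      list(message = sprintf(
                             "no feasible configuration in grid (best P(fail) = %.4g)",
                             best_pfail),
                           call = sys.call(-1),
                           best_p_fail = best_pfail))
    stop(cond)
  }
  best
}
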