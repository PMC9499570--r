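# Classical DMRG cost scaling (CPU O(k^3 M^3), memory O(k^2 M^2), disk
# O(k^3 M^2)) and the generic THC-rank-per-orbital regression.

#' A DMRG resource cost point
#'
#' @param k Active orbital count.
#' @param M Bond dimension.
#' @param cpu_hours,memory_gb,disk_gb Measured or extrapolated
#'   resources; all positive.
#' @return A list of class `dmrg_cost_point`.
#' @export
dmrg_cost_point <- function(k, M, cpu_hours, memory_gb, disk_gb) {
  vals <- c(k, M, cpu_hours, memory_gb, disk_gb)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all DMRG cost-point fields must be positive")
  structure(list(k = k, M = M, cpu_hours = cpu_hours,
                 memory_gb = memory_gb, disk_gb = disk_gb),
            class = "dmrg_cost_point")
}

#' Extrapolate DMRG resources to a new orbital count and bond dimension
#'
#' Applies the scaling laws `cpu ~ k^3 M^3`, `memory ~ k^2 M^2`,
#' `disk ~ k^3 M^2` to a reference cost point.  No rounding is applied
#' internally; use [round_cost_point()] for report-time integer values.
#'
#' @param ref A [dmrg_cost_point()].
#' @param k_new Target orbital count (> 0).
#' @param m_new Target bond dimension (> 0).
#' @return A new `dmrg_cost_point` at `(k_new, m_new)`.
#' @export
dmrg_extrapolate <- function(ref, k_new, m_new) {
  stopifnot(inherits(ref, "dmrg_cost_point"))
  if (!is.finite(k_new) || !is.finite(m_new) || k_new <= 0 || m_new <= 0)
    stop("k_new and m_new must be positive")
  rk <- k_new / ref$k
  rm <- m_new / ref$M
  dmrg_cost_point(k_new, m_new,
                  cpu_hours = ref$cpu_hours * rk^3 * rm^3,
                  memory_gb = ref$memory_gb * rk^2 * rm^2,
                  disk_gb = ref$disk_gb * rk^3 * rm^2)
}

#' Round a DMRG cost point for reporting
#'
#' Nearest integer, half away from zero.
#'
#' @param pt A `dmrg_cost_point`.
#' @return The point with integer-rounded resource fields.
#' @export
round_cost_point <- function(pt) {
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)
  pt$cpu_hours <- rnd(pt$cpu_hours)
  pt$memory_gb <- rnd(pt$memory_gb)
  pt$disk_gb <- rnd(pt$disk_gb)
  pt
}

#' @export
print.dmrg_cost_point <- function(x, ...) {
  cat(sprintf("DMRG cost @ k = %g, M = %g: %.6g CPU-h, %.6g GB memory, %.6g GB disk\n",
              x$k, x$M, x$cpu_hours, x$memory_gb, x$disk_gb))
  invisible(x)
}

#' Read DMRG cost points from CSV
#'
#' Columns `k, M, cpu_hours, memory_gb, disk_gb`.
#'
#' @param path CSV path.
#' @return A list of `dmrg_cost_point`s.
#' @export
read_cost_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("k", "M", "cpu_hours", "memory_gb", "disk_gb")
  if (!all(need %in% names(df)))
    stop("cost-point CSV must have columns ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    do.call(dmrg_cost_point, as.list(df[i, need])))
}

#' Generic THC rank-per-orbital multiplier
#'
#' Least-squares regression of THC rank on orbital count N through the
#' origin, giving the single "generic rank" multiplier `M ~ c * N`
#' (the aggregated-fit multiplier reported for heme active spaces is
#' 4.7).
#'
#' @param points Data frame or matrix with columns `(N, rank)`, at
#'   least two positive points.
#' @return A list of class `rank_regression`: `multiplier`, `points`.
#' @export
generic_thc_rank <- function(points) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("N", "rank")
  if (nrow(pts) < 2L) stop("need at least two (N, rank) points")
  if (any(pts$N <= 0) || any(pts$rank <= 0))
    stop("points must be positive")
  if (sum(pts$N^2) == 0) stop("degenerate points")
  mult <- sum(pts$N * pts$rank) / sum(pts$N^2)
  structure(list(multiplier = mult, points = pts),
            class = "rank_regression")
}

#' @export
print.rank_regression <- function(x, ...) {
  cat(sprintf("Generic THC rank: M ~ %.3f * N (%d points)\n",
              x$multiplier, nrow(x$points)))
  invisible(x)
}
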