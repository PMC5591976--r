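#' Viable-mass ratio
#'
#' Computes `f = (2 * pi / V0) * integral(phi * r dr)` over the annulus,
#' the tumour mass relative to its initial mass. The initial mass equals
#' the initial tumour volume `V0 = pi * (r_outer^2 - r_inner^2)` because
#' the dimensionless density starts at 1 everywhere, so `f(0) = 1` exactly.
#'
#' @param grid A [radial_grid()] object.
#' @param phi Numeric vector of non-negative per-node cell densities.
#' @return A single non-negative number.
#' @export
#' @examples
#' g <- radial_grid(model_params(0.3, 0.102, 0.01))
#' mass_ratio(g, rep(0.5, g$n))  # 0.5 by linearity
mass_ratio <- function(grid, phi) {
  annular_integral(grid, phi) / grid$annulus_area
}

#' Time at which the tumour falls below an extinction threshold
#'
#' Finds the earliest time at which the viable-mass ratio drops below
#' `threshold`, linearly interpolated between the bracketing recorded
#' points. The default threshold of 1e-2 of the initial mass, together with
#' the convention of reporting the ceiling in whole apoptotic cycles,
#' operationalizes "all cancer cells die after N cycles".
#'
#' @param x A `chemo_sim` object, or a data frame with columns `t` and `f`.
#' @param threshold Extinction threshold, strictly between 0 and 1
#'   (default 1e-2).
#' @return The interpolated crossing time, or `NA` if `f` never falls below
#'   `threshold` within the simulated horizon.
#' @export
#' @examples
#' death_time(data.frame(t = c(0, 1, 2), f = c(1, 0.5, 0.005)))
death_time <- function(x, threshold = 1e-2) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  series <- if (inherits(x, "chemo_sim")) x$series else x
  t <- series$t
  f <- series$f
  below <- which(f < threshold)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (threshold - f[i - 1L]) * (t[i] - t[i - 1L]) / (f[i] - f[i - 1L])
}

#' Long-term regime from growth rate and saturated uptake
#'
#' After a long treatment the cumulative uptake at a point saturates at
#' `mu = integral_0^Inf sigma * phi dtau` and the density behaves like
#' `exp((alpha - mu) * t)`: the tumour proliferates if `alpha > mu`, decays
#' if `alpha < mu`, and sits in a quiescent state — progression balanced by
#' death — if `alpha == mu` (compared within a relative tolerance, since an
#' exact-equality regime is measure-zero in floating point).
#'
#' @param alpha Dimensionless growth rate(s). Vectorized.
#' @param mu Saturated cumulative uptake(s), non-negative. Vectorized.
#' @param tol Relative tolerance for declaring `alpha == mu`
#'   (default 1e-9).
#' @return Character vector with elements `"growth"`, `"decay"` or
#'   `"quiescence"`.
#' @export
#' @examples
#' classify_long_term(c(0.3, 0.1, 0.2), c(0.1, 0.3, 0.2))
classify_long_term <- function(alpha, mu, tol = 1e-9) {
  if (any(mu < 0)) stop("`mu` must be non-negative", call. = FALSE)
  res <- rep("quiescence", length.out = max(length(alpha), length(mu)))
  d <- alpha - mu
  scale <- pmax(abs(alpha), abs(mu), 1)
  res[d > tol * scale] <- "growth"
  res[d < -tol * scale] <- "decay"
  res
}

#' Saturated cumulative uptake at a node
#'
#' Estimates the long-time uptake limit `mu` at one radial node as the
#' terminal value of `U` in a finished run. The estimate is meaningful only
#' once the uptake has plateaued (`dU/dt = sigma * phi` vanishes as the
#' local density dies out); a run in which `U` is still rising faster than
#' `rate_tol` relative per apoptotic cycle is rejected as unsaturated.
#'
#' @param sim A `chemo_sim` object.
#' @param node Node index in `1:n_r`, or `NULL` (default) for all nodes.
#' @param rate_tol Maximum allowed relative growth rate of `U` at the end
#'   of the run (default 1e-3 per apoptotic cycle).
#' @return If `node` is given, a single number; otherwise a tibble with
#'   columns `r` and `mu`.
#' @export
saturated_uptake <- function(sim, node = NULL, rate_tol = 1e-3) {
  stopifnot(inherits(sim, "chemo_sim"))
  fs <- sim$final_state
  sigma <- solve_sigma(sim$grid, fs$phi)
  rate <- sigma * fs$phi / pmax(fs$U, .Machine$double.eps)
  check <- if (is.null(node)) rate else rate[node]
  if (any(check > rate_tol)) {
    stop("uptake not saturated: U still rising at relative rate ",
         format(max(check), digits = 3), " per cycle (> ", rate_tol,
         "); run longer or lower alpha", call. = FALSE)
  }
  if (is.null(node)) {
    tibble::tibble(r = sim$grid$r, mu = fs$U)
  } else {
    fs$U[[node]]
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the time series of a simulation
#'
#' @param x A `chemo_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `t` (apoptotic cycles) and `f`
#'   (viable-mass ratio).
#' @export
tidy.chemo_sim <- function(x, ...) {
  x$series
}

#' One-row summary of a simulation
#'
#' @param x A `chemo_sim` object.
#' @param threshold Extinction threshold passed to [death_time()].
#' @param ... Unused.
#' @return A one-row tibble: the parameters, `f_max`, `f_final`,
#'   `death_time` (NA if not reached), `death_cycles` (its ceiling in whole
#'   apoptotic cycles), and the numerics used.
#' @export
glance.chemo_sim <- function(x, threshold = 1e-2, ...) {
  dtm <- death_time(x, threshold)
  tibble::tibble(
    alpha = x$params$alpha,
    rb_over_l = x$params$rb_over_l,
    bvf = x$params$bvf,
    f_max = max(x$series$f),
    f_final = x$series$f[nrow(x$series)],
    death_time = dtm,
    death_cycles = if (is.na(dtm)) NA_real_ else ceiling(dtm),
    threshold = threshold,
    n_r = x$numerics$n_r,
    dt = x$numerics$dt,
    t_end = x$numerics$t_end
  )
}
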