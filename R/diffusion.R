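#' Quasi-steady drug field on the annulus
#'
#' Solves the dimensionless quasi-steady drug equation
#' `(1/r) d/dr (r dsigma/dr) - phi * sigma = 0` in cylindrical symmetry,
#' with `sigma = 1` at the vessel wall (Dirichlet) and zero flux at the
#' outer radius (Neumann). Drug diffusion equilibrates much faster than the
#' cell-death timescale, so the time derivative of the transport equation is
#' dropped and the elliptic problem is re-solved against the current cell
#' density at every time step.
#'
#' The cylindrical Laplacian is discretized in conservative form,
#' `(1/r_i) * (r_{i+1/2} (s_{i+1} - s_i) - r_{i-1/2} (s_i - s_{i-1})) / h^2`,
#' and the outer Neumann condition is imposed through a second-order ghost
#' node, giving a tridiagonal system solved directly (Thomas algorithm).
#' For non-negative `phi` the operator is an M-matrix, so the solve cannot
#' be singular and the discrete maximum principle guarantees
#' `0 <= sigma <= 1`.
#'
#' @param grid A [radial_grid()] object.
#' @param phi Numeric vector of non-negative per-node cell densities.
#' @return Numeric vector of per-node drug concentrations in `[0, 1]`, with
#'   `sigma[1] == 1` exactly.
#' @seealso [bessel_sigma()] for the closed-form solution at constant `phi`.
#' @export
#' @examples
#' g <- radial_grid(model_params(0.3, 0.102, 0.01))
#' sig <- solve_sigma(g, rep(1, g$n))
#' sig[1]  # 1 at the vessel wall
solve_sigma <- function(grid, phi) {
  stopifnot(inherits(grid, "radial_grid"))
  n <- grid$n
  if (length(phi) != n) {
    stop("`phi` must have one value per grid node (", n, ")", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi < 0)) {
    stop("`phi` must be finite and non-negative", call. = FALSE)
  }
  r <- grid$r
  h <- grid$h
  rp <- r + h / 2
  rm <- r - h / 2
  i <- 2:(n - 1L)

  # rows: Dirichlet at node 1, conservative stencil inside, ghost-node
  # Neumann (s_{n+1} = s_{n-1}) at node n
  lower <- c(rm[i] / (r[i] * h^2), (rp[n] + rm[n]) / (r[n] * h^2))
  upper <- c(0, rp[i] / (r[i] * h^2))
  diag <- c(1,
            -(rp[i] + rm[i]) / (r[i] * h^2) - phi[i],
            -(rp[n] + rm[n]) / (r[n] * h^2) - phi[n])
  rhs <- c(1, rep(0, n - 1L))

  sigma <- thomas_solve(lower, diag, upper, rhs)
  if (any(!is.finite(sigma))) {
    stop("tridiagonal solve produced non-finite drug concentrations; ",
         "this cannot occur for non-negative phi and indicates a ",
         "programming fault (n = ", n, ", h = ", h, ")", call. = FALSE)
  }
  sigma
}

# Thomas algorithm for a tridiagonal system.
# lower[i] multiplies x[i] in row i+1; upper[i] multiplies x[i+1] in row i.
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1L] <- upper[1L] / diag[1L]
  dp[1L] <- rhs[1L] / diag[1L]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}
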