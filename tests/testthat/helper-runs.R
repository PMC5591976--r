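# Shared simulation runs, computed once per test session. The headline
# configuration (alpha = 0.3, rb/L = 0.102, BVF = 0.01 at default numerics)
# is used by several files; memoise it.
run_cache <- new.env(parent = emptyenv())

cached_run <- function(alpha, rb_over_l = 0.102, bvf = 0.01, ...) {
  key <- paste(alpha, rb_over_l, bvf, ..., sep = "|")
  if (is.null(run_cache[[key]])) {
    run_cache[[key]] <- simulate_chemo(
      model_params(alpha, rb_over_l, bvf), ...)
  }
  run_cache[[key]]
}

# Coarse-but-resolved numerics for tests that only need qualitative shape.
coarse <- list(n_r = 101L, dt = 4e-3)

# Integrate the point kill model (sigma frozen at a constant) with rk4_step,
# returning the trajectory of a single node.
integrate_point_model <- function(sigma, alpha, dt, t_end) {
  n_steps <- as.integer(round(t_end / dt))
  state <- list(t = 0, phi = 1, U = 0, sigma = sigma)
  t <- numeric(n_steps + 1L)
  phi <- numeric(n_steps + 1L)
  U <- numeric(n_steps + 1L)
  phi[1L] <- 1
  for (k in seq_len(n_steps)) {
    state <- rk4_step(state, dt, alpha)
    t[k + 1L] <- state$t
    phi[k + 1L] <- state$phi
    U[k + 1L] <- state$U
  }
  list(t = t, phi = phi, U = U)
}
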