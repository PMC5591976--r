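test_that("right-hand side implements uptake-proportional kill plus growth", {
  out <- kill_rhs(phi = 1, U = 0, sigma = 1, alpha = 0.3)
  expect_equal(out$dphi, 0.3)
  expect_equal(out$dU, 1)

  out2 <- kill_rhs(phi = 2, U = 0.5, sigma = 0.25, alpha = 0)
  expect_equal(out2$dphi, -1.0)
  expect_equal(out2$dU, 0.5)

  # extinct tissue stays extinct
  out3 <- kill_rhs(phi = c(0, 1), U = c(5, 5), sigma = c(1, 1), alpha = 0.3)
  expect_equal(out3$dphi[1], 0)
  expect_equal(out3$dU[1], 0)

  expect_error(kill_rhs(1:3, 1:2, 1:3, 0), "equal lengths")
})

test_that("RK4 reproduces exponential growth with fourth-order accuracy", {
  # drug source disabled: phi(t) = exp(alpha t)
  alpha <- 0.3
  t_end <- 2
  err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    traj <- integrate_point_model(sigma = 0, alpha = alpha, dt = dt,
                                  t_end = t_end)
    abs(traj$phi[length(traj$phi)] - exponential_growth(alpha, t_end))
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(abs(orders - 4) < 0.3))
})

test_that("point kill model matches the sech^2 closed form", {
  # sigma frozen at 1, alpha = 0: phi = sech^2(t/sqrt(2)),
  # U = sqrt(2) tanh(t/sqrt(2))
  traj <- integrate_point_model(sigma = 1, alpha = 0, dt = 1e-3, t_end = 5)
  ref <- point_kill_phi(traj$t)
  expect_equal(traj$phi, ref$phi, tolerance = 1e-10)
  expect_equal(traj$U, ref$U, tolerance = 1e-10)
})

test_that("growth balanced by saturated uptake gives quiescence", {
  # alpha equal to U pointwise: dphi/dt = 0
  out <- kill_rhs(phi = 0.7, U = 0.2, sigma = 0.5, alpha = 0.2)
  expect_equal(out$dphi, 0)
})

test_that("simulation starts at exactly unit mass and keeps uptake monotone", {
  mp <- model_params(0.3, 0.102, 0.01)
  sim <- simulate_chemo(mp, n_r = coarse$n_r, dt = coarse$dt, t_end = 4,
                        record_every = 25,
                        snapshot_times = c(0, 1, 2, 3, 4))
  expect_lt(abs(sim$series$f[1] - 1), 1e-14)
  expect_true(all(sim$series$f >= 0))
  # U non-decreasing in t at every node, non-negative
  wide <- tidyr::pivot_wider(sim$snapshots[c("t", "r", "U")],
                             names_from = "t", values_from = "U")
  Umat <- as.matrix(wide[-1])
  expect_true(all(Umat >= 0))
  expect_true(all(apply(Umat, 1, function(u) all(diff(u) >= 0))))
})

test_that("without proliferation the mass ratio never increases", {
  sim <- simulate_chemo(model_params(0, 0.102, 0.01), n_r = coarse$n_r,
                        dt = coarse$dt, t_end = 6)
  expect_true(all(diff(sim$series$f) <= 0))
})

test_that("temporal refinement converges and sigma refresh policy is benign", {
  mp <- model_params(0.3, 0.102, 0.01)
  # halving dt barely moves f once spatial error dominates
  f_end <- vapply(c(8e-3, 4e-3), function(dt) {
    s <- simulate_chemo(mp, n_r = 101, dt = dt, t_end = 3,
                        record_every = 1000)
    s$series$f[nrow(s$series)]
  }, numeric(1))
  expect_lt(abs(diff(f_end)), 1e-6)

  # refreshing sigma per RK4 stage instead of per step changes f by less
  # than the spatial discretization error (Richardson estimate from a
  # grid-doubling pair)
  a <- simulate_chemo(mp, n_r = 101, dt = 2e-3, t_end = 3, record_every = 50)
  b <- simulate_chemo(mp, n_r = 101, dt = 2e-3, t_end = 3, record_every = 50,
                      sigma_refresh = "stage")
  fine <- simulate_chemo(mp, n_r = 201, dt = 2e-3, t_end = 3,
                         record_every = 50)
  split_diff <- max(abs(a$series$f - b$series$f))
  spatial_err <- max(abs(a$series$f - fine$series$f)) * 4 / 3
  expect_lt(split_diff, spatial_err)
})

test_that("death time responds monotonically to vascularization and growth", {
  # better-vascularized tumours die earlier; faster-growing ones die later
  runs <- lapply(list(c(0.3, 0.01), c(0.3, 0.05), c(0.7, 0.05)),
                 function(p) {
                   simulate_chemo(model_params(p[1], 0.102, p[2]),
                                  n_r = coarse$n_r, dt = coarse$dt,
                                  t_end = 10, record_every = 25)
                 })
  d <- vapply(runs, death_time, numeric(1))
  expect_gt(d[1], d[2])  # BVF 0.01 -> 0.05 at alpha 0.3: earlier death
  expect_lt(d[2], d[3])  # alpha 0.3 -> 0.7 at BVF 0.05: later death
})

test_that("absurd time steps fail loudly", {
  state <- list(t = 0, phi = 1, U = 0, sigma = 1)
  expect_error(rk4_step(state, dt = 1e80, alpha = 0), "time step too large")
  expect_error(rk4_step(state, dt = -1, alpha = 0), "positive")
  expect_error(simulate_chemo(model_params(0.3, 0.102, 0.01), t_end = -1),
               "positive")
})
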