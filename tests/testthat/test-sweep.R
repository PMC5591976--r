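tiny <- list(n_r = 31L, dt = 0.01, t_end = 0.1, record_every = 2L)

test_that("sweep grid expands lexicographically and validates combinations", {
  g <- sweep_grid(alphas = c(0, 0.3), bvfs = c(0.01, 0.05),
                  rb_over_ls = 0.102)
  expect_equal(nrow(g), 4)
  expect_equal(g$alpha, c(0, 0, 0.3, 0.3))
  expect_equal(g$bvf, c(0.01, 0.05, 0.01, 0.05))

  expect_error(sweep_grid(numeric(0), 0.01, 0.102), "non-empty")
  expect_error(sweep_grid(0.3, 1.2, 0.102), "BVF")
})

test_that("sweep summarises runs in order with extinction and regime", {
  sw <- suppressMessages(
    run_sweep(sweep_grid(c(0, 0.3), 0.01, 0.102), n_r = 51,
              dt = 5e-3, t_end = 8, record_every = 20))
  expect_s3_class(sw, "chemo_sweep")
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sw$summary$status, c("ok", "ok"))
  expect_equal(sw$summary$regime, c("decay", "decay"))
  expect_true(all(sw$summary$death_cycles == 6))
  # proliferation delays extinction
  expect_gt(sw$summary$death_time[2], sw$summary$death_time[1])

  td <- tidy(sw)
  expect_true(all(c("alpha", "bvf", "rb_over_l", "t", "f") %in% names(td)))
  expect_identical(glance(sw), sw$summary)
})

test_that("sweeps are deterministic end to end", {
  g <- sweep_grid(c(0, 0.3), 0.05, 0.05)
  sw1 <- suppressMessages(run_sweep(g, n_r = tiny$n_r, dt = tiny$dt,
                                    t_end = 2))
  sw2 <- suppressMessages(run_sweep(g, n_r = tiny$n_r, dt = tiny$dt,
                                    t_end = 2))
  expect_identical(sw1$summary, sw2$summary)
  expect_identical(tidy(sw1), tidy(sw2))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(sw1, d1)
  write_results(sw2, d2)
  for (f in list.files(d1)) {
    if (grepl("\\.csv$", f)) {
      expect_identical(readLines(file.path(d1, f)),
                       readLines(file.path(d2, f)))
    }
  }
})

test_that("a single failed run is marked without aborting the sweep", {
  real_simulate <- kroghchemo::simulate_chemo
  testthat::local_mocked_bindings(
    simulate_chemo = function(mp, ...) {
      if (mp$alpha > 0.5) stop("boom")
      real_simulate(mp, ...)
    },
    .package = "kroghchemo"
  )
  sw <- suppressMessages(
    run_sweep(sweep_grid(c(0, 0.7), 0.05, 0.05), n_r = tiny$n_r,
              dt = tiny$dt, t_end = tiny$t_end))
  expect_equal(sw$summary$status, c("ok", "failed"))
  expect_true(is.na(sw$summary$death_time[2]))
  expect_false(is.na(sw$summary$regime[1]))
})

test_that("outputs are one summary plus one series file per run", {
  g <- sweep_grid(c(0, 0.3, 0.7), c(0.05, 0.1), c(0.05, 0.102))
  sw <- suppressMessages(
    run_sweep(g, n_r = tiny$n_r, dt = tiny$dt, t_end = tiny$t_end,
              record_every = tiny$record_every))
  d <- withr::local_tempdir()
  write_results(sw, d)
  files <- list.files(d)
  expect_equal(sum(grepl("^series_", files)), 12)
  expect_true("summary.csv" %in% files)
  expect_true("metadata.json" %in% files)
  expect_equal(nrow(utils::read.csv(file.path(d, "summary.csv"))), 12)

  meta <- jsonlite::read_json(file.path(d, "metadata.json"))
  expect_equal(length(meta$grid), 12)
  expect_equal(meta$numerics$dt, tiny$dt)
})

test_that("single-run output writes series, snapshots and metadata", {
  sim <- simulate_chemo(model_params(0.3, 0.102, 0.05), n_r = tiny$n_r,
                        dt = tiny$dt, t_end = tiny$t_end,
                        snapshot_times = c(0, 0.1))
  d <- withr::local_tempdir()
  write_results(sim, d)
  expect_setequal(list.files(d),
                  c("series.csv", "snapshots.csv", "metadata.json"))
  ser <- utils::read.csv(file.path(d, "series.csv"))
  expect_equal(ser$f[1], 1)
})

test_that("malformed sweep inputs are rejected up front", {
  expect_error(run_sweep(data.frame(alpha = 0.3)), "columns")
  expect_error(run_sweep(data.frame(alpha = 0.3, bvf = 2, rb_over_l = 0.1)),
               "BVF")
  expect_error(run_sweep(data.frame(alpha = numeric(0), bvf = numeric(0),
                                    rb_over_l = numeric(0))),
               "at least one row")
})
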