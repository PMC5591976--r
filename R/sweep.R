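#' Build a parameter grid for a sweep
#'
#' Expands lists of growth rates, blood volume fractions and vessel radii
#' into the full factorial grid, in deterministic lexicographic order
#' (`alpha` outermost, then `bvf`, then `rb_over_l`). Every combination is
#' validated up front.
#'
#' @param alphas Numeric vector of dimensionless growth rates (non-empty).
#' @param bvfs Numeric vector of blood volume fractions in (0, 1).
#' @param rb_over_ls Numeric vector of dimensionless vessel radii.
#' @return A tibble with columns `alpha`, `bvf`, `rb_over_l`, one row per
#'   combination.
#' @export
#' @examples
#' sweep_grid(alphas = c(0, 0.3), bvfs = 0.01, rb_over_ls = 0.102)
sweep_grid <- function(alphas, bvfs, rb_over_ls) {
  if (length(alphas) == 0L || length(bvfs) == 0L || length(rb_over_ls) == 0L) {
    stop("`alphas`, `bvfs` and `rb_over_ls` must all be non-empty",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(alpha = alphas, bvf = bvfs,
                             rb_over_l = rb_over_ls)
  purrr::pwalk(grid, function(alpha, bvf, rb_over_l) {
    model_params(alpha, rb_over_l, bvf)
  })
  grid
}

#' Run a deterministic parameter sweep
#'
#' Runs one [simulate_chemo()] per row of the parameter grid, in row order,
#' and summarises each run: the extinction time under `threshold`, its
#' ceiling in whole apoptotic cycles, and the observed trajectory regime.
#' A failure in a single run is caught, reported on standard error and
#' marked `"failed"` in the summary without aborting the remaining runs.
#' The whole pipeline is deterministic: identical inputs give identical
#' outputs.
#'
#' @param params A data frame with columns `alpha`, `bvf` and `rb_over_l`
#'   (one row per run), e.g. from [sweep_grid()].
#' @param n_r,t_end,dt,record_every Numerics passed to [simulate_chemo()].
#' @param threshold Extinction threshold for [death_time()] (default 1e-2).
#' @param keep_series Keep each run's `f(t)` series (default `TRUE`; the
#'   series become a list-column of the result).
#' @return An object of class `chemo_sweep`: a list with `summary` (tibble
#'   with columns `alpha`, `bvf`, `rb_over_l`, `death_time`, `death_cycles`,
#'   `regime`, `threshold`, `status`), `runs` (list of `chemo_sim` objects
#'   or `NULL` for failed runs, when `keep_series` is `TRUE`), and
#'   `numerics`.
#' @export
#' @examples
#' sw <- run_sweep(sweep_grid(c(0, 0.3), 0.01, 0.102),
#'                 n_r = 51, dt = 5e-3)
#' sw$summary
run_sweep <- function(params, n_r = 401L, t_end = 10, dt = 1e-3,
                      record_every = 10L, threshold = 1e-2,
                      keep_series = TRUE) {
  stopifnot(is.data.frame(params))
  need <- c("alpha", "bvf", "rb_over_l")
  if (!all(need %in% names(params))) {
    stop("`params` must have columns alpha, bvf, rb_over_l", call. = FALSE)
  }
  if (nrow(params) == 0L) stop("`params` must have at least one row",
                               call. = FALSE)
  purrr::pwalk(params[need], function(alpha, bvf, rb_over_l) {
    model_params(alpha, rb_over_l, bvf)
  })

  runs <- vector("list", nrow(params))
  rows <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    alpha <- params$alpha[i]
    bvf <- params$bvf[i]
    rb_over_l <- params$rb_over_l[i]
    message(sprintf("run %d/%d: alpha = %g, BVF = %g, rb/L = %g",
                    i, nrow(params), alpha, bvf, rb_over_l))
    base <- tibble::tibble(alpha = alpha, bvf = bvf, rb_over_l = rb_over_l)
    sim <- tryCatch(
      simulate_chemo(model_params(alpha, rb_over_l, bvf), n_r = n_r,
                     t_end = t_end, dt = dt, record_every = record_every),
      error = function(e) {
        message(sprintf("run failed (alpha = %g, BVF = %g, rb/L = %g): %s",
                        alpha, bvf, rb_over_l, conditionMessage(e)))
        NULL
      })
    if (is.null(sim)) {
      rows[[i]] <- dplyr::mutate(base, death_time = NA_real_,
                                 death_cycles = NA_real_,
                                 regime = NA_character_,
                                 threshold = threshold, status = "failed")
      next
    }
    if (keep_series) runs[[i]] <- sim
    dtm <- death_time(sim, threshold)
    rows[[i]] <- dplyr::mutate(
      base,
      death_time = dtm,
      death_cycles = if (is.na(dtm)) NA_real_ else ceiling(dtm),
      regime = trajectory_regime(sim, threshold),
      threshold = threshold, status = "ok")
  }
  summary <- dplyr::bind_rows(rows)

  structure(
    list(summary = summary,
         runs = if (keep_series) runs else NULL,
         numerics = list(n_r = n_r, t_end = t_end, dt = dt,
                         record_every = record_every,
                         threshold = threshold)),
    class = "chemo_sweep"
  )
}

# Empirical regime of a finished trajectory: extinction within the horizon
# means decay; otherwise use the late-time slope of log f.
trajectory_regime <- function(sim, threshold = 1e-2, tol = 1e-6) {
  if (!is.na(death_time(sim, threshold))) return("decay")
  s <- sim$series
  n <- nrow(s)
  i0 <- max(1L, n - max(2L, n %/% 10L))
  slope <- (log(s$f[n]) - log(s$f[i0])) / (s$t[n] - s$t[i0])
  if (slope > tol) "growth" else if (slope < -tol) "decay" else "quiescence"
}

#' @export
print.chemo_sweep <- function(x, ...) {
  cat(sprintf("<chemo_sweep> %d runs (n_r = %d, dt = %g, t_end = %g)\n",
              nrow(x$summary), x$numerics$n_r, x$numerics$dt,
              x$numerics$t_end))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.chemo_sweep <- function(x, ...) {
  if (is.null(x$runs)) {
    stop("sweep was run with keep_series = FALSE; no series to tidy",
         call. = FALSE)
  }
  purrr::map2_dfr(seq_along(x$runs), x$runs, function(i, sim) {
    if (is.null(sim)) return(NULL)
    dplyr::mutate(sim$series,
                  alpha = x$summary$alpha[i],
                  bvf = x$summary$bvf[i],
                  rb_over_l = x$summary$rb_over_l[i],
                  .before = 1L)
  })
}

#' @export
glance.chemo_sweep <- function(x, ...) {
  x$summary
}

#' Write simulation or sweep outputs to disk
#'
#' Writes the tabular outputs of a run or sweep: a summary CSV, one `f(t)`
#' series CSV per run, per-time radial snapshot CSVs when present, and a
#' JSON metadata file recording all parameters, numeric settings and the
#' package version. All floating-point values are written with 17
#' significant digits so that re-running an identical configuration gives
#' byte-identical numeric content.
#'
#' @param x A `chemo_sim` or `chemo_sweep` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir) {
  UseMethod("write_results")
}

fmt17 <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

write_csv17 <- function(df, path) {
  utils::write.csv(fmt17(as.data.frame(df)), path, row.names = FALSE,
                   quote = FALSE)
  path
}

#' @export
write_results.chemo_sim <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_csv17(x$series, file.path(dir, "series.csv")),
    if (!is.null(x$snapshots)) {
      write_csv17(x$snapshots, file.path(dir, "snapshots.csv"))
    }
  )
  meta <- list(params = unclass(x$params)[c("alpha", "rb_over_l", "bvf")],
               numerics = x$numerics,
               package_version = as.character(utils::packageVersion("kroghchemo")))
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, meta_path))
}

#' @export
write_results.chemo_sweep <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_csv17(x$summary, file.path(dir, "summary.csv"))
  if (!is.null(x$runs)) {
    for (i in seq_along(x$runs)) {
      if (is.null(x$runs[[i]])) next
      s <- x$summary[i, ]
      nm <- sprintf("series_alpha%g_bvf%g_rbl%g.csv",
                    s$alpha, s$bvf, s$rb_over_l)
      paths <- c(paths, write_csv17(x$runs[[i]]$series, file.path(dir, nm)))
    }
  }
  meta <- list(grid = as.data.frame(x$summary[c("alpha", "bvf", "rb_over_l")]),
               numerics = x$numerics,
               package_version = as.character(utils::packageVersion("kroghchemo")))
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, meta_path))
}
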