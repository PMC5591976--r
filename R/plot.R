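#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the viable-mass ratio of one run
#'
#' Draws `f(t)` against time in apoptotic cycles, with the extinction
#' threshold as a dashed reference line.
#'
#' @param object A `chemo_sim` object.
#' @param threshold Extinction threshold to mark (default 1e-2).
#' @param log_f Plot `f` on a log scale (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemo_sim <- function(object, threshold = 1e-2, log_f = FALSE, ...) {
  p <- ggplot2::ggplot(object$series, ggplot2::aes(x = .data$t, y = .data$f)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "time (apoptotic cycles)",
      y = "viable-mass ratio f",
      title = sprintf("alpha = %g, rb/L = %g, BVF = %g",
                      object$params$alpha, object$params$rb_over_l,
                      object$params$bvf)) +
    ggplot2::theme_minimal()
  if (log_f) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a sweep as panels keyed by growth rate
#'
#' Mirrors the standard presentation of the response curves: one panel per
#' (BVF, rb/L) geometry, curves coloured by the growth rate `alpha`.
#'
#' @param object A `chemo_sweep` object run with `keep_series = TRUE`.
#' @param threshold Extinction threshold to mark (default 1e-2).
#' @param log_f Plot `f` on a log scale (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemo_sweep <- function(object, threshold = 1e-2, log_f = FALSE,
                                 ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$f,
                                        colour = factor(.data$alpha))) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$bvf), cols = ggplot2::vars(.data$rb_over_l),
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (apoptotic cycles)", y = "viable-mass ratio f",
                  colour = "alpha") +
    ggplot2::theme_minimal()
  if (log_f) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot radial drug and density profiles
#'
#' Draws the stored radial snapshots of the cell density and drug
#' concentration at the requested times.
#'
#' @param sim A `chemo_sim` run with `snapshot_times`.
#' @return A ggplot object with one panel per field, lines keyed by time.
#' @export
plot_profiles <- function(sim) {
  stopifnot(inherits(sim, "chemo_sim"))
  if (is.null(sim$snapshots)) {
    stop("simulation was run without `snapshot_times`", call. = FALSE)
  }
  df <- tidyr::pivot_longer(sim$snapshots, c("phi", "sigma"),
                            names_to = "field", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$value,
                                   colour = factor(round(.data$t, 6)))) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$field), scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(phi = "cell density phi",
                            sigma = "drug concentration sigma"))) +
    ggplot2::labs(x = "radius (diffusion lengths)", y = NULL,
                  colour = "t (cycles)") +
    ggplot2::theme_minimal()
}
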