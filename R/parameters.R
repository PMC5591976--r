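#' Dimensional model constants
#'
#' Bundles the seven physical constants of the dimensional drug-transport /
#' cell-kill model: drug diffusivity, cellular uptake rate, kill rate per
#' unit cumulative drug concentration, vessel-wall drug concentration,
#' initial cell density, cell growth rate, and blood-vessel radius.
#'
#' Any consistent unit system may be used; the model only requires that the
#' product `lambda_k * lambda_u * phi0 * sigma0` has units of 1/time^2 (so
#' that the apoptotic-cycle time scale `T` is a time) and that
#' `D / (phi0 * lambda_u)` has units of length^2.
#'
#' @param D Drug diffusivity (length^2/time). Strictly positive.
#' @param lambda_u Cellular uptake rate of drug per volume
#'   (1/(density * time)). Strictly positive.
#' @param lambda_k Death rate of tumour cells per unit cumulative drug
#'   concentration. Strictly positive.
#' @param sigma0 Drug concentration at the vessel wall (concentration).
#'   Strictly positive.
#' @param phi0 Initial cell density (density). Strictly positive.
#' @param alpha Cell growth rate (1/time). Non-negative.
#' @param rb Blood vessel radius (length). Strictly positive.
#'
#' @return An object of class `dimensional_params` (a named list of the
#'   seven constants).
#' @seealso [nondimensionalize()]
#' @export
#' @examples
#' dimensional_params(D = 1, lambda_u = 1, lambda_k = 1, sigma0 = 1,
#'                    phi0 = 1, alpha = 1, rb = 0.102)
dimensional_params <- function(D, lambda_u, lambda_k, sigma0, phi0, alpha, rb) {
  p <- list(D = D, lambda_u = lambda_u, lambda_k = lambda_k, sigma0 = sigma0,
            phi0 = phi0, alpha = alpha, rb = rb)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  strict <- setdiff(names(p), "alpha")
  bad <- strict[vapply(p[strict], function(v) v <= 0, logical(1))]
  if (length(bad) > 0L) {
    stop("`", bad[[1L]], "` must be strictly positive", call. = FALSE)
  }
  if (p$alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  structure(p, class = "dimensional_params")
}

#' Dimensionless model parameters
#'
#' The three dimensionless knobs that fully determine the nondimensional
#' system: the growth rate per apoptotic cycle `alpha`, the vessel radius in
#' diffusion lengths `rb_over_l`, and the blood volume fraction `bvf` (ratio
#' of blood volume to tumour volume). The outer radius of the tissue annulus
#' served by one vessel is `rb_over_l / sqrt(bvf)`, which exceeds the inner
#' radius because `bvf < 1`.
#'
#' @param alpha Dimensionless growth rate (growth rate times the
#'   apoptotic-cycle time scale `T`). Non-negative.
#' @param rb_over_l Vessel radius divided by the drug diffusion length `L`.
#'   Strictly positive.
#' @param bvf Blood volume fraction, strictly between 0 and 1. Larger values
#'   mean a more highly vascularized tumour and a thinner annulus per vessel.
#'
#' @return An object of class `model_params` with fields `alpha`,
#'   `rb_over_l`, `bvf` and the derived `r_outer = rb_over_l / sqrt(bvf)`.
#' @export
#' @examples
#' model_params(alpha = 0.3, rb_over_l = 0.102, bvf = 0.01)
model_params <- function(alpha, rb_over_l, bvf) {
  mp <- structure(
    list(alpha = alpha, rb_over_l = rb_over_l, bvf = bvf,
         r_outer = rb_over_l / sqrt(bvf)),
    class = "model_params"
  )
  validate_model_params(mp)
}

#' Validate dimensionless parameters
#'
#' Checks the invariants of a [model_params()] object and returns it
#' unchanged if they all hold.
#'
#' @param mp A `model_params` object.
#' @return `mp`, invisibly unchanged, if valid; otherwise an error naming the
#'   violated constraint.
#' @export
validate_model_params <- function(mp) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(mp$alpha) || !num1(mp$rb_over_l) || !num1(mp$bvf)) {
    stop("alpha, rb_over_l and bvf must each be a single finite number",
         call. = FALSE)
  }
  if (mp$alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  if (mp$rb_over_l <= 0) stop("`rb_over_l` must be strictly positive",
                              call. = FALSE)
  if (mp$bvf <= 0 || mp$bvf >= 1) {
    stop("BVF must lie strictly between 0 and 1", call. = FALSE)
  }
  mp
}

#' Nondimensionalize the physical constants
#'
#' Converts a set of dimensional constants into the three dimensionless
#' parameters solved internally, along with the characteristic scales:
#' the apoptotic-cycle time scale
#' `T = (lambda_k * lambda_u * phi0 * sigma0)^(-1/2)` and the drug diffusion
#' length `L = sqrt(D / (phi0 * lambda_u))`. The dimensionless growth rate is
#' `alpha * T` and the dimensionless vessel radius is `rb / L`.
#'
#' The blood volume fraction is a tissue property that cannot be derived from
#' the seven constants, so it must be supplied alongside them.
#'
#' @param p A [dimensional_params()] object.
#' @param bvf Blood volume fraction in (0, 1).
#' @return A list with components `params` (a [model_params()] object),
#'   `time_scale` (`T`) and `length_scale` (`L`).
#' @export
#' @examples
#' p <- dimensional_params(D = 4, lambda_u = 1, lambda_k = 1, sigma0 = 4,
#'                         phi0 = 1, alpha = 0.15, rb = 0.204)
#' nondimensionalize(p, bvf = 0.01)
nondimensionalize <- function(p, bvf) {
  if (!inherits(p, "dimensional_params")) {
    stop("`p` must be a dimensional_params object", call. = FALSE)
  }
  time_scale <- 1 / sqrt(p$lambda_k * p$lambda_u * p$phi0 * p$sigma0)
  length_scale <- sqrt(p$D / (p$phi0 * p$lambda_u))
  mp <- model_params(alpha = p$alpha * time_scale,
                     rb_over_l = p$rb / length_scale,
                     bvf = bvf)
  list(params = mp, time_scale = time_scale, length_scale = length_scale)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  alpha (growth per apoptotic cycle): %g\n", x$alpha))
  cat(sprintf("  rb/L  (vessel radius in diffusion lengths): %g\n",
              x$rb_over_l))
  cat(sprintf("  BVF   (blood volume fraction): %g\n", x$bvf))
  cat(sprintf("  annulus: [%g, %g]\n", x$rb_over_l, x$r_outer))
  invisible(x)
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("<dimensional_params>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
tidy.model_params <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, rb_over_l = x$rb_over_l, bvf = x$bvf,
                 r_outer = x$r_outer)
}
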