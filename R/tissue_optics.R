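#' Wrap phase to the principal interval (-pi, pi]
#'
#' Maps arbitrary phase values (radians) into the principal interval,
#' with the convention that +pi is kept and -pi maps to +pi, matching
#' the range of [atan2()][base::atan2].
#'
#' @param x numeric vector/matrix/array of phase values in radians.
#' @return object of the same shape with all values in `(-pi, pi]`.
#' @examples
#' wrap_phase(6.0)      # 6 - 2*pi
#' wrap_phase(-pi)      # +pi
#' @export
wrap_phase <- function(x) {
  stopifnot(is.numeric(x))
  pi - ((pi - x) %% (2 * pi))
}

#' Construct an optical medium
#'
#' Describes a turbid medium as ground matter of refractive index `n_g`
#' containing mono-disperse spherical scattering centers of index `n_sc`
#' at volume concentration `c_sc`, sphere radius `r_um` (micrometres) and
#' sphere volume density `Vs_per_um3` (per cubic micrometre).
#'
#' @param n_g refractive index of the ground matter (>= 1).
#' @param n_sc refractive index of the scattering centers (>= 1).
#' @param c_sc volume concentration of scatterers, in `[0, 1]`.
#' @param r_um scatterer sphere radius in micrometres (> 0).
#' @param Vs_per_um3 sphere volume density in um^-3 (>= 0).
#' @return an object of class `optical_medium`.
#' @seealso [median_refractive_index()], [scattering_coefficient()]
#' @export
optical_medium <- function(n_g, n_sc, c_sc, r_um = 0.5, Vs_per_um3 = 0.1) {
  if (!is.numeric(c_sc) || length(c_sc) != 1L || is.na(c_sc) ||
      c_sc < 0 || c_sc > 1)
    stop("`c_sc` must be a single value in [0, 1]")
  if (n_g < 1 || n_sc < 1)
    stop("refractive indices must be >= 1")
  if (r_um <= 0) stop("`r_um` must be positive")
  if (Vs_per_um3 < 0) stop("`Vs_per_um3` must be non-negative")
  structure(
    list(n_g = n_g, n_sc = n_sc, c_sc = c_sc,
         r_um = r_um, Vs_per_um3 = Vs_per_um3),
    class = "optical_medium"
  )
}

#' @export
print.optical_medium <- function(x, ...) {
  cat("<optical_medium>\n",
      sprintf("  n_g = %.4f, n_sc = %.4f, c_sc = %.3f\n",
              x$n_g, x$n_sc, x$c_sc),
      sprintf("  r = %.3f um, V_S = %.4f um^-3\n", x$r_um, x$Vs_per_um3),
      sprintf("  n_m = %.4f\n", median_refractive_index(x)),
      sep = "")
  invisible(x)
}

#' Median refractive index of a scattering medium
#'
#' Volume-weighted mixture index
#' `n_m = c_sc * n_sc + (1 - c_sc) * n_g`: the effective (median)
#' refractive index of ground matter with embedded scattering centers.
#'
#' @param medium an [optical_medium()].
#' @return dimensionless refractive index, bounded by `n_g` and `n_sc`.
#' @examples
#' median_refractive_index(optical_medium(1.36, 1.45, 0.3))  # 1.387
#' @export
median_refractive_index <- function(medium) {
  stopifnot(inherits(medium, "optical_medium"))
  medium$c_sc * medium$n_sc + (1 - medium$c_sc) * medium$n_g
}

#' Scattering coefficient of a mono-disperse sphere suspension
#'
#' Phenomenological power law for the scattering coefficient of
#' dielectric spheres of radius `r` (um) and volume density `V_S`
#' (um^-3) in ground matter:
#' `mu_sc = 3.28 * pi * r^2 * V_S * (2*pi*r/lambda)^0.37 *
#'  (n_sc/n_g - 1)^2.09`, with all lengths in micrometres, so `mu_sc`
#' is in um^-1 (multiply by 1e4 for cm^-1).
#'
#' The exponent 2.09 is non-integer, so the relative index contrast
#' `n_sc/n_g` must be >= 1; media with scatterers rarer than the ground
#' matter raise an error rather than returning a complex/NaN value.
#'
#' @param medium an [optical_medium()] with `n_sc >= n_g`.
#' @param lambda_um wavelength in micrometres (> 0).
#' @return scattering coefficient in um^-1.
#' @examples
#' m <- optical_medium(n_g = 1.0, n_sc = 1.06, c_sc = 0.1,
#'                     r_um = 0.5, Vs_per_um3 = 0.1)
#' scattering_coefficient(m, 0.632)   # ~1.303e-3 um^-1
#' @export
scattering_coefficient <- function(medium, lambda_um) {
  stopifnot(inherits(medium, "optical_medium"))
  if (!is.numeric(lambda_um) || any(lambda_um <= 0))
    stop("`lambda_um` must be positive")
  ratio <- medium$n_sc / medium$n_g
  if (ratio < 1)
    stop("scattering_coefficient() requires n_sc >= n_g ",
         "(non-integer exponent of the index contrast)")
  r <- medium$r_um
  3.28 * pi * r^2 * medium$Vs_per_um3 *
    (2 * pi * r / lambda_um)^0.37 * (ratio - 1)^2.09
}

#' Phase shift from an optical path difference
#'
#' Converts an optical path difference (refractive index times geometric
#' path, micrometres) at wavelength `lambda_um` into a wrapped phase
#' `wrap(2 * pi * OPD / lambda)` in `(-pi, pi]`.
#'
#' @param delta_opd_um optical path difference in micrometres (vectorised).
#' @param lambda_um wavelength in micrometres (> 0).
#' @return wrapped phase in radians.
#' @examples
#' phase_from_opd(0.158, 0.632)  # pi/2
#' phase_from_opd(0.632, 0.632)  # full cycle wraps back to ~0
#' @export
phase_from_opd <- function(delta_opd_um, lambda_um) {
  if (!is.numeric(lambda_um) || any(lambda_um <= 0))
    stop("`lambda_um` must be positive")
  wrap_phase(2 * pi * delta_opd_um / lambda_um)
}
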