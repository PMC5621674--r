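#' Lame parameter and bulk modulus from engineering constants
#'
#' For a nearly-incompressible neo-Hookean solid the small-strain tangent
#' modulus `E` and Poisson's ratio `nu` determine the Lame shear parameter
#' and the initial bulk modulus through
#' `mu = E / (2 (1 + nu))` and `kappa = E / (3 (1 - 2 nu))`.
#'
#' @param E Small-strain tangent modulus, kPa (> 0).
#' @param nu Poisson's ratio in `[0, 0.5)`; the default 0.49 encodes near
#'   incompressibility of high-water-content embryonic tissue.
#' @return A list with `mu` and `kappa` in kPa.
#' @export
lame_parameters <- function(E, nu = 0.49) {
  if (!is.numeric(E) || any(E <= 0) || any(!is.finite(E)))
    pa_stop("E must be positive and finite", "pamech_invalid_material")
  if (!is.numeric(nu) || any(nu < 0))
    pa_stop("nu must be non-negative", "pamech_invalid_material")
  if (any(nu >= 0.5))
    pa_stop("nu >= 0.5: the incompressible limit has no finite bulk modulus",
            "pamech_incompressible_limit")
  list(mu = E / (2 * (1 + nu)), kappa = E / (3 * (1 - 2 * nu)))
}

#' Construct a constitutive law
#'
#' @param model `"neo-hookean"` (nearly-incompressible hyperelastic, the
#'   default for embryonic myocardium) or `"linear"` (linear stress-strain
#'   comparison model, still analyzed at finite deformation).
#' @param E Small-strain tangent modulus, kPa.
#' @param nu Poisson's ratio, default 0.49.
#' @return An object of class `material_law` with derived `mu` and `kappa`.
#' @export
material_law <- function(model = c("neo-hookean", "linear"), E, nu = 0.49) {
  model <- match.arg(model)
  lam <- lame_parameters(E, nu)
  structure(list(model = model, E = E, nu = nu, mu = lam$mu, kappa = lam$kappa),
            class = "material_law")
}

#' @export
print.material_law <- function(x, ...) {
  cat(sprintf("<material_law> %s: E = %.4g kPa, nu = %.3g (mu = %.4g, kappa = %.4g kPa)\n",
              x$model, x$E, x$nu, x$mu, x$kappa))
  invisible(x)
}
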