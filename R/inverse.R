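#' Pointwise mean of load-deflection curves
#'
#' Interpolates each curve onto a common `lbar` grid spanning the shared
#' support and averages the pressures; this mean curve is the target of the
#' inverse modulus fit.
#'
#' @param curves A list of [load_deflection_curve]s.
#' @param grid Optional explicit `lbar` grid; by default 50 points from 0 to
#'   the smallest curve maximum.
#' @return A [load_deflection_curve].
#' @export
mean_curve <- function(curves, grid = NULL) {
  if (!length(curves))
    pa_stop("mean_curve() needs at least one curve", "pamech_insufficient_data")
  lo <- max(vapply(curves, function(cv) min(cv$lbar), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$lbar), numeric(1)))
  if (hi <= lo)
    pa_stop("curves have disjoint lbar support; no common range to average over",
            "pamech_incompatible_support")
  if (is.null(grid)) grid <- seq(lo, hi, length.out = 50L)
  pmat <- vapply(curves, function(cv) {
    o <- order(cv$lbar)
    approx(cv$lbar[o], cv$pressure[o], xout = grid, ties = mean, rule = 2)$y
  }, numeric(length(grid)))
  load_deflection_curve(grid, rowMeans(as.matrix(pmat)))
}

#' Inverse fit of the small-strain tangent modulus
#'
#' Recovers the apparent modulus `E` of the bilayer wall by iteratively
#' adjusting the forward finite-element model until its load-deflection
#' curve best matches a target curve in a least-squares sense.  The misfit
#' is measured in the deflection direction at the model's pressure steps
#' (pressure is the controlled variable), summed over steps falling inside
#' the target's pressure range and the fit window `lbar <= lbar_max`.
#'
#' A single forward solve at a reference modulus seeds the search bracket
#' through the near-proportionality of deflection and compliance; a bounded
#' scalar minimization (Brent) on log `E` then refines it, expanding the
#' bracket when the minimum lands on its edge, to an absolute tolerance of
#' about `tol` kPa.
#'
#' @param target A [load_deflection_curve] spanning `lbar` up to at least 0.3.
#' @param geom A [wall_geometry] for the fitted group.
#' @param law_template A [material_law] fixing the constitutive model and
#'   Poisson's ratio; its `E` is ignored.
#' @param bounds Search interval for `E` in kPa.
#' @param tol Absolute tolerance on `E`, kPa.
#' @param lbar_max Fit window on normalized deflection.
#' @param step Pressure step of the forward sweeps, kPa.
#' @param refine Mesh refinement of the forward model.
#' @return An object of class `fit_result`: `E_opt` (kPa), `residual`
#'   (summed squared deflection misfit), `n_forward_solves`, `converged`.
#' @export
fit_modulus <- function(target, geom,
                        law_template = material_law("neo-hookean", E = 1),
                        bounds = c(0.1, 100), tol = 0.01, lbar_max = 0.4,
                        step = 0.2, refine = 1) {
  if (!inherits(target, "load_deflection_curve"))
    pa_stop("target must be a load_deflection_curve", "pamech_invalid_curve")
  if (max(target$lbar) < 0.3)
    pa_stop("target curve must span lbar up to at least 0.3",
            "pamech_insufficient_data")
  if (any(bounds <= 0) || bounds[1L] >= bounds[2L])
    pa_stop("bounds must be a positive increasing interval",
            "pamech_invalid_material")
  o <- order(target$lbar)
  t_lbar <- target$lbar[o]
  t_pres <- target$pressure[o]
  p_top <- max(t_pres[t_lbar <= lbar_max + 1e-9])
  n_solves <- 0L

  model_curve <- function(E) {
    mat <- material_law(law_template$model, E = E, nu = law_template$nu)
    n_solves <<- n_solves + 1L
    res <- forward_curve(geom, mat, p_max = max(p_top, 3 * step),
                         step = step, stop_lbar = lbar_max * 1.125,
                         refine = refine)
    # a truncated sweep still supports the misfit if it spans enough of the
    # fit window; only a very short curve is a hard failure
    if (!res$completed && max(res$lbar) < lbar_max * 0.65 &&
        sum(res$pressure > 1e-12 & res$pressure <= p_top + 1e-9) < 3L)
      pa_stop(sprintf("forward model failed to converge at E = %.4g kPa", E),
              "pamech_nonconvergence")
    res
  }
  objective <- function(E) {
    res <- model_curve(E)
    sel <- res$pressure > 1e-12 & res$pressure <= p_top + 1e-9 &
      res$lbar <= lbar_max + 1e-9
    if (sum(sel) < 2L) sel <- res$pressure > 1e-12  # very stiff trial: use all
    lb_t <- approx(t_pres, t_lbar, xout = res$pressure[sel], ties = mean,
                   rule = 2)$y
    sum((res$lbar[sel] - lb_t)^2)
  }

  # seed from one solve: deflection scales like 1/E at fixed pressure
  E0 <- exp(mean(log(bounds)))
  r0 <- model_curve(E0)
  slope0 <- max(r0$lbar) / max(r0$pressure)
  slope_t <- max(t_lbar[t_lbar <= lbar_max + 1e-9]) / p_top
  E_seed <- min(max(E0 * slope0 / slope_t, bounds[1L]), bounds[2L])

  lo <- max(bounds[1L], E_seed / 1.7)
  hi <- min(bounds[2L], E_seed * 1.7)
  at_bound <- FALSE
  for (round in 1:6) {
    opt <- optimize(function(lE) objective(exp(lE)), c(log(lo), log(hi)),
                    tol = tol / (2 * max(E_seed, 1)))
    E_opt <- exp(opt$minimum)
    edge_lo <- (E_opt - lo) < 2 * tol
    edge_hi <- (hi - E_opt) < 2 * tol
    if (!edge_lo && !edge_hi) break
    if (edge_lo && lo <= bounds[1L] + 1e-12) { at_bound <- TRUE; break }
    if (edge_hi && hi >= bounds[2L] - 1e-12) { at_bound <- TRUE; break }
    if (edge_lo) lo <- max(bounds[1L], lo / 2)
    if (edge_hi) hi <- min(bounds[2L], hi * 2)
  }
  if (at_bound)
    warning(sprintf("fitted modulus %.4g kPa sits at a search bound", E_opt))
  structure(list(E_opt = E_opt, residual = opt$objective,
                 n_forward_solves = n_solves, converged = !at_bound),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> E = %.4g kPa (residual %.3g, %d forward solves%s)\n",
              x$E_opt, x$residual, x$n_forward_solves,
              if (x$converged) "" else ", at search bound"))
  invisible(x)
}
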