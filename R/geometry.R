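#' Bilayer wall and pipette geometry
#'
#' Geometry of the axisymmetric aspiration model: a cylinder of ventricular
#' wall (compact myocardium on top, perfectly bonded to an effective-medium
#' trabecular layer below) contacted by a rigid flat-tipped pipette on the
#' symmetry axis.
#'
#' @param t_c Compact layer thickness, mm.
#' @param t_tr Trabecular layer thickness, mm.
#' @param rho_tr Trabecular solid fraction in `(0, 1]`; the trabecular
#'   layer's material parameters are scaled by this fraction.
#' @param r_i Pipette inner radius, mm (default 0.050).
#' @param wall Pipette wall thickness, mm (default 0.035, outer radius 0.085).
#' @param fillet Pipette edge fillet radius, mm; kept for bookkeeping, the
#'   mesh resolves the edge by local grading rather than explicit fillet
#'   geometry.
#' @param r_domain Outer radius of the modeled tissue cylinder, mm.  The far
#'   edge is fully fixed; aspiration-induced fields decay well before it.
#' @return An object of class `wall_geometry`.
#' @export
wall_geometry <- function(t_c, t_tr, rho_tr = 1, r_i = 0.050, wall = 0.035,
                          fillet = 0.005, r_domain = 0.4) {
  vals <- c(t_c = t_c, t_tr = t_tr, r_i = r_i, wall = wall, r_domain = r_domain)
  if (any(!is.finite(vals)) || any(vals < 0) || r_i <= 0 || r_domain <= 0)
    pa_stop("all lengths must be finite and non-negative, r_i and r_domain positive",
            "pamech_invalid_geometry")
  if (t_c + t_tr <= 0)
    pa_stop("total wall thickness t_c + t_tr must be positive",
            "pamech_invalid_geometry")
  if (r_i + wall >= r_domain)
    pa_stop("pipette outer radius must lie inside the domain radius",
            "pamech_invalid_geometry")
  if (!is.finite(rho_tr) || rho_tr <= 0 || rho_tr > 1)
    pa_stop("trabecular solid fraction rho_tr must be in (0, 1]",
            "pamech_invalid_geometry")
  structure(list(t_c = t_c, t_tr = t_tr, rho_tr = rho_tr, r_i = r_i,
                 wall = wall, fillet = fillet, r_domain = r_domain),
            class = "wall_geometry")
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf("<wall_geometry> t_c = %.3g, t_tr = %.3g mm, rho_tr = %.3g; r_i = %.3g, wall = %.3g, r_domain = %.3g mm\n",
              x$t_c, x$t_tr, x$rho_tr, x$r_i, x$wall, x$r_domain))
  invisible(x)
}

#' Reference study-group presets
#'
#' Wall geometries (confocal-reconstruction means, shrinkage-corrected) and
#' fitted small-strain tangent moduli for the four modeled conditions of the
#' ED12.5 mouse study: control and PTA-mutant left and right ventricles.
#' These are the default conditions of the synthetic cohort generator and
#' the forward models.
#'
#' @return A named list (`control_LV`, `mutant_LV`, `control_RV`,
#'   `mutant_RV`), each entry holding a [wall_geometry] and the modulus `E`
#'   in kPa (Poisson's ratio 0.49 throughout).
#' @export
group_presets <- function() {
  list(
    control_LV = list(geom = wall_geometry(0.062, 0.314, 0.482), E = 5.78),
    mutant_LV  = list(geom = wall_geometry(0.047, 0.307, 0.513), E = 12.3),
    control_RV = list(geom = wall_geometry(0.066, 0.289, 0.405), E = 2.42),
    mutant_RV  = list(geom = wall_geometry(0.057, 0.274, 0.562), E = 9.48))
}

#' Reference measured strain-energy densities
#'
#' Cohort mean (standard error) strain energy density in kJ/m^3 for the three
#' tested epicardial locations at ED12.5, for both strain ranges, as measured
#' by pipette aspiration (n = 10 per group).  Used to calibrate the synthetic
#' cohorts and for ratio checks.
#'
#' @return A `data.frame` with columns `region`, `group`, `range`, `mean`, `se`.
#' @export
reference_sed <- function() {
  data.frame(
    region = rep(c("LV", "RV", "OFT"), each = 4L),
    group = rep(c("control", "mutant"), times = 6L),
    range = rep(rep(c(0.2, 0.4), each = 2L), times = 3L),
    mean = c(0.093, 0.208, 0.416, 0.701,
             0.037, 0.163, 0.177, 0.651,
             0.166, 0.143, 0.607, 0.606),
    se = c(0.021, 0.057, 0.091, 0.183,
           0.010, 0.032, 0.044, 0.135,
           0.050, 0.038, 0.147, 0.132),
    stringsAsFactors = FALSE)
}
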