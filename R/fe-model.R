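#' Build the axisymmetric aspiration finite-element model
#'
#' Meshes the r-z section of the bilayer wall with 6-node quadratic triangles
#' carrying a continuous linear pressure field (mixed displacement-pressure
#' formulation for the nearly-incompressible material), splits it into
#' compact and trabecular subdomains at `z = -t_c`, and scales the
#' trabecular subdomain's material parameters (`mu` and `kappa` alike, i.e.
#' `E` at fixed `nu`) by the trabecular solid fraction.  The mesh is graded
#' toward the pipette edge annulus where stress concentrates.
#'
#' Boundary conditions: symmetry on the axis, zero vertical displacement
#' with free radial sliding (roller) on the pipette-contact annulus, free
#' surface elsewhere on top, and a fully fixed outer edge.
#'
#' @param geom A [wall_geometry].
#' @param mat A [material_law].
#' @param refine Mesh refinement multiplier; 1 gives the default density
#'   (about 650 quadratic triangles), 2 halves the target element size.
#' @return An object of class `fe_model`.
#' @export
build_model <- function(geom, mat, refine = 1) {
  if (!inherits(geom, "wall_geometry"))
    pa_stop("geom must be a wall_geometry", "pamech_invalid_geometry")
  if (!inherits(mat, "material_law"))
    pa_stop("mat must be a material_law", "pamech_invalid_material")
  mesh <- pa_mesh(geom, refine)
  if (is.null(mesh$bele) || mesh$n_elements < 8L)
    pa_stop(sprintf("mesh generation failed (%d elements, no loaded surface)",
                    mesh$n_elements), "pamech_meshing_error")
  scale_e <- ifelse(mesh$trabecular, geom$rho_tr, 1)
  # Ramped vertical foundation over the fillet spans of the pipette tip:
  # stiffness per unit area rises linearly from 0 at the fillet start to an
  # effectively rigid value where flat contact begins, smearing the edge
  # fillet into a graded roller and removing the corner singularity of a
  # sharp free-to-pinned transition.
  f <- min(geom$fillet, geom$wall / 4)
  sele <- matrix(0L, 0L, 3L)
  skv <- matrix(0, 0L, 3L)
  skh <- numeric(0)
  if (f > 0) {
    r_o <- geom$r_i + geom$wall
    k_area <- 400 * mat$mu / f  # rigid against tractions of a few kPa
    for (e in seq_len(nrow(mesh$top_edges))) {
      nd <- mesh$top_edges[e, ]
      r_nd <- mesh$nodes[nd, 1L]
      inner <- r_nd > geom$r_i - 1e-12 & r_nd < geom$r_i + f + 1e-12
      outer <- r_nd > r_o - f - 1e-12 & r_nd < r_o + 1e-12
      if (!any(inner | outer)) next
      s <- pmax((r_nd - geom$r_i) / f * inner, (r_o - r_nd) / f * outer)
      s <- pmin(pmax(s, 0), 1)
      if (all(s * k_area <= 0)) next
      sele <- rbind(sele, nd)
      skv <- rbind(skv, k_area * s)
      skh <- c(skh, 30 * mat$mu * 2 * pi * mean(r_nd))
    }
  }
  structure(
    c(mesh,
      list(mu_e = mat$mu * scale_e, ka_e = mat$kappa * scale_e,
           model_code = if (mat$model == "neo-hookean") 0L else 1L,
           sele = sele, skv = skv, skh = skh, geom = geom, mat = mat,
           refine = refine)),
    class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %s, E = %.4g kPa: %d quadratic triangles, %d nodes, %d dofs (interface at z = %.4g mm)\n",
              x$mat$model, x$mat$E, x$n_elements, nrow(x$nodes), x$ndof,
              -x$geom$t_c))
  invisible(x)
}
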