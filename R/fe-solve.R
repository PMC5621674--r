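# Incremental-load Newton driver for the axisymmetric aspiration model.

# Precompute the reduced (free-dof) sparsity pattern and the mapping from
# assembly triplets to compressed-column slots, so each Newton iteration
# only aggregates values and refreshes K@x.
solver_context <- function(model, follower) {
  sys <- fe_system(model$nodes, model$tri, model$mu_e, model$ka_e,
                   model$model_code, model$pmap, model$np,
                   numeric(model$ndof), model$bele, 1e-3, follower, model$sele, model$skv, model$skh, TRUE)
  free <- model$free
  red <- integer(model$ndof)
  red[free] <- seq_along(free)
  ki <- red[sys$ti]
  kj <- red[sys$tj]
  keep <- ki > 0L & kj > 0L
  ki <- ki[keep]
  kj <- kj[keep]
  ord <- order(kj, ki)
  kis <- ki[ord]
  kjs <- kj[ord]
  n <- length(kis)
  newgrp <- c(TRUE, kis[-1L] != kis[-n] | kjs[-1L] != kjs[-n])
  ends <- c(which(newgrp)[-1L] - 1L, n)
  nf <- length(free)
  Kpat <- Matrix::sparseMatrix(i = kis[newgrp], j = kjs[newgrp],
                               x = numeric(sum(newgrp)), dims = c(nf, nf))
  ctx <- new.env(parent = emptyenv())
  ctx$keep <- keep
  ctx$ord <- ord
  ctx$ends <- ends
  ctx$Kpat <- Kpat
  ctx$flu <- NULL  # cached LU factorization, refreshed on demand
  ctx
}

# factorize the tangent at the current state
refactor <- function(model, sol, pload, follower, ctx) {
  sys <- fe_system(model$nodes, model$tri, model$mu_e, model$ka_e,
                   model$model_code, model$pmap, model$np, sol,
                   model$bele, pload, follower, model$sele, model$skv,
                   model$skh, TRUE)
  if (!isTRUE(sys$ok)) return(FALSE)
  txs <- sys$tx[ctx$keep][ctx$ord]
  cs <- cumsum(txs)[ctx$ends]
  K <- ctx$Kpat
  K@x <- cs - c(0, cs[-length(cs)])
  ctx$flu <- tryCatch(Matrix::lu(K), error = function(e) NULL)
  !is.null(ctx$flu)
}

# residual norm at a trial state, Inf when the mesh inverts
resid_norm <- function(model, sol, pload, follower) {
  sys <- fe_system(model$nodes, model$tri, model$mu_e, model$ka_e,
                   model$model_code, model$pmap, model$np, sol,
                   model$bele, pload, follower, model$sele, model$skv, model$skh, FALSE)
  if (!isTRUE(sys$ok)) return(Inf)
  sqrt(sum(sys$res[model$free]^2))
}

# One Newton solve at fixed load; returns list(sol, converged, iters).
# Modified Newton: the LU factorization cached in `ctx` is reused across
# iterations and load steps (the tangent changes slowly along the smooth
# load path) and refreshed at the current state whenever progress is poor;
# the convergence test always uses the exact residual.
newton_solve <- function(model, sol, pload, follower, tol, max_iter, ctx) {
  free <- model$free
  fresh <- FALSE
  n_refac <- 0L  # factorizations are the dominant cost: bound them per call
  rn_hist <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    sys <- fe_system(model$nodes, model$tri, model$mu_e, model$ka_e,
                     model$model_code, model$pmap, model$np, sol,
                     model$bele, pload, follower, model$sele, model$skv,
                     model$skh, FALSE)
    if (!isTRUE(sys$ok)) return(list(sol = sol, converged = FALSE, iters = it))
    r <- sys$res[free]
    fref <- max(sqrt(sum(sys$fext[free]^2)), 1e-12)
    rn_old <- sqrt(sum(r^2))
    if (rn_old <= tol * fref)
      return(list(sol = sol, converged = TRUE, iters = it - 1L))
    if (is.null(ctx$flu)) {
      if (n_refac >= 5L || !refactor(model, sol, pload, follower, ctx))
        return(list(sol = sol, converged = FALSE, iters = it))
      n_refac <- n_refac + 1L
      fresh <- TRUE
    }
    step_ok <- FALSE
    for (pass in 1:2) {
      d <- tryCatch(as.numeric(Matrix::solve(ctx$flu, -r)),
                    error = function(e) NULL)
      if (!is.null(d) && all(is.finite(d))) {
        # backtracking line search on the residual norm
        alpha <- 1
        trial <- sol
        for (ls in 1:8) {
          trial[free] <- sol[free] + alpha * d
          rn_new <- resid_norm(model, trial, pload, follower)
          if (rn_new < rn_old * (1 - 1e-4 * alpha) || rn_new <= tol * fref) break
          alpha <- alpha / 2
        }
        step_ok <- is.finite(rn_new) && rn_new < rn_old &&
          !(alpha < 0.02 && rn_new > 0.9 * rn_old)
      }
      if (step_ok || fresh) break
      # stale tangent made no progress: refactor at the current state
      if (n_refac >= 5L || !refactor(model, sol, pload, follower, ctx))
        return(list(sol = sol, converged = FALSE, iters = it))
      n_refac <- n_refac + 1L
      fresh <- TRUE
    }
    if (!step_ok) return(list(sol = sol, converged = FALSE, iters = it))
    sol <- trial
    rn_hist[it] <- rn_new
    # overall stagnation: refresh the tangent once more, then give up
    if (it >= 6L && rn_new > 0.5 * rn_hist[it - 5L]) {
      if (n_refac >= 4L) return(list(sol = sol, converged = FALSE, iters = it))
      ctx$flu <- NULL
    }
    # reuse pays off only while contraction is adequate
    if (rn_new > 0.5 * rn_old && !fresh) ctx$flu <- NULL
    fresh <- FALSE
  }
  # converged iff the final residual meets tolerance
  sys <- fe_system(model$nodes, model$tri, model$mu_e, model$ka_e,
                   model$model_code, model$pmap, model$np, sol,
                   model$bele, pload, follower, model$sele, model$skv,
                   model$skh, FALSE)
  conv <- isTRUE(sys$ok) && {
    fref <- max(sqrt(sum(sys$fext[free]^2)), 1e-12)
    sqrt(sum(sys$res[free]^2)) <= tol * fref
  }
  list(sol = sol, converged = conv, iters = max_iter)
}

#' Quasistatic pressure sweep of the aspiration model
#'
#' Increments the aspiration pressure from 0 to `p_max` in steps of `step`
#' (default 0 to 3.5 kPa in 0.2-kPa steps), solving large-deformation
#' quasistatic equilibrium at each level with full Newton iteration and
#' automatic step halving on divergence.  The suction acts as a follower
#' pressure (normal to the deformed surface) on the free surface inside the
#' pipette by default; `follower = FALSE` applies it along the reference
#' normal instead.
#'
#' @param model An [build_model()] result.
#' @param p_max Maximum aspiration pressure, kPa.
#' @param step Pressure increment, kPa.
#' @param stop_lbar Optional early stop: end the sweep after the first step
#'   whose normalized center deflection reaches this value.
#' @param follower Follower (deformed-normal) pressure load, default `TRUE`.
#' @param tol Relative Newton residual tolerance.
#' @param max_iter Newton iteration cap per load level.
#' @param store_fields Keep the converged displacement/pressure field of
#'   every step (needed for strain queries).
#' @return An object of class `fe_result` with per-step `pressure`,
#'   `deflection` (mm), `lbar`, convergence info and (optionally) the fields.
#' @export
solve_sweep <- function(model, p_max = 3.5, step = 0.2, stop_lbar = NULL,
                        follower = TRUE, tol = 1e-8, max_iter = 40,
                        store_fields = TRUE) {
  if (!inherits(model, "fe_model"))
    pa_stop("model must be an fe_model", "pamech_invalid_model")
  if (p_max <= 0 || step <= 0)
    pa_stop("p_max and step must be positive", "pamech_invalid_model")
  targets <- seq(step, p_max + 1e-12, by = step)
  if (p_max - targets[length(targets)] > 1e-9)
    targets <- c(targets, p_max)  # land exactly on p_max
  sol <- numeric(model$ndof)
  uz_dof <- 2L * model$apex_node
  pressures <- 0
  deflection <- 0
  fields <- if (store_fields) list(sol) else NULL
  p_cur <- 0
  all_ok <- TRUE
  ctx <- solver_context(model, follower)
  sol_prev <- sol
  p_prev <- 0
  predict_at <- function(p_new) {
    if (p_cur > p_prev)
      sol + (sol - sol_prev) * ((p_new - p_cur) / (p_cur - p_prev))
    else sol
  }
  try_level <- function(p_new) {
    start <- predict_at(p_new)
    res <- newton_solve(model, start, p_new, follower, tol, max_iter, ctx)
    if (!res$converged && !identical(start, sol))
      res <- newton_solve(model, sol, p_new, follower, tol, max_iter, ctx)
    res
  }
  for (p_t in targets) {
    # Substepping: always retry the full remaining increment after a
    # successful substep (large steps leap over sharp local folds of the
    # discretized path that small steps walk into), halving on divergence.
    # A stubborn fold triggers a rescue: converge beyond the target and
    # come back down onto it from above.
    p_sub <- p_t
    n_fail <- 0L
    n_rescue <- 0L
    while (p_cur < p_t - 1e-12) {
      res <- try_level(p_sub)
      if (res$converged) {
        sol_prev <- sol
        p_prev <- p_cur
        sol <- res$sol
        p_cur <- p_sub
        p_sub <- p_t
        next
      }
      n_fail <- n_fail + 1L
      if (n_fail > 16L) {
        all_ok <- FALSE
        break
      }
      if (n_rescue < 2L && (n_fail == 1L || p_sub - p_cur < step / 4)) {
        n_rescue <- n_rescue + 1L
        rescued <- FALSE
        for (jump in c(0.5, 1, 2, 3) * step) {
          r1 <- try_level(p_t + jump)
          if (r1$converged) {
            r2 <- newton_solve(model, r1$sol, p_t, follower, tol, max_iter, ctx)
            if (r2$converged) {
              sol_prev <- r1$sol
              p_prev <- p_t + jump
              sol <- r2$sol
              p_cur <- p_t
              rescued <- TRUE
              break
            }
          }
        }
        if (rescued) next
      }
      p_sub <- p_cur + (p_sub - p_cur) / 2
      if (p_sub - p_cur < step * 1e-3) {
        all_ok <- FALSE
        break
      }
    }
    if (!all_ok) {
      warning(sprintf(
        "Newton failed to converge beyond %.4g kPa (last converged step %.4g kPa)",
        p_t, pressures[length(pressures)]))
      break
    }
    pressures <- c(pressures, p_t)
    deflection <- c(deflection, sol[uz_dof])
    if (store_fields) fields[[length(fields) + 1L]] <- sol
    if (!is.null(stop_lbar) &&
        deflection[length(deflection)] / model$geom$r_i >= stop_lbar) break
  }
  structure(list(pressure = pressures, deflection = deflection,
                 lbar = deflection / model$geom$r_i,
                 fields = fields, model = model, follower = follower,
                 completed = all_ok),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  n <- length(x$pressure)
  cat(sprintf("<fe_result> %d load steps to %.3g kPa, lbar up to %.4g%s\n",
              n - 1L, max(x$pressure), max(x$lbar),
              if (x$completed) "" else " [sweep truncated]"))
  invisible(x)
}

#' Load-deflection curve of a converged sweep
#'
#' @param result An [solve_sweep()] result.
#' @return A [load_deflection_curve] of normalized center deflection at the
#'   axis node of the top surface versus aspiration pressure.
#' @export
load_deflection <- function(result) {
  if (!inherits(result, "fe_result"))
    pa_stop("load_deflection() expects an fe_result", "pamech_invalid_model")
  load_deflection_curve(result$lbar, result$pressure)
}

#' Green strain at a material point
#'
#' Green strain tensor components at the reference point `(r, z)` for one
#' stored load step, evaluated from the deformation gradient of the element
#' containing the point (on the axis the circumferential stretch uses the
#' l'Hopital limit).
#'
#' @param result An [solve_sweep()] result with stored fields.
#' @param step_index Index into the stored load steps (1 is the unloaded state).
#' @param r,z Reference coordinates in mm.
#' @return Named vector `E_rr`, `E_zz`, `E_tt`, `E_rz`.
#' @export
green_strain_at <- function(result, step_index, r, z) {
  if (is.null(result$fields))
    pa_stop("sweep was run with store_fields = FALSE", "pamech_invalid_model")
  model <- result$model
  loc <- locate_point(model, r, z)
  Fc <- fe_defgrad(model$nodes, model$tri, loc$elem, loc$l1, loc$l2,
                   result$fields[[step_index]])
  Frr <- Fc[1L]; Frz <- Fc[2L]; Fzr <- Fc[3L]; Fzz <- Fc[4L]; Fth <- Fc[5L]
  c(E_rr = (Frr^2 + Fzr^2 - 1) / 2,
    E_zz = (Frz^2 + Fzz^2 - 1) / 2,
    E_tt = (Fth^2 - 1) / 2,
    E_rz = (Frr * Frz + Fzr * Fzz) / 2)
}

#' Green strain at the bubble apex
#'
#' Green strain tensor components at the material point initially at the
#' center of the aspirated surface, `(r, z) = (0, 0)`, interpolated linearly
#' between the bracketing load steps to the requested normalized deflection.
#'
#' @param result An [solve_sweep()] result with stored fields.
#' @param lbar Normalized center deflection at which to report (e.g. 0.2, 0.4).
#' @return Named vector `E_rr`, `E_zz`, `E_tt`, `E_rz`.
#' @export
apex_strain <- function(result, lbar = 0.4) {
  lb <- result$lbar
  if (max(lb) < lbar)
    pa_stop(sprintf("sweep reaches lbar = %.4g, short of %.4g", max(lb), lbar),
            "pamech_range_exceeded")
  k <- which(lb >= lbar)[1L]
  if (k == 1L) return(green_strain_at(result, 1L, 0, 0))
  e1 <- green_strain_at(result, k - 1L, 0, 0)
  e2 <- green_strain_at(result, k, 0, 0)
  f <- (lbar - lb[k - 1L]) / (lb[k] - lb[k - 1L])
  e1 + f * (e2 - e1)
}

#' Strain decay profile
#'
#' Profile of a Green strain component along the depth direction (down the
#' symmetry axis from the surface apex) or the radial direction (outward
#' along the top surface), at the load step closest to the requested
#' normalized deflection, normalized by the apex value.
#'
#' @param result An [solve_sweep()] result with stored fields.
#' @param lbar Normalized center deflection of the reported state.
#' @param direction `"depth"` or `"radial"`.
#' @param component One of `"E_rr"`, `"E_zz"`, `"E_tt"`.
#' @param n Number of sample points.
#' @return A `data.frame` with `distance` (mm from the apex), `strain`, and
#'   `relative` (strain / apex strain).
#' @export
strain_profile <- function(result, lbar = 0.4,
                           direction = c("depth", "radial"),
                           component = "E_zz", n = 80) {
  direction <- match.arg(direction)
  lb <- result$lbar
  if (max(lb) < lbar)
    pa_stop(sprintf("sweep reaches lbar = %.4g, short of %.4g", max(lb), lbar),
            "pamech_range_exceeded")
  k <- which(lb >= lbar)[1L]
  geom <- result$model$geom
  eps <- 1e-6
  if (direction == "depth") {
    tt <- geom$t_c + geom$t_tr
    dist <- seq(0, tt * (1 - 1e-6), length.out = n)
    pts <- cbind(r = 0, z = -dist)
  } else {
    dist <- seq(0, geom$r_domain * (1 - 1e-6), length.out = n)
    pts <- cbind(r = dist, z = 0)
  }
  vals <- vapply(seq_len(n), function(i) {
    green_strain_at(result, k, pts[i, 1L], pts[i, 2L])[[component]]
  }, numeric(1))
  apex <- vals[1L]
  data.frame(distance = dist, strain = vals,
             relative = if (abs(apex) > 1e-300) vals / apex else vals)
}

# ---- forward-curve cache ----------------------------------------------------

fe_cache_key <- function(geom, mat, refine, p_max, step, stop_lbar, follower) {
  paste(format(c(geom$t_c, geom$t_tr, geom$rho_tr, geom$r_i, geom$wall,
                 geom$r_domain, mat$E, mat$nu, refine, p_max, step,
                 stop_lbar %||% -1, as.numeric(follower)),
               digits = 15),
        mat$model, collapse = "|")
}

#' Forward load-deflection curve, cached
#'
#' Builds the model, runs [solve_sweep()], and caches the result in the
#' package session cache keyed by geometry, material and solver settings, so
#' repeated identical sweeps (inverse fits, cohort simulation, statistics
#' replicates) are computed once per session.
#'
#' @param geom A [wall_geometry].
#' @param mat A [material_law].
#' @param refine Mesh refinement multiplier.
#' @param store_fields Keep per-step fields in the cached result.
#' @inheritParams solve_sweep
#' @return The cached [solve_sweep()] `fe_result`.
#' @export
forward_curve <- function(geom, mat, p_max = 3.5, step = 0.2,
                          stop_lbar = NULL, follower = TRUE, refine = 1,
                          store_fields = FALSE) {
  key <- fe_cache_key(geom, mat, refine, p_max, step, stop_lbar, follower)
  hit <- .pamech_cache[[key]]
  if (!is.null(hit) && (!store_fields || !is.null(hit$fields))) {
    .pamech_cache$n_hits <- (.pamech_cache$n_hits %||% 0) + 1
    return(hit)
  }
  model <- build_model(geom, mat, refine = refine)
  res <- solve_sweep(model, p_max = p_max, step = step, stop_lbar = stop_lbar,
                     follower = follower, store_fields = store_fields)
  .pamech_cache[[key]] <- res
  .pamech_cache$n_solves <- (.pamech_cache$n_solves %||% 0) + 1
  res
}

#' Clear the forward-solve session cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_fe_cache <- function() {
  n <- length(ls(.pamech_cache))
  rm(list = ls(.pamech_cache), envir = .pamech_cache)
  invisible(n)
}
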