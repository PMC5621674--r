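# Synthetic cohort generator: inverts the measurement chain through the
# forward model so every analysis stage is testable without raw recordings.

#' Default synthetic cohort specification
#'
#' The generator's default conditions mirror the study design: four
#' group/region conditions (control and mutant, LV and RV) with the
#' reference wall geometries and fitted moduli, n = 10 specimens each, a
#' quasistatic vacuum ramp of 0.4 kPa/s sampled at 15 Hz, additive Gaussian
#' measurement noise on the tracked deflection (sigma = 0.0005 mm, about 1%
#' of the pipette radius), and per-specimen lognormal jitter on the modulus
#' (sigma_log = 0.25) for biological variability.
#'
#' @param n Specimens per condition.
#' @param sigma Deflection measurement noise SD, mm.
#' @param sigma_log Lognormal SD of the per-specimen modulus jitter.
#' @param ramp_rate Pressure ramp rate, kPa/s.
#' @param sample_rate Sampling rate, Hz.
#' @param lbar_stop The ramp stops once the aspirated length reaches this
#'   normalized value (the operator aspirates past the analyzed range).
#' @param p_cap Hard pressure cap, kPa.
#' @return A list of per-condition entries (`group`, `region`, `geom`, `E`,
#'   plus the shared ramp/noise settings).
#' @export
default_cohort_spec <- function(n = 10, sigma = 5e-4, sigma_log = 0.25,
                                ramp_rate = 0.4, sample_rate = 15,
                                lbar_stop = 0.5, p_cap = 8) {
  gp <- group_presets()
  conds <- list(
    list(group = "control", region = "LV", geom = gp$control_LV$geom, E = gp$control_LV$E),
    list(group = "mutant",  region = "LV", geom = gp$mutant_LV$geom,  E = gp$mutant_LV$E),
    list(group = "control", region = "RV", geom = gp$control_RV$geom, E = gp$control_RV$E),
    list(group = "mutant",  region = "RV", geom = gp$mutant_RV$geom,  E = gp$mutant_RV$E))
  lapply(conds, function(cd) {
    c(cd, list(n = n, sigma = sigma, sigma_log = sigma_log,
               ramp_rate = ramp_rate, sample_rate = sample_rate,
               lbar_stop = lbar_stop, p_cap = p_cap))
  })
}

validate_spec_entry <- function(entry) {
  if (entry$n < 1 || entry$sigma < 0 || entry$sigma_log < 0 ||
      entry$ramp_rate <= 0 || entry$sample_rate <= 0 || entry$E <= 0)
    pa_stop("invalid cohort spec entry", "pamech_invalid_spec")
  invisible(entry)
}

# group-level forward curve (cached); covers lbar slightly past the stop
base_group_curve <- function(entry, refine = 1) {
  mat <- material_law("neo-hookean", E = entry$E)
  forward_curve(entry$geom, mat, p_max = entry$p_cap, step = 0.2,
                stop_lbar = entry$lbar_stop * 1.04, refine = refine)
}

#' Simulate one aspiration trace
#'
#' Draws one specimen from a cohort condition: the specimen's modulus is the
#' condition modulus times a lognormal jitter factor, its noise-free
#' deflection follows the forward finite-element load-deflection curve
#' (hyperelastic scale invariance maps the group curve exactly onto any
#' jittered modulus: the deformation at pressure `p` under modulus `f*E`
#' equals the deformation at `p/f` under `E`), and iid Gaussian measurement
#' noise is added to the tracked deflection.  The ramp ends once the
#' normalized deflection passes `lbar_stop`.
#'
#' @param entry One condition entry of [default_cohort_spec()].
#' @param seed Integer seed for this specimen; `NULL` uses the current RNG
#'   stream.
#' @param specimen Specimen id label.
#' @param refine Mesh refinement of the underlying forward solve.
#' @return An [aspiration_trace].
#' @export
simulate_trace <- function(entry, seed = NULL, specimen = "s1", refine = 1) {
  validate_spec_entry(entry)
  base <- base_group_curve(entry, refine = refine)
  with_seed(seed, {
    # lognormal biological jitter, truncated at 2 sigma so every specimen's
    # ramp can span the analyzed deformation range within the pressure cap
    z <- if (entry$sigma_log > 0) rnorm(1, 0, entry$sigma_log) else 0
    f <- exp(max(min(z, 2 * entry$sigma_log), -2 * entry$sigma_log))
    # pressure at which this specimen passes the stop length
    lb_max_base <- max(base$lbar)
    lb_stop <- min(entry$lbar_stop, lb_max_base)
    p_stop_base <- approx(base$lbar, base$pressure, xout = lb_stop,
                          ties = mean)$y
    p_stop <- min(f * p_stop_base, entry$p_cap)
    dt <- 1 / entry$sample_rate
    n_samp <- max(4L, ceiling(p_stop / entry$ramp_rate / dt) + 1L)
    time <- (seq_len(n_samp) - 1L) * dt
    pressure <- entry$ramp_rate * time
    lbar <- approx(base$pressure, base$lbar, xout = pressure / f,
                   ties = mean, rule = 2)$y
    deflection <- lbar * entry$geom$r_i
    if (entry$sigma > 0)
      deflection <- deflection + rnorm(n_samp, 0, entry$sigma)
    aspiration_trace(time, pressure, deflection, r_i = entry$geom$r_i,
                     specimen = specimen, region = entry$region,
                     group = entry$group)
  })
}

#' Simulate full cohorts to disk
#'
#' Writes `n` traces per condition as delimited text plus a JSON manifest
#' consumable by [sed_table()].  All randomness flows from the one `seed`;
#' per-specimen seeds are drawn from it and recorded in the manifest.
#'
#' @param spec A cohort spec, default [default_cohort_spec()].
#' @param outdir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param refine Mesh refinement of the forward solves.
#' @return The manifest list, invisibly; manifest JSON is written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
simulate_cohorts <- function(spec = default_cohort_spec(), outdir, seed = 1,
                             refine = 1) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    pa_stop(sprintf("cannot create output directory '%s'", outdir),
            "pamech_filesystem_error")
  total <- sum(vapply(spec, function(e) e$n, numeric(1)))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  rows <- list()
  k <- 0L
  for (entry in spec) {
    validate_spec_entry(entry)
    for (i in seq_len(entry$n)) {
      k <- k + 1L
      id <- sprintf("%s_%s_%02d", entry$group, entry$region, i)
      tr <- simulate_trace(entry, seed = seeds[k], specimen = id,
                           refine = refine)
      fn <- paste0(id, ".csv")
      write_trace(tr, file.path(outdir, fn))
      rows[[k]] <- data.frame(file = fn, specimen = id, region = entry$region,
                              group = entry$group, seed = seeds[k],
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- list(seed = seed, files = do.call(rbind, rows))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a binary voxel stack with a planted solid fraction
#'
#' Generates a spatially correlated random blob field (white noise smoothed
#' with a separable box kernel) and thresholds it at the quantile giving the
#' requested solid fraction, emulating a trabecular meshwork of the stated
#' density.
#'
#' @param shape Integer vector of stack dimensions.
#' @param target_fraction Solid fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @param voxel Voxel size, mm.
#' @param smooth Half-width of the smoothing kernel in voxels.
#' @return A [voxel_stack]; realized fraction within 0.005 of the target.
#' @export
simulate_voxel_stack <- function(shape = c(48, 48, 32), target_fraction = 0.5,
                                 seed = NULL, voxel = c(0.01, 0.01, 0.002),
                                 smooth = 2) {
  if (target_fraction <= 0 || target_fraction >= 1)
    pa_stop("target_fraction must be in (0, 1)", "pamech_invalid_spec")
  nvox <- prod(shape)
  if (nvox < 1 / 0.005)
    pa_stop(sprintf("stack of %d voxels cannot resolve a fraction to 0.005", nvox),
            "pamech_resolution_error")
  field <- with_seed(seed, array(rnorm(nvox), dim = shape))
  if (smooth > 0) {
    slice_axis <- function(a, ax, idx) {
      switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
             a[, , idx, drop = FALSE])
    }
    for (ax in 1:3) {
      n <- shape[ax]
      acc <- array(0, shape)
      for (off in -smooth:smooth) {
        idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicated edges
        acc <- acc + slice_axis(field, ax, idx)
      }
      field <- acc / (2 * smooth + 1)
    }
  }
  thr <- quantile(field, 1 - target_fraction, names = FALSE)
  voxel_stack(array(field > thr, dim = shape), voxel)
}
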