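#' Strain energy density of a load-deflection curve
#'
#' Trapezoidal integral of aspiration pressure over the normalized aspirated
#' length, from 0 up to `lbar_max`.  The pressure-lbar product is
#' kPa x (dimensionless), numerically equal to kJ/m^3: the energy per unit
#' volume stored by the aspiration, used as a model-free stiffness metric.
#' Individual trapezoids are summed between successive sample pairs in time
#' order (signed, so measurement jitter cancels rather than inflating the
#' area), and the pressure at exactly `lbar = lbar_max` is obtained by linear
#' interpolation between the bracketing samples so the result does not depend
#' on sampling phase.
#'
#' @param curve A [load_deflection_curve] starting at `lbar = 0`.
#' @param lbar_max Upper integration limit; the conventional ranges are 0.2
#'   (maximum surface strains roughly 0.04-0.06) and 0.4 (roughly 0.12-0.16).
#' @return Strain energy density in kJ/m^3.
#' @export
compute_sed <- function(curve, lbar_max = 0.4) {
  if (!inherits(curve, "load_deflection_curve"))
    pa_stop("compute_sed() expects a load_deflection_curve", "pamech_invalid_curve")
  if (!is.numeric(lbar_max) || length(lbar_max) != 1L || lbar_max < 0)
    pa_stop("lbar_max must be a single non-negative number", "pamech_invalid_curve")
  if (lbar_max == 0) return(0)
  lb <- curve$lbar
  pr <- curve$pressure
  mx <- max(lb)
  if (mx < lbar_max)
    pa_stop(sprintf(
      "curve reaches lbar = %.4g, short of the requested %.4g by %.4g",
      mx, lbar_max, lbar_max - mx), "pamech_range_exceeded")
  k <- which(lb >= lbar_max)[1L]
  if (k == 1L) {
    # first sample already at/beyond the limit: single trapezoid from origin
    return(lbar_max * pr[1L] / 2)
  }
  if (lb[k] > lbar_max) {
    f <- (lbar_max - lb[k - 1L]) / (lb[k] - lb[k - 1L])
    pe <- pr[k - 1L] + f * (pr[k] - pr[k - 1L])
    lb <- c(lb[seq_len(k - 1L)], lbar_max)
    pr <- c(pr[seq_len(k - 1L)], pe)
  } else {
    lb <- lb[seq_len(k)]
    pr <- pr[seq_len(k)]
  }
  trapz(lb, pr)
}

#' Linear or quadratic trend fit to a load-deflection curve
#'
#' Ordinary least-squares polynomial fit of pressure on `lbar`, restricted to
#' `lbar` within `lbar_range` (default 0-0.4, the range over which the
#' aspiration data are analyzed).  R^2 is defined as
#' `1 - SS_res / SS_tot` about the mean for both degrees.
#'
#' @param curve A [load_deflection_curve].
#' @param degree 1 (linear) or 2 (quadratic).
#' @param lbar_range Restriction window on `lbar`.
#' @return A list with `coefficients` (ascending powers), `r2`, and `n`.
#' @export
fit_trend <- function(curve, degree = 1, lbar_range = c(0, 0.4)) {
  if (!inherits(curve, "load_deflection_curve"))
    pa_stop("fit_trend() expects a load_deflection_curve", "pamech_invalid_curve")
  if (!degree %in% c(1, 2))
    pa_stop("degree must be 1 or 2", "pamech_invalid_curve")
  sel <- curve$lbar >= lbar_range[1L] & curve$lbar <= lbar_range[2L]
  x <- curve$lbar[sel]
  y <- curve$pressure[sel]
  if (length(x) < degree + 2L)
    pa_stop(sprintf("need at least %d points in lbar range [%g, %g], got %d",
                    degree + 2L, lbar_range[1L], lbar_range[2L], length(x)),
            "pamech_insufficient_data")
  fit <- lm(y ~ stats::poly(x, degree, raw = TRUE))
  ssres <- sum(fit$residuals^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot <= 1e-300) as.numeric(ssres <= 1e-300) else 1 - ssres / sstot
  list(coefficients = unname(coef(fit)), r2 = max(0, min(1, r2)), n = length(x))
}

#' Per-test stiffness summary
#'
#' Computes the standard per-test metrics from one trace: strain energy
#' density over `lbar` 0-0.2 and 0-0.4, the linear slope (kPa per unit
#' `lbar`), and the linear and quadratic R^2 over 0-0.4.
#'
#' @param trace An [aspiration_trace] (or an already normalized
#'   [load_deflection_curve] plus explicit metadata).
#' @param specimen,region,group Metadata overrides when `trace` is a curve.
#' @return A one-row `data.frame` with columns `specimen`, `region`, `group`,
#'   `sed_02`, `sed_04`, `slope`, `r2_lin`, `r2_quad`.
#' @export
sed_summary <- function(trace, specimen = NULL, region = NULL, group = NULL) {
  if (inherits(trace, "aspiration_trace")) {
    curve <- normalize_trace(trace)
    specimen <- specimen %||% trace$specimen
    region <- region %||% trace$region
    group <- group %||% trace$group
  } else if (inherits(trace, "load_deflection_curve")) {
    curve <- trace
    specimen <- specimen %||% "s1"
    region <- region %||% "LV"
    group <- group %||% "control"
  } else {
    pa_stop("sed_summary() expects a trace or a curve", "pamech_invalid_trace")
  }
  lin <- fit_trend(curve, 1)
  quad <- fit_trend(curve, 2)
  data.frame(specimen = specimen, region = region, group = group,
             sed_02 = compute_sed(curve, 0.2),
             sed_04 = compute_sed(curve, 0.4),
             slope = lin$coefficients[2L],
             r2_lin = lin$r2, r2_quad = quad$r2,
             stringsAsFactors = FALSE)
}

#' Summarize a cohort of trace files into a SED table
#'
#' Reads every trace listed in a cohort manifest (JSON, as written by
#' [simulate_cohorts()]), computes the per-test summary, and optionally
#' writes the combined table as CSV.
#'
#' @param manifest Path to a manifest JSON file, or an already-parsed
#'   manifest list with a `files` data frame (columns `file`, `specimen`,
#'   `region`, `group`).
#' @param out Optional output CSV path.
#' @return A `data.frame`, one row per test.
#' @export
sed_table <- function(manifest, out = NULL) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  } else {
    dir <- "."
  }
  files <- as.data.frame(manifest$files, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(files)), function(i) {
    path <- files$file[i]
    if (!file.exists(path)) path <- file.path(dir, files$file[i])
    tr <- read_trace(path, specimen = files$specimen[i],
                     region = files$region[i], group = files$group[i])
    sed_summary(tr)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  tab
}
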