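#' Construct a pipette-aspiration trace
#'
#' One recorded (or simulated) aspiration test: a quasistatic suction ramp
#' applied through a flat-tipped pipette sealed to the tissue surface, with
#' the center aspirated length tracked over time.
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param pressure Aspiration (suction) pressure in kPa, positive for vacuum;
#'   the first sample is expected to sit near 0.
#' @param deflection Center aspirated length `L` in mm at each sample.
#' @param r_i Pipette inner radius in mm (default 0.050, a 0.100-mm ID
#'   borosilicate pipette).
#' @param specimen,region,group Metadata labels; `region` is one of
#'   `"LV"`, `"RV"`, `"OFT"`, `group` one of `"control"`, `"mutant"`.
#' @param baseline_tol Tolerance (kPa) for the zero-pressure start check.
#' @return An object of class `aspiration_trace`.
#' @export
aspiration_trace <- function(time, pressure, deflection, r_i = 0.050,
                             specimen = "s1", region = "LV",
                             group = "control", baseline_tol = 0.05) {
  if (!is.numeric(r_i) || length(r_i) != 1L || !is.finite(r_i) || r_i <= 0)
    pa_stop("pipette inner radius r_i must be a single positive number",
            "pamech_invalid_geometry")
  n <- length(time)
  if (n < 4L)
    pa_stop(sprintf("a trace needs at least 4 samples, got %d", n),
            "pamech_insufficient_data")
  if (length(pressure) != n || length(deflection) != n)
    pa_stop("time, pressure and deflection must have equal length",
            "pamech_insufficient_data")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    pa_stop("time must be finite and strictly increasing", "pamech_invalid_trace")
  if (any(!is.finite(deflection)) || any(!is.finite(pressure)))
    pa_stop("pressure and deflection must be finite", "pamech_invalid_trace")
  if (abs(pressure[1L]) > baseline_tol)
    warning(sprintf("first pressure sample is %.3g kPa, not near 0", pressure[1L]))
  structure(
    list(time = as.numeric(time), pressure = as.numeric(pressure),
         deflection = as.numeric(deflection), r_i = r_i,
         specimen = as.character(specimen), region = as.character(region),
         group = as.character(group)),
    class = "aspiration_trace")
}

#' @export
print.aspiration_trace <- function(x, ...) {
  cat(sprintf("<aspiration_trace> %s %s/%s: %d samples, %.3g-%.3g kPa, r_i = %.3g mm\n",
              x$specimen, x$region, x$group, length(x$time),
              min(x$pressure), max(x$pressure), x$r_i))
  invisible(x)
}

#' Construct a load-deflection curve
#'
#' Aspiration pressure as a function of the normalized aspirated length
#' `lbar = L / r_i`; the central analysis object for both the
#' strain-energy-density metric and the inverse finite-element fit.
#'
#' @param lbar Dimensionless normalized aspirated length.
#' @param pressure Aspiration pressure in kPa, same length as `lbar`.
#' @param degenerate Flag: curve carries no deformation signal.
#' @param nonmonotone Flag: `lbar` backtracks by more than 5% of its range.
#' @return An object of class `load_deflection_curve`.
#' @export
load_deflection_curve <- function(lbar, pressure, degenerate = FALSE,
                                  nonmonotone = FALSE) {
  if (length(lbar) < 2L || length(pressure) != length(lbar))
    pa_stop("a curve needs at least 2 (lbar, pressure) pairs of equal length",
            "pamech_insufficient_data")
  structure(list(lbar = as.numeric(lbar), pressure = as.numeric(pressure),
                 degenerate = isTRUE(degenerate),
                 nonmonotone = isTRUE(nonmonotone)),
            class = "load_deflection_curve")
}

#' @export
print.load_deflection_curve <- function(x, ...) {
  cat(sprintf("<load_deflection_curve> %d points, lbar 0-%.3g, pressure %.3g-%.3g kPa%s%s\n",
              length(x$lbar), max(x$lbar), min(x$pressure), max(x$pressure),
              if (x$degenerate) " [degenerate]" else "",
              if (x$nonmonotone) " [nonmonotone]" else ""))
  invisible(x)
}

#' @export
plot.load_deflection_curve <- function(x, ...,
                                       xlab = expression(bar(L) == L / r[i]),
                                       ylab = "aspiration pressure (kPa)",
                                       type = "l") {
  graphics::plot(x$lbar, x$pressure, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' Normalize an aspiration trace into a load-deflection curve
#'
#' Removes the first-sample baseline from both pressure and deflection so the
#' curve starts at (0, 0), then divides the deflection by the pipette inner
#' radius.  Samples are kept in time order; measurement jitter may make
#' `lbar` locally non-monotone, which downstream integration handles with
#' signed trapezoids.  Curves whose `lbar` backtracks by more than 5% of its
#' range are flagged `nonmonotone`; curves with (numerically) no deflection
#' signal are flagged `degenerate`.
#'
#' @param trace An [aspiration_trace].
#' @return A [load_deflection_curve].
#' @export
normalize_trace <- function(trace) {
  if (!inherits(trace, "aspiration_trace"))
    pa_stop("normalize_trace() expects an aspiration_trace", "pamech_invalid_trace")
  lbar <- (trace$deflection - trace$deflection[1L]) / trace$r_i
  pressure <- trace$pressure - trace$pressure[1L]
  rng <- diff(range(lbar))
  degenerate <- rng <= 1e-12
  backtrack <- if (degenerate) 0 else max(0, -min(diff(lbar)))
  nonmonotone <- !degenerate && backtrack > 0.05 * rng
  load_deflection_curve(lbar, pressure, degenerate = degenerate,
                        nonmonotone = nonmonotone)
}

#' Write an aspiration trace to delimited text
#'
#' One file per test: `#`-prefixed metadata comment lines followed by a
#' header row `time_s,pressure_kPa,deflection_mm`.
#'
#' @param trace An [aspiration_trace].
#' @param path Output file path (`.csv` comma-separated, `.tsv` tab-separated).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# specimen: %s", trace$specimen),
               sprintf("# region: %s", trace$region),
               sprintf("# group: %s", trace$group),
               sprintf("# r_i_mm: %.17g", trace$r_i)), con)
  writeLines(paste(c("time_s", "pressure_kPa", "deflection_mm"), collapse = sep), con)
  writeLines(paste(format(trace$time, digits = 17, trim = TRUE),
                   format(trace$pressure, digits = 17, trim = TRUE),
                   format(trace$deflection, digits = 17, trim = TRUE),
                   sep = sep), con)
  invisible(path)
}

#' Read an aspiration trace from delimited text
#'
#' Accepts the dialect written by [write_trace()]: `#` comment lines carrying
#' `specimen`, `region`, `group` and `r_i_mm` metadata, then a header row and
#' comma- or tab-separated columns `time_s`, `pressure_kPa`, `deflection_mm`.
#' Metadata arguments override values found in the file.
#'
#' @param path Input file.
#' @param r_i,specimen,region,group Optional metadata overrides.
#' @return An [aspiration_trace].
#' @export
read_trace <- function(path, r_i = NULL, specimen = NULL, region = NULL,
                       group = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    pa_stop(sprintf("no data rows in '%s'", path), "pamech_insufficient_data")
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  df <- read.csv(text = paste(body, collapse = "\n"), sep = sep)
  need <- c("time_s", "pressure_kPa", "deflection_mm")
  if (!all(need %in% names(df)))
    pa_stop(sprintf("'%s' lacks columns %s", path,
                    paste(setdiff(need, names(df)), collapse = ", ")),
            "pamech_invalid_trace")
  aspiration_trace(
    time = df$time_s, pressure = df$pressure_kPa, deflection = df$deflection_mm,
    r_i = r_i %||% as.numeric(meta[["r_i_mm"]] %||% 0.050),
    specimen = specimen %||% (meta[["specimen"]] %||% "s1"),
    region = region %||% (meta[["region"]] %||% "LV"),
    group = group %||% (meta[["group"]] %||% "control"))
}
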