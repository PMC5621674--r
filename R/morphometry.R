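#' Shrinkage and foreshortening correction of measured dimensions
#'
#' Cleared-tissue imaging underestimates true dimensions: optical clearing
#' shrinks the tissue isotropically by 20%, and refractile foreshortening
#' compresses the optical z-axis by a further 19%.  Raw in-plane lengths are
#' therefore divided by 0.80, and raw z lengths by 0.80 and then by 0.81.
#'
#' @param raw Named numeric vector of raw lengths in mm; names taken from
#'   `axis`.
#' @param axis Character vector, one of `"x"`, `"y"`, `"z"` per entry.
#' @return Corrected lengths, mm.
#' @export
correct_dimensions <- function(raw, axis = names(raw)) {
  if (any(!is.finite(raw)) || any(raw <= 0))
    pa_stop("raw lengths must be positive and finite", "pamech_invalid_length")
  if (is.null(axis) || !all(axis %in% c("x", "y", "z")))
    pa_stop("each entry needs an axis label in {x, y, z}", "pamech_invalid_length")
  f <- dimension_correction_factors()
  unname(raw) * unname(f[axis])
}

#' Per-axis and volumetric correction factors
#'
#' @return Named vector with the multiplicative correction factors for `x`,
#'   `y`, `z` lengths and for a `volume` (their product).
#' @export
dimension_correction_factors <- function() {
  xy <- 1 / 0.80
  z <- 1 / 0.80 / 0.81
  c(x = xy, y = xy, z = z, volume = xy * xy * z)
}

#' Construct a voxel stack
#'
#' @param data 3-D array; non-zero / `TRUE` voxels are tissue (foreground).
#'   Integer-labeled arrays are accepted for chamber masks.
#' @param voxel Voxel size `(dx, dy, dz)` in mm.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, voxel = c(0.01, 0.01, 0.002)) {
  if (!is.array(data) || length(dim(data)) != 3L || !length(data))
    pa_stop("data must be a non-empty 3-D array", "pamech_invalid_stack")
  if (length(voxel) != 3L || any(!is.finite(voxel)) || any(voxel <= 0))
    pa_stop("voxel sizes must be three positive numbers", "pamech_invalid_stack")
  structure(list(data = data, voxel = as.numeric(voxel)), class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_stack> %d x %d x %d voxels of %.4g x %.4g x %.4g mm, %.1f%% foreground\n",
              d[1L], d[2L], d[3L], x$voxel[1L], x$voxel[2L], x$voxel[3L],
              100 * mean(x$data != 0)))
  invisible(x)
}

as_roi <- function(stack, roi) {
  d <- dim(stack$data)
  if (is.null(roi)) {
    roi <- lapply(d, seq_len)
  } else {
    if (!is.list(roi) || length(roi) != 3L)
      pa_stop("roi must be a list of three index vectors", "pamech_empty_region")
    for (k in 1:3)
      if (length(roi[[k]]) && (min(roi[[k]]) < 1L || max(roi[[k]]) > d[k]))
        pa_stop("roi exceeds stack bounds", "pamech_out_of_domain")
  }
  if (!all(lengths(roi) > 0L))
    pa_stop("roi selects no voxels", "pamech_empty_region")
  roi
}

#' Trabecular solid fraction of a binary stack
#'
#' Fraction of foreground (tissue) voxels within a region of interest: the
#' extent of solid tissue as a proportion of the total volume occupied by
#' the trabecular meshwork.
#'
#' @param stack A [voxel_stack] with binary foreground.
#' @param roi Optional region of interest: a list of three index vectors
#'   (rows, columns, slices); default is the whole stack.
#' @return Fraction in `[0, 1]`.
#' @export
solid_fraction <- function(stack, roi = NULL) {
  if (!inherits(stack, "voxel_stack"))
    pa_stop("solid_fraction() expects a voxel_stack", "pamech_invalid_stack")
  roi <- as_roi(stack, roi)
  sub <- stack$data[roi[[1L]], roi[[2L]], roi[[3L]], drop = FALSE]
  mean(sub != 0)
}

#' Chamber volume from a labeled mask
#'
#' Volume of one labeled chamber: labeled voxel count times the voxel
#' volume, optionally corrected for clearing shrinkage and z-foreshortening
#' (the default, since masks are measured in raw image coordinates).
#'
#' @param stack A [voxel_stack] whose data holds integer labels.
#' @param label Label value to measure.
#' @param corrected Apply the volumetric correction factor (default `TRUE`).
#' @return Volume in mm^3.
#' @export
chamber_volume <- function(stack, label = 1, corrected = TRUE) {
  if (!inherits(stack, "voxel_stack"))
    pa_stop("chamber_volume() expects a voxel_stack", "pamech_invalid_stack")
  present <- unique(as.vector(stack$data))
  if (!label %in% present)
    pa_stop(sprintf("label %s not present in the mask", format(label)),
            "pamech_label_error")
  n <- sum(stack$data == label)
  v <- n * prod(stack$voxel)
  if (corrected) v <- v * dimension_correction_factors()[["volume"]]
  v
}

#' Read a multi-page TIFF binary mask
#'
#' @param path TIFF file, one page per z-slice.
#' @param voxel Voxel size `(dx, dy, dz)` in mm.
#' @param threshold Foreground threshold on the normalized gray value.
#' @return A [voxel_stack] with logical foreground.
#' @export
read_mask_tiff <- function(path, voxel = c(0.01, 0.01, 0.002),
                           threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p
  }, matrix(0, nrow(pages[[1L]]), ncol(pages[[1L]])))
  voxel_stack(arr > threshold, voxel)
}

#' Write a binary stack as multi-page TIFF
#'
#' @param stack A [voxel_stack].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(stack, path) {
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3L]), function(k) {
    matrix(as.numeric(stack$data[, , k] != 0), d[1L], d[2L])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
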