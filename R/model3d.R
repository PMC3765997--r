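#' Build a dense 3D model by linear interpolation between slices
#'
#' For every pixel column, the value at fractional position `t` between
#' consecutive slice centers `i` and `i+1` is `(1 - t) * a + t * b`, so the
#' original slice planes are reproduced exactly at `t = 0, 1`. Each
#' inter-slice interval is subdivided into `z_refinement` equal steps,
#' giving `(n_slices - 1) * z_refinement + 1` refined planes spanning the
#' first to the last slice center (no extrapolation beyond either).
#'
#' @param stack A `pat_image_stack` (masks or raw intensities) with at least
#'   2 slices.
#' @param z_refinement Integer >= 1, sub-steps per inter-slice interval
#'   (default 8: sub-millimetre axial sampling at 6 mm slice spacing).
#' @return A `pat_model3d` with continuous occupancy in the range of the
#'   input values.
#' @examples
#' s <- image_stack(array(c(0, 1), c(1, 1, 2)), c(1, 1), slice_thickness = 6)
#' m <- interpolate_between_slices(s, z_refinement = 2)
#' m$occupancy[1, 1, ]  # 0, 0.5, 1
#' @export
interpolate_between_slices <- function(stack, z_refinement = 8L) {
  stopifnot(inherits(stack, "pat_image_stack"))
  z_refinement <- as.integer(z_refinement)
  if (z_refinement < 1L) abort("`z_refinement` must be >= 1")
  ns <- n_slices(stack)
  if (ns < 2L)
    abort(paste0("interpolation needs >= 2 slices; for a single slice use ",
                 "area x slice thickness (see `mask_stack_volume()`)"))
  d <- dim(stack$data)
  np <- (ns - 1L) * z_refinement + 1L
  occ <- array(0, c(d[1], d[2], np))
  for (i in seq_len(ns - 1L)) {
    a <- stack$data[, , i]; b <- stack$data[, , i + 1L]
    base <- (i - 1L) * z_refinement
    for (j in 0:(z_refinement - 1L)) {
      t <- j / z_refinement
      occ[, , base + j + 1L] <- (1 - t) * a + t * b
    }
  }
  occ[, , np] <- stack$data[, , ns]
  structure(
    list(occupancy = occ, z_refinement = z_refinement,
         geometry = geometry_of(stack), n_source_slices = ns,
         binary = FALSE, binarization_threshold = NA_real_),
    class = "pat_model3d")
}

#' @export
print.pat_model3d <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<pat_model3d> %d x %d x %d refined planes (z_refinement %d, %s)\n",
    d[1], d[2], d[3], x$z_refinement,
    if (x$binary) sprintf("binary at threshold %g", x$binarization_threshold)
    else "continuous"))
  invisible(x)
}

#' Binarize a 3D model
#'
#' Occupancy becomes 1 where the interpolated value is greater than or equal
#' to `threshold` (ties included: a midplane value of exactly 0.5 is inside
#' at the default threshold), else 0. For binary input masks this is the
#' identity on the original slice planes.
#'
#' @param model A `pat_model3d`.
#' @param threshold Scalar in the open interval (0, 1); default 0.5, the
#'   mid-surface between marked and unmarked tissue.
#' @return A binary `pat_model3d`.
#' @export
binarize <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "pat_model3d"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    abort("`threshold` must lie strictly between 0 and 1")
  model$occupancy <- (model$occupancy >= threshold) * 1
  model$binary <- TRUE
  model$binarization_threshold <- threshold
  model
}

#' Volume of a binary 3D model
#'
#' Two estimators are provided. `"voxel-count"` counts refined voxels — the
#' slabs of height `dz / z_refinement` between consecutive refined planes —
#' where a voxel is occupied iff both of its bounding planes are occupied
#' (the slab lies entirely inside the thresholded model), and multiplies the
#' count by the voxel volume `dy * dx * dz / z_refinement`.
#' `"trapezoidal-area"` applies the trapezoidal rule to the per-slice
#' cross-sectional areas on the original slice planes:
#' `V = sum dz * (A_i + A_{i+1}) / 2`. For binary masks thresholded at 0.5
#' the voxel count converges to the trapezoidal value from below as
#' `z_refinement` grows (and equals it for even `z_refinement`). `dz` is the
#' center-to-center slice spacing.
#'
#' @param model A binary `pat_model3d` (see [binarize()]).
#' @param method `"voxel-count"` or `"trapezoidal-area"`.
#' @return A one-row tibble of class `pat_volume`: `volume_ml`,
#'   `voxel_count` (`NA` for the trapezoidal method), `method`.
#' @export
model_volume <- function(model, method = c("voxel-count", "trapezoidal-area")) {
  stopifnot(inherits(model, "pat_model3d"))
  method <- match.arg(method)
  if (!model$binary || !all(model$occupancy %in% c(0, 1)))
    abort("model occupancy must be binary; call binarize() first")
  g <- model$geometry
  dz <- g$slice_thickness + g$slice_gap
  px_area <- g$pixel_spacing[1] * g$pixel_spacing[2]
  np <- dim(model$occupancy)[3]
  if (method == "voxel-count") {
    occ <- model$occupancy
    both <- occ[, , -np, drop = FALSE] * occ[, , -1, drop = FALSE]
    count <- sum(both)
    vol_mm3 <- count * px_area * dz / model$z_refinement
    tibble_volume(vol_mm3 / 1000, count, method)
  } else {
    idx <- seq(1L, np, by = model$z_refinement)
    areas <- vapply(idx, function(k) sum(model$occupancy[, , k]), 0) * px_area
    vol_mm3 <- sum(dz * (areas[-length(areas)] + areas[-1]) / 2)
    tibble_volume(vol_mm3 / 1000, NA_integer_, method)
  }
}

tibble_volume <- function(volume_ml, voxel_count, method) {
  out <- tibble::tibble(volume_ml = volume_ml,
                        voxel_count = as.integer(voxel_count),
                        method = method)
  class(out) <- c("pat_volume", class(out))
  out
}

#' Volume of a binary mask stack
#'
#' Convenience wrapper running [interpolate_between_slices()], [binarize()]
#' and [model_volume()]. Degenerate stacks are handled explicitly: an empty
#' compartment has zero volume, and a single-slice stack is measured as
#' `area x slice_thickness` (a slab of one slice), since no inter-slice
#' interpolation is possible.
#'
#' @param masks A binary `pat_image_stack`.
#' @param method Passed to [model_volume()].
#' @param z_refinement Passed to [interpolate_between_slices()].
#' @param threshold Passed to [binarize()].
#' @return Volume in mL (scalar). An empty compartment (`NULL`) has volume 0.
#' @export
mask_stack_volume <- function(masks, method = c("voxel-count", "trapezoidal-area"),
                              z_refinement = 8L, threshold = 0.5) {
  method <- match.arg(method)
  if (is.null(masks)) return(0)
  stopifnot(inherits(masks, "pat_image_stack"))
  if (!is_mask_stack(masks)) abort("mask stack must be binary")
  ns <- n_slices(masks)
  px_area <- masks$pixel_spacing[1] * masks$pixel_spacing[2]
  if (ns == 0L) return(0)
  if (ns == 1L)
    return(sum(masks$data) * px_area * masks$slice_thickness / 1000)
  model <- binarize(interpolate_between_slices(masks, z_refinement), threshold)
  model_volume(model, method)$volume_ml
}
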