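#' Compartment landmark configuration
#'
#' The atrial/ventricular partition is defined by two user-identified
#' landmark slices on the 0-based, cranial-to-caudal slice grid:
#' `rpa_slice`, the first slice at or below the right pulmonary artery
#' (slices above it are excluded — fat there is not pericardial), and
#' `mitral_hinge_slice`, the slice containing the mitral valve hinge, which
#' is the first ventricular slice (half-open convention). Atrial fat
#' therefore occupies slices `[rpa_slice, mitral_hinge_slice)` and
#' ventricular fat `[mitral_hinge_slice, last]` down to the apex.
#'
#' @param mitral_hinge_slice 0-based index of the first ventricular slice.
#' @param rpa_slice 0-based index of the first included (atrial) slice;
#'   default 0 (nothing excluded cranially).
#' @return A `pat_compartment_bounds`.
#' @export
compartment_bounds <- function(mitral_hinge_slice, rpa_slice = 0L) {
  mitral_hinge_slice <- as.integer(mitral_hinge_slice)
  rpa_slice <- as.integer(rpa_slice)
  if (rpa_slice < 0L) abort("`rpa_slice` must be >= 0")
  if (mitral_hinge_slice < rpa_slice)
    abort("`mitral_hinge_slice` must be >= `rpa_slice`")
  structure(list(mitral_hinge_slice = mitral_hinge_slice,
                 rpa_slice = rpa_slice),
            class = "pat_compartment_bounds")
}

#' Split a mask stack into atrial and ventricular compartments
#'
#' The split is made on the original slice grid, before any interpolation,
#' so interpolated voxels never straddle compartments and the two outputs
#' partition the included slice range exactly.
#'
#' @param masks A binary `pat_image_stack`.
#' @param bounds A [compartment_bounds()]; both landmark slices must exist
#'   in the stack.
#' @return A list with elements `atrial` and `ventricular`, each a
#'   `pat_image_stack` restricted to its compartment's slices, or `NULL`
#'   when the compartment contains no slices.
#' @export
split_compartments <- function(masks, bounds) {
  stopifnot(inherits(masks, "pat_image_stack"),
            inherits(bounds, "pat_compartment_bounds"))
  ns <- n_slices(masks)
  if (bounds$mitral_hinge_slice > ns - 1L)
    abort(sprintf("mitral_hinge_slice %d outside stack of %d slices",
                  bounds$mitral_hinge_slice, ns))
  take <- function(idx0) {
    if (length(idx0) == 0L) return(NULL)
    image_stack(masks$data[, , idx0 + 1L, drop = FALSE], masks$pixel_spacing,
                masks$slice_thickness, masks$slice_gap, masks$subject_id)
  }
  atrial_idx <- if (bounds$rpa_slice < bounds$mitral_hinge_slice)
    bounds$rpa_slice:(bounds$mitral_hinge_slice - 1L) else integer(0)
  vent_idx <- bounds$mitral_hinge_slice:(ns - 1L)
  list(atrial = take(atrial_idx), ventricular = take(vent_idx))
}

#' Quantify compartment fat volumes and masses
#'
#' Splits the mask stack at the landmark slices, measures each compartment's
#' volume with the 3D interpolated model (single-slice compartments fall
#' back to area x slice thickness), and converts volume to mass with the
#' adipose density constant (default 0.9 g/mL).
#'
#' @param masks A binary `pat_image_stack` of fat masks.
#' @param bounds A [compartment_bounds()].
#' @param density_g_per_ml Adipose tissue density, g/mL (default 0.9).
#' @param z_refinement Axial refinement for the 3D model (default 8).
#' @param method Volume estimator, see [model_volume()].
#' @return A one-row tibble of class `pat_fat_quant` with columns
#'   `atrial_volume_ml`, `ventricular_volume_ml`, `total_volume_ml`,
#'   `atrial_mass_g`, `ventricular_mass_g`, `total_mass_g`,
#'   `density_g_per_ml`. Totals are the exact sums of the compartments.
#' @examples
#' m <- array(0, c(16, 16, 6)); m[4:9, 4:9, ] <- 1
#' masks <- image_stack(m, c(1, 1), slice_thickness = 6)
#' quantify_fat(masks, compartment_bounds(mitral_hinge_slice = 2))
#' @export
quantify_fat <- function(masks, bounds, density_g_per_ml = 0.9,
                         z_refinement = 8L,
                         method = c("voxel-count", "trapezoidal-area")) {
  method <- match.arg(method)
  if (!is.finite(density_g_per_ml) || density_g_per_ml <= 0)
    abort("`density_g_per_ml` must be positive")
  if (!is_mask_stack(masks)) abort("mask stack must be binary")
  parts <- split_compartments(masks, bounds)
  if (sum(masks$data) == 0)
    warn("mask stack is empty; quantification is all zeros")
  va <- mask_stack_volume(parts$atrial, method, z_refinement)
  vv <- mask_stack_volume(parts$ventricular, method, z_refinement)
  out <- tibble::tibble(
    atrial_volume_ml = va, ventricular_volume_ml = vv,
    total_volume_ml = va + vv,
    atrial_mass_g = density_g_per_ml * va,
    ventricular_mass_g = density_g_per_ml * vv,
    total_mass_g = density_g_per_ml * va + density_g_per_ml * vv,
    density_g_per_ml = density_g_per_ml)
  class(out) <- c("pat_fat_quant", class(out))
  out
}
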