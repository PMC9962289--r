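#' Z-spectrum stack for APT-weighted imaging
#'
#' Bundles co-registered saturated images at signed frequency offsets (in
#' ppm relative to water) with the unsaturated reference image `s0`. The
#' APT-weighted contrast used downstream is the magnetization transfer ratio
#' asymmetry at 3.5 ppm, which needs exactly the -3.5 ppm and +3.5 ppm
#' saturated images plus `s0`.
#'
#' @param signals 4D numeric array, last dimension indexing offsets (a 3D
#'   array is accepted for a single offset).
#' @param offsets numeric vector of signed offsets in ppm, one per signal
#'   volume.
#' @param s0 3D numeric array, unsaturated reference signal.
#' @param spacing voxel spacing in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `z_spectrum_stack`.
#' @export
z_spectrum_stack <- function(signals, offsets, s0, spacing = c(1, 1, 1),
                             affine = NULL) {
  s0 <- as_volume3d(s0)
  if (length(dim(signals)) == 3L) signals <- array(signals, c(dim(signals), 1L))
  if (length(dim(signals)) != 4L)
    stop("`signals` must be a 4D array (x, y, z, offset)", call. = FALSE)
  offsets <- as.numeric(offsets)
  if (dim(signals)[4] != length(offsets))
    stop("length(offsets) must match the 4th dimension of `signals`",
         call. = FALSE)
  if (anyDuplicated(offsets))
    stop("duplicate ppm offsets", call. = FALSE)
  check_same_grid(dim(signals)[1:3], dim(s0), "signal and s0 grids")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (is.null(affine)) affine <- spacing_affine(spacing)
  structure(list(signals = signals, offsets = offsets, s0 = s0,
                 spacing = spacing, affine = affine),
            class = "z_spectrum_stack")
}

# Locate an offset volume, with a tolerance for floating ppm values.
z_offset_volume <- function(z, ppm, tol = 1e-6) {
  i <- which(abs(z$offsets - ppm) <= tol)
  if (length(i) != 1L)
    stop(sprintf("Z-spectrum stack is missing the %+.1f ppm offset", ppm),
         call. = FALSE)
  array(z$signals[, , , i], dim(z$s0))
}

#' Compute an MTRasym (APT-weighted) map
#'
#' Voxelwise magnetization transfer ratio asymmetry at 3.5 ppm,
#' \deqn{MTR_{asym}(3.5\,ppm) = (s(-3.5\,ppm) - s(+3.5\,ppm)) / s_0,}
#' expressed as a dimensionless fraction (multiply by 100 only at report
#' time). Voxels with `s0 <= 0`, non-finite inputs, or outside `mask` are
#' flagged invalid in the returned map rather than silently zeroed. No B0
#' correction or Z-spectrum interpolation is applied; supply a pre-corrected
#' stack if the acquisition needs one.
#'
#' @param z a [z_spectrum_stack()] containing the -3.5 and +3.5 ppm offsets.
#' @param mask optional binary analysis mask on the same grid.
#' @return A [parametric_map()] in `"fraction"` units.
#' @examples
#' s0 <- array(1000, c(2, 2, 1))
#' sig <- array(c(rep(700, 4), rep(650, 4)), c(2, 2, 1, 2))
#' z <- z_spectrum_stack(sig, c(-3.5, 3.5), s0)
#' compute_mtrasym_map(z)$values[1, 1, 1]  # 0.05
#' @export
compute_mtrasym_map <- function(z, mask = NULL) {
  stopifnot(inherits(z, "z_spectrum_stack"))
  s_neg <- z_offset_volume(z, -3.5)
  s_pos <- z_offset_volume(z, +3.5)
  if (is.null(mask)) {
    mask <- array(TRUE, dim(z$s0))
  } else {
    mask <- as_binary_mask(mask)
    check_same_grid(mask, z$s0, "mask and image grids")
  }
  valid <- mask & z$s0 > 0 & is.finite(z$s0) & is.finite(s_neg) &
    is.finite(s_pos)
  vals <- array(NA_real_, dim(z$s0))
  vals[valid] <- (s_neg[valid] - s_pos[valid]) / z$s0[valid]
  parametric_map(vals, units = "fraction", spacing = z$spacing,
                 affine = z$affine, valid = valid)
}

#' Pick the lesion-maximal slice
#'
#' The APT acquisition is a single 2D slice positioned at the maximum extent
#' of the lesion; this helper reproduces that choice on a 3D lesion mask by
#' returning the index (along the third axis) of the slice with the largest
#' in-mask area. Ties resolve to the lowest index.
#'
#' @param mask binary 3D lesion mask.
#' @return integer slice index.
#' @export
lesion_max_slice <- function(mask) {
  mask <- as_binary_mask(mask)
  areas <- apply(mask, 3, sum)
  if (all(areas == 0)) stop("empty lesion mask", call. = FALSE)
  which.max(areas)
}
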