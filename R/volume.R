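#' Voxel-grid parametric map
#'
#' A lightweight container for a quantitative MR map on a regular voxel grid:
#' an MTRasym map (dimensionless fraction) or a CBF map (mL/100 g/min),
#' together with voxel spacing, a voxel-to-world affine and a validity mask.
#' Voxels outside the validity mask hold `NA` and are excluded from all
#' downstream histogram statistics rather than imputed or zeroed.
#'
#' @param values numeric 3D array of voxel values (use a third dimension of 1
#'   for single-slice maps).
#' @param units map units, `"fraction"` for MTRasym or `"mL/100g/min"` for CBF.
#' @param spacing voxel spacing in mm, length 3.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). Defaults
#'   to a diagonal scaling by `spacing`.
#' @param valid logical array of the same dimension flagging usable voxels;
#'   defaults to `is.finite(values)`.
#' @return An object of class `parametric_map` with elements `values`,
#'   `units`, `spacing`, `affine`, `valid`.
#' @examples
#' m <- parametric_map(array(1, c(4, 4, 2)), units = "fraction")
#' dim(m$values)
#' @export
parametric_map <- function(values,
                           units = c("fraction", "mL/100g/min"),
                           spacing = c(1, 1, 1),
                           affine = NULL,
                           valid = NULL) {
  units <- match.arg(units)
  values <- as_volume3d(values)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as_volume3d(valid)
  storage.mode(valid) <- "logical"
  if (!identical(dim(values), dim(valid)))
    stop("`values` and `valid` must share dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  if (is.null(affine)) affine <- spacing_affine(spacing)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  values[!valid] <- NA_real_
  structure(
    list(values = values, units = units, spacing = spacing,
         affine = affine, valid = valid),
    class = "parametric_map"
  )
}

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<parametric_map> %d x %d x %d voxels, %s\n", d[1], d[2], d[3],
              x$units))
  cat(sprintf("  spacing: %s mm; valid voxels: %d/%d\n",
              paste(format(x$spacing), collapse = " x "),
              sum(x$valid), length(x$valid)))
  rng <- suppressWarnings(range(x$values[x$valid]))
  if (all(is.finite(rng)))
    cat(sprintf("  range (valid): [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

# Coerce vectors/matrices to a 3D array; 2D input becomes a single slice.
as_volume3d <- function(x) {
  if (is.null(dim(x))) x <- array(x, c(length(x), 1L, 1L))
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L)
    stop("expected a 2D or 3D array", call. = FALSE)
  x
}

# Default voxel-to-world affine: diagonal spacing, origin at voxel (0,0,0).
spacing_affine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

# Shared grid check used across quantification steps; accepts arrays or
# already-extracted dimension vectors.
check_same_grid <- function(a, b, what = "volumes") {
  da <- if (is.null(dim(a))) a else dim(a)
  db <- if (is.null(dim(b))) b else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("shape mismatch: %s have dimensions %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# Binary mask coercion: accepts logical or 0/1 numeric arrays.
as_binary_mask <- function(mask, what = "mask") {
  mask <- as_volume3d(mask)
  if (is.logical(mask)) return(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop(sprintf("`%s` must be binary (logical or 0/1)", what), call. = FALSE)
  array(mask == 1, dim(mask))
}
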