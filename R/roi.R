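#' Resample a parametric map onto a reference grid
#'
#' Maps each reference voxel through the reference affine into world space,
#' then through the inverse of the source affine into source voxel space,
#' and interpolates — the internal stand-in for registering the lower
#' resolution APT/CBF maps onto the higher resolution DWI grid when an
#' affine alignment is already known (identity for phantoms). The validity
#' mask propagates conservatively: a resampled voxel is valid only if every
#' source voxel contributing to its interpolation is valid and in bounds.
#'
#' @param map a [parametric_map()].
#' @param ref_shape integer triple, reference grid dimensions.
#' @param ref_affine 4x4 voxel-to-world matrix of the reference grid.
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @param src_affine optional override of the source affine (defaults to
#'   `map$affine`).
#' @return A [parametric_map()] on the reference grid.
#' @export
resample_to_reference <- function(map, ref_shape, ref_affine,
                                  interpolation = c("linear", "nearest"),
                                  src_affine = NULL) {
  stopifnot(inherits(map, "parametric_map"))
  interpolation <- match.arg(interpolation)
  ref_shape <- as.integer(ref_shape)
  stopifnot(length(ref_shape) == 3L)
  ref_affine <- as.matrix(ref_affine)
  if (is.null(src_affine)) src_affine <- map$affine
  if (abs(det(src_affine)) < .Machine$double.eps * 16)
    stop("singular source affine", call. = FALSE)
  if (abs(det(ref_affine)) < .Machine$double.eps * 16)
    stop("singular reference affine", call. = FALSE)

  # Fast path: same grid, same affine -> identity.
  if (identical(ref_shape, dim(map$values)) &&
      isTRUE(all.equal(unname(src_affine), unname(ref_affine),
                       tolerance = 1e-12))) {
    out <- map
    out$affine <- ref_affine
    return(out)
  }

  d_src <- dim(map$values)
  M <- solve(src_affine) %*% ref_affine  # reference voxel -> source voxel
  g <- as.matrix(expand.grid(x = seq_len(ref_shape[1]) - 1,
                             y = seq_len(ref_shape[2]) - 1,
                             z = seq_len(ref_shape[3]) - 1))
  src <- t(M %*% rbind(t(g), 1))[, 1:3, drop = FALSE] + 1  # 1-based voxels

  vals <- map$values
  vals_ok <- map$valid
  nref <- nrow(src)
  out_vals <- rep(NA_real_, nref)
  out_valid <- rep(FALSE, nref)

  lin_index <- function(i, j, k)
    i + (j - 1L) * d_src[1] + (k - 1L) * d_src[1] * d_src[2]

  if (interpolation == "nearest") {
    i <- round(src[, 1]); j <- round(src[, 2]); k <- round(src[, 3])
    inb <- i >= 1 & i <= d_src[1] & j >= 1 & j <= d_src[2] &
      k >= 1 & k <= d_src[3]
    li <- lin_index(i[inb], j[inb], k[inb])
    ok <- vals_ok[li]
    v <- vals[li]
    out_valid[inb] <- ok
    out_vals[inb][ok] <- v[ok]
  } else {
    i0 <- floor(src[, 1]); j0 <- floor(src[, 2]); k0 <- floor(src[, 3])
    fx <- src[, 1] - i0; fy <- src[, 2] - j0; fz <- src[, 3] - k0
    # Clamp exact upper-edge hits so they interpolate within bounds.
    hit <- i0 == d_src[1] & fx == 0; i0[hit] <- i0[hit] - 1; fx[hit] <- 1
    hit <- j0 == d_src[2] & fy == 0; j0[hit] <- j0[hit] - 1; fy[hit] <- 1
    hit <- k0 == d_src[3] & fz == 0; k0[hit] <- k0[hit] - 1; fz[hit] <- 1
    inb <- i0 >= 1 & i0 + 1 <= d_src[1] & j0 >= 1 & j0 + 1 <= d_src[2] &
      k0 >= 1 & k0 + 1 <= d_src[3]
    ii <- which(inb)
    acc <- numeric(length(ii))
    okall <- rep(TRUE, length(ii))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) fx[ii] else 1 - fx[ii]) *
        (if (dy == 1) fy[ii] else 1 - fy[ii]) *
        (if (dz == 1) fz[ii] else 1 - fz[ii])
      li <- lin_index(i0[ii] + dx, j0[ii] + dy, k0[ii] + dz)
      okall <- okall & (vals_ok[li] | w == 0)
      v <- vals[li]
      v[!vals_ok[li]] <- 0  # weight is 0 wherever this matters for validity
      acc <- acc + w * v
    }
    out_valid[ii] <- okall
    out_vals[ii[okall]] <- acc[okall]
  }
  parametric_map(array(out_vals, ref_shape), units = map$units,
                 spacing = sqrt(colSums(ref_affine[1:3, 1:3]^2)),
                 affine = ref_affine,
                 valid = array(out_valid, ref_shape))
}

#' First-order histogram features of an ROI
#'
#' The ten first-order statistics over the valid in-mask voxels of a map:
#' mean, max, min, excess kurtosis, skewness, and the 10th, 25th, 50th,
#' 75th and 90th percentiles. Conventions (isolated here on purpose, since
#' histogram software differs):
#' \itemize{
#'   \item percentiles use linear interpolation at position
#'     \eqn{(n-1)\,q} of the sorted sample (R's default type 7);
#'   \item skewness is the Fisher-Pearson moment coefficient
#'     \eqn{m_3 / m_2^{3/2}};
#'   \item kurtosis is excess kurtosis \eqn{m_4 / m_2^2 - 3};
#'   \item a zero-variance ROI reports skewness and kurtosis of 0 and sets
#'     the `degenerate` flag.
#' }
#'
#' @param map a [parametric_map()].
#' @param mask binary ROI mask on the map's grid.
#' @return list of class `histogram_features` with the ten statistics,
#'   `n_voxels`, `units` and `degenerate`.
#' @examples
#' m <- parametric_map(array(c(1, 2, 3, 4, 5, NA), c(6, 1, 1)), "fraction")
#' f <- extract_histogram_features(m, array(c(rep(TRUE, 5), FALSE), c(6, 1, 1)))
#' c(f$mean, f$p10, f$kurtosis)  # 3, 1.4, -1.3
#' @export
extract_histogram_features <- function(map, mask) {
  stopifnot(inherits(map, "parametric_map"))
  mask <- as_binary_mask(mask)
  check_same_grid(mask, map$values, "mask and map grids")
  eff <- mask & map$valid
  if (!any(eff))
    stop("empty effective ROI: mask does not intersect valid voxels",
         call. = FALSE)
  x <- map$values[eff]
  n <- length(x)
  m <- mean(x)
  cx <- x - m
  m2 <- mean(cx^2)
  degenerate <- m2 <= 0
  skew <- if (degenerate) 0 else mean(cx^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean(cx^4) / m2^2 - 3
  q <- unname(stats::quantile(x, c(.10, .25, .50, .75, .90), type = 7))
  structure(list(
    mean = m, max = max(x), min = min(x), kurtosis = kurt, skewness = skew,
    p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    n_voxels = n, units = map$units, degenerate = degenerate),
    class = "histogram_features")
}

#' Relative (lesion minus contralateral) features
#'
#' Statistic-by-statistic difference of two ROI feature sets: e.g. the
#' relative max is the lesion max minus the contralateral max. The
#' difference is taken at the statistic level (not over a voxelwise
#' difference image) because the two ROIs need not contain the same number
#' of voxels. A hypoperfused lesion therefore yields a negative relative
#' mean, matching the sign convention of the rASL biomarkers.
#'
#' @param lesion,contralateral `histogram_features` computed from the same
#'   kind of map (units must agree).
#' @param family feature family tag, `"rAPT"` or `"rASL"`.
#' @return list of class `relative_features` with the ten differenced
#'   statistics and the family tag.
#' @export
relative_features <- function(lesion, contralateral,
                              family = c("rAPT", "rASL")) {
  family <- match.arg(family)
  stopifnot(inherits(lesion, "histogram_features"),
            inherits(contralateral, "histogram_features"))
  if (!identical(lesion$units, contralateral$units))
    stop(sprintf("unit mismatch: lesion in %s, contralateral in %s",
                 lesion$units, contralateral$units), call. = FALSE)
  stats <- histogram_stat_names()
  d <- stats::setNames(
    vapply(stats, function(s) lesion[[s]] - contralateral[[s]], numeric(1)),
    stats)
  structure(c(as.list(d), list(family = family, units = lesion$units)),
            class = "relative_features")
}

#' Flatten relative features to a named row
#'
#' Helper producing the `rAPT_<stat>` / `rASL_<stat>` columns used in cohort
#' CSVs. rAPT values are converted from fraction to percent here — fractions
#' internally, percent only at report time.
#'
#' @param rel a `relative_features` object.
#' @return named numeric vector of length 10.
#' @export
relative_features_row <- function(rel) {
  stopifnot(inherits(rel, "relative_features"))
  v <- vapply(histogram_stat_names(), function(s) rel[[s]], numeric(1))
  if (rel$family == "rAPT") {
    scale_stats <- setdiff(histogram_stat_names(), c("kurtosis", "skewness"))
    v[scale_stats] <- v[scale_stats] * 100
  }
  stats::setNames(v, paste0(rel$family, "_", histogram_stat_names()))
}
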