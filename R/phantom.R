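#' Phantom specification
#'
#' Describes a synthetic single-subject acquisition: a spherical "lesion"
#' with programmed MTRasym and CBF values on a uniform background, placed in
#' the left half of the grid so that mirroring across the midline yields a
#' disjoint contralateral region. The raw signals are generated by
#' algebraically inverting the quantification equations, so noiseless
#' quantification recovers the programmed values exactly.
#'
#' Defaults describe a desk-scale but physiologically sensible subject:
#' a 48 x 48 x 12 grid at 2 x 2 x 6 mm, a 10 mm radius lesion, lesion/background
#' CBF of 60/40 mL/100 g/min, lesion MTRasym of 3% versus 0% background, and
#' 1% Gaussian signal noise (SNR ~ 100 on the unsaturated reference).
#'
#' @param grid_shape integer triple, voxels per axis (first axis must be even
#'   so the midline mirror is well defined).
#' @param voxel_spacing mm triple.
#' @param lesion_center voxel coordinates (1-based) of the lesion centre.
#' @param lesion_radius lesion radius in mm, > 0.
#' @param lesion_mtrasym,background_mtrasym MTRasym as dimensionless
#'   fractions.
#' @param lesion_cbf,background_cbf CBF in mL/100 g/min.
#' @param noise_sd Gaussian noise SD as a fraction of the unsaturated
#'   reference signal; applied to raw signals, not to derived maps.
#' @param seed integer master seed; all randomness flows from it through a
#'   per-subject counter so cohorts are reproducible regardless of the order
#'   subjects are generated in.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 12L),
                         voxel_spacing = c(2, 2, 6),
                         lesion_center = c(14, 24, 6),
                         lesion_radius = 10,
                         lesion_mtrasym = 0.03,
                         background_mtrasym = 0,
                         lesion_cbf = 60,
                         background_cbf = 40,
                         noise_sd = 0.01,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(voxel_spacing) == 3L,
            length(lesion_center) == 3L)
  if (any(grid_shape < 2L)) stop("grid too small", call. = FALSE)
  if (grid_shape[1] %% 2L != 0L)
    stop("first grid axis must have even length for midline mirroring",
         call. = FALSE)
  if (!is.numeric(lesion_radius) || lesion_radius <= 0)
    stop("`lesion_radius` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  spec <- list(grid_shape = grid_shape,
               voxel_spacing = as.numeric(voxel_spacing),
               lesion_center = as.numeric(lesion_center),
               lesion_radius = lesion_radius,
               lesion_mtrasym = lesion_mtrasym,
               background_mtrasym = background_mtrasym,
               lesion_cbf = lesion_cbf,
               background_cbf = background_cbf,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  mask <- sphere_mask(spec)
  if (!any(mask))
    stop("lesion lies outside the grid: no voxel within lesion_radius of ",
         "lesion_center", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  if (any(idx[, 1] > grid_shape[1] / 2L))
    stop("lesion must lie entirely within the left half of the grid ",
         "(x index <= ", grid_shape[1] / 2L, ") so the mirrored ",
         "contralateral region is disjoint", call. = FALSE)
  spec
}

# Spherical lesion mask in mm space.
sphere_mask <- function(spec) {
  d <- spec$grid_shape; sp <- spec$voxel_spacing; c0 <- spec$lesion_center
  x <- (seq_len(d[1]) - c0[1]) * sp[1]
  y <- (seq_len(d[2]) - c0[2]) * sp[2]
  z <- (seq_len(d[3]) - c0[3]) * sp[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(r2 <= spec$lesion_radius^2, d)
}

# Deterministic per-(seed, counter) stream; keeps derived seeds below 2^31.
derive_seed <- function(seed, counter = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 16807
  as.integer(s %% 2147483629 + 1)
}

#' Generate a synthetic single-subject acquisition
#'
#' Builds a Z-spectrum stack and an ASL control/label pair whose exact
#' quantification recovers the programmed MTRasym and CBF maps (before
#' noise). The unsaturated reference is `s0 = 1000` a.u. with saturated
#' images at 50% baseline saturation split antisymmetrically by the
#' programmed MTRasym; the ASL label image is `control - dM` with `dM`
#' obtained by inverting the CBF equation at `Scsf = 760` a.u. Additive
#' Gaussian noise (`noise_sd` x 1000 a.u.) enters on every raw signal
#' volume, mimicking acquisition noise that precedes quantification.
#'
#' @param spec a [phantom_spec()].
#' @param params an [asl_quant_params()] list used for the inversion (and
#'   returned inside the acquisition so quantification is consistent).
#' @param subject integer counter mixed into the seed stream, so
#'   multi-subject cohorts are reproducible subject-by-subject.
#' @return list with elements `z` ([z_spectrum_stack()]), `asl`
#'   ([asl_acquisition()]), `lesion_mask`, `contralateral_mask`, and `truth`
#'   (programmed `mtrasym` and `cbf` maps plus the spec).
#' @export
generate_phantom_subject <- function(spec, params = asl_quant_params(),
                                     subject = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  mask <- sphere_mask(spec)
  s0_ref <- 1000

  mtr <- array(spec$background_mtrasym, d)
  mtr[mask] <- spec$lesion_mtrasym
  cbf <- array(spec$background_cbf, d)
  cbf[mask] <- spec$lesion_cbf

  # Saturated images: 50% baseline saturation, asymmetry carries MTRasym.
  s_neg <- s0_ref * (0.5 + mtr / 2)
  s_pos <- s0_ref * (0.5 - mtr / 2)
  s0 <- array(s0_ref, d)

  # ASL: invert the quantification to get the control-label difference.
  p <- params
  Scsf <- 760
  m0a <- compute_m0a(Scsf, p)
  w_s <- p$w / 1000; T1a_s <- p$T1a / 1000
  TE_s <- p$TE / 1000; T2a_s <- p$T2a / 1000
  gain <- p$unit_scale * exp(w_s / T1a_s) * exp(TE_s / T2a_s) /
    (p$rho * 2 * p$alpha * T1a_s * m0a)
  if (p$include_bolus_term)
    gain <- gain / (1 - exp(-p$labeling_duration / 1000 / T1a_s))
  dM <- cbf / gain
  control <- array(500, d)
  label <- control - dM

  if (spec$noise_sd > 0) {
    set.seed(derive_seed(spec$seed, subject))
    sd <- spec$noise_sd * s0_ref
    n <- prod(d)
    s_neg <- s_neg + array(stats::rnorm(n, 0, sd), d)
    s_pos <- s_pos + array(stats::rnorm(n, 0, sd), d)
    s0 <- s0 + array(stats::rnorm(n, 0, sd), d)
    control <- control + array(stats::rnorm(n, 0, sd), d)
    label <- label + array(stats::rnorm(n, 0, sd), d)
  }

  affine <- spacing_affine(spec$voxel_spacing)
  z <- z_spectrum_stack(
    signals = array(c(s_neg, s_pos), c(d, 2L)),
    offsets = c(-3.5, 3.5), s0 = s0,
    spacing = spec$voxel_spacing, affine = affine)
  asl <- asl_acquisition(control, label, Scsf = Scsf, params = p,
                         spacing = spec$voxel_spacing, affine = affine)
  list(
    z = z, asl = asl,
    lesion_mask = mask,
    contralateral_mask = mirror_mask(mask, axis = 1L),
    truth = list(
      mtrasym = parametric_map(mtr, "fraction", spec$voxel_spacing, affine),
      cbf = parametric_map(cbf, "mL/100g/min", spec$voxel_spacing, affine),
      spec = spec)
  )
}

#' Mirror a mask across the grid midline
#'
#' Reflects a binary mask across the centre plane of the chosen axis — the
#' automated counterpart of placing a contralateral control region on the
#' opposite hemisphere. Reflection preserves the voxel count, and applying
#' it twice returns the original mask.
#'
#' @param mask binary array (logical or 0/1).
#' @param axis axis to reflect (1 = left-right by convention).
#' @return logical array of the same dimensions.
#' @export
mirror_mask <- function(mask, axis = 1L) {
  m <- as_binary_mask(mask)
  nd <- length(dim(m))
  if (axis < 1L || axis > nd) stop("invalid `axis`", call. = FALSE)
  idx <- rep(list(quote(expr = )), nd)
  idx[[axis]] <- rev(seq_len(dim(m)[axis]))
  do.call(`[`, c(list(m), idx, list(drop = FALSE)))
}

#' Write a phantom subject to disk
#'
#' Serializes the raw volumes as NIfTI-1 plus a JSON sidecar of ground truth
#' and acquisition constants, in the layout the command-line `quantify` step
#' reads back.
#'
#' @param subj output of [generate_phantom_subject()].
#' @param dir output directory (created if missing).
#' @param id subject identifier used as a filename prefix.
#' @return invisibly, the named vector of file paths written.
#' @export
write_phantom_subject <- function(subj, dir, id = "sub01") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- subj$z$spacing; af <- subj$z$affine
  f <- function(name) file.path(dir, paste0(id, "_", name))
  paths <- c(
    zstack = f("zstack.nii"), s0 = f("s0.nii"),
    control = f("asl_control.nii"), label = f("asl_label.nii"),
    lesion = f("lesion_mask.nii"), contra = f("contralateral_mask.nii"),
    truth = f("truth.json"))
  write_nifti(subj$z$signals, paths["zstack"], spacing = sp, affine = af)
  write_nifti(subj$z$s0, paths["s0"], spacing = sp, affine = af)
  write_nifti(subj$asl$control, paths["control"], spacing = sp, affine = af)
  write_nifti(subj$asl$label, paths["label"], spacing = sp, affine = af)
  write_nifti(subj$lesion_mask, paths["lesion"], spacing = sp, affine = af,
              datatype = "uint8")
  write_nifti(subj$contralateral_mask, paths["contra"], spacing = sp,
              affine = af, datatype = "uint8")
  truth <- list(
    format_version = "1",
    offsets_ppm = subj$z$offsets,
    Scsf = subj$asl$Scsf,
    asl_params = unclass(subj$asl$params),
    spec = unclass(subj$truth$spec),
    lesion_mtrasym = subj$truth$spec$lesion_mtrasym,
    background_mtrasym = subj$truth$spec$background_mtrasym,
    lesion_cbf = subj$truth$spec$lesion_cbf,
    background_cbf = subj$truth$spec$background_cbf)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
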