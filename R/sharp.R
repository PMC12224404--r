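# Regularized SHARP background removal.
#
# A field generated by sources outside the brain is harmonic inside it and
# therefore satisfies the spherical-mean-value (SMV) property: averaging over
# any sphere contained in the mask reproduces the centre value. The filter
# C = delta - SMV consequently annihilates the background, leaving only the
# local tissue field convolved with C; the local field is recovered by
# Tikhonov-regularized deconvolution and the harmonic background follows by
# subtraction.

#' SHARP configuration
#'
#' @param voxel_mm isotropic voxel size (mm).
#' @param kernel_radius_mm radius of the SMV kernel (mm); must exceed the
#'   voxel size. Default 4 voxels, a conventional QSM choice.
#' @param reg_lambda Tikhonov regularization weight (unitless, >= 0).
#' @param erosion_voxels mask erosion depth in voxels; at least the kernel
#'   radius so that every retained voxel sees a complete sphere.
#' @return list of class `sharp_config`.
#' @export
sharp_config <- function(voxel_mm,
                         kernel_radius_mm = 4 * voxel_mm,
                         reg_lambda = 1e-2,
                         erosion_voxels = ceiling(kernel_radius_mm / voxel_mm)) {
  if (kernel_radius_mm <= voxel_mm)
    stop("`kernel_radius_mm` must exceed the voxel size")
  if (reg_lambda < 0) stop("`reg_lambda` must be non-negative")
  if (erosion_voxels < ceiling(kernel_radius_mm / voxel_mm))
    stop("`erosion_voxels` must be at least kernel_radius_mm / voxel_mm")
  structure(list(voxel_mm = voxel_mm, kernel_radius_mm = kernel_radius_mm,
                 reg_lambda = reg_lambda, erosion_voxels = erosion_voxels),
            class = "sharp_config")
}

#' Remove the harmonic background field with regularized SHARP
#'
#' @param total 3D field volume in ppb (defined inside `mask`).
#' @param mask [brain_mask()].
#' @param cfg [sharp_config()].
#' @return list with `local` (3D field in ppb, zero outside the eroded mask)
#'   and `eroded_mask` ([brain_mask()]).
#' @export
remove_background_sharp <- function(total, mask, cfg) {
  if (!is.array(total) || length(dim(total)) != 3L)
    stop("`total` must be a 3D array")
  if (!identical(dim(total), dim(mask))) stop("field and mask grids differ")
  if (!all(is.finite(total[mask]))) stop("field must be finite inside the mask")

  d <- dim(total)
  radius_vox <- cfg$kernel_radius_mm / cfg$voxel_mm
  Ck <- 1 - Re(fft(.sphere_kernel(d, radius_vox)))
  eroded <- tryCatch(
    erode_mask(mask, cfg$erosion_voxels),
    error = function(e)
      stop(sprintf("mask too thin for SHARP: empty after erosion by %d voxels",
                   cfg$erosion_voxels)))

  b <- total
  b[!mask] <- 0
  Cb <- .fft_convolve(b, Ck)
  Cb[!eroded] <- 0
  local <- Re(fft(Ck * fft(Cb) / (Ck^2 + cfg$reg_lambda), inverse = TRUE)) / length(b)
  local[!eroded] <- 0
  list(local = local, eroded_mask = eroded)
}

#' Harmonic background field by subtraction
#'
#' `harmonic = total - local` on the eroded mask, zero elsewhere. Accepts 4D
#' field series (or 3D volumes, treated as a single timepoint).
#'
#' @param total [field_volume_series()] of kind "total" (or a raw array).
#' @param local [field_volume_series()] of kind "local" (or a raw array),
#'   valid on `eroded_mask`.
#' @param eroded_mask [brain_mask()] on which the local field is defined.
#' @return [field_volume_series()] of kind "harmonic".
#' @export
harmonic_field <- function(total, local, eroded_mask) {
  tv <- if (inherits(total, "field_series")) total$values else total
  lv <- if (inherits(local, "field_series")) local$values else local
  if (length(dim(tv)) == 3L) dim(tv) <- c(dim(tv), 1L)
  if (length(dim(lv)) == 3L) dim(lv) <- c(dim(lv), 1L)
  if (!identical(dim(tv), dim(lv)))
    stop("total and local field grids differ")
  if (!identical(dim(tv)[1:3], dim(eroded_mask)))
    stop("field and mask grids differ")
  h <- tv - lv
  h[!array(eroded_mask, dim(h))] <- 0
  field_volume_series(h, eroded_mask, kind = "harmonic")
}
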