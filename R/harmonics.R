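# Real solid-harmonic basis and per-timepoint least-squares field fitting.

# Evaluate the real regular solid harmonics (Cartesian polynomial form) at
# normalized coordinates. Column order and explicit polynomials:
#   l = 0: 1
#   l = 1: x, y, z
#   l = 2: xy, xz, yz, x^2 - y^2, 2z^2 - x^2 - y^2
#   l = 3: y(3x^2 - y^2), xyz, y(4z^2 - x^2 - y^2), z(2z^2 - 3x^2 - 3y^2),
#          x(4z^2 - x^2 - y^2), z(x^2 - y^2), x(x^2 - 3y^2)
# All are harmonic polynomials (degree <= 3), used unnormalized: any fixed
# invertible column scaling gives the same fitted field, and with the zeroth
# column equal to 1 its coefficient is directly a field offset in ppb.
.sh_labels <- c("c00",
                "c1p1", "c1m1", "c10",
                "c2m2", "c2p1", "c2m1", "c2p2", "c20",
                "c3m3", "c3m2", "c3m1", "c30", "c3p1", "c3p2", "c3p3")

.sh_evaluate <- function(x, y, z, order) {
  n <- length(x)
  cols <- list(rep(1, n))
  if (order >= 1) cols <- c(cols, list(x, y, z))
  if (order >= 2) cols <- c(cols, list(
    x * y, x * z, y * z, x^2 - y^2, 2 * z^2 - x^2 - y^2))
  if (order >= 3) cols <- c(cols, list(
    y * (3 * x^2 - y^2), x * y * z, y * (4 * z^2 - x^2 - y^2),
    z * (2 * z^2 - 3 * x^2 - 3 * y^2), x * (4 * z^2 - x^2 - y^2),
    z * (x^2 - y^2), x * (x^2 - 3 * y^2)))
  m <- do.call(cbind, cols)
  colnames(m) <- .sh_labels[seq_len((order + 1)^2)]
  m
}

#' Real solid-harmonic basis on a voxel set
#'
#' Builds the design matrix of real regular solid harmonics up to `order`
#' evaluated at `(coord - centroid) * voxel_mm / scale_mm`. Centring at the
#' mask centroid and scaling by half the largest mask extent keeps the cubic
#' columns well conditioned. For `order = 3` the basis has
#' `(3 + 1)^2 = 16` columns.
#'
#' @param mask_coords M x 3 matrix of voxel coordinates (any consistent
#'   integer indexing; the fixed scan order of the mask).
#' @param voxel_mm isotropic voxel size (mm).
#' @param order maximum harmonic order (0 to 3, default 3).
#' @param origin_mm optional fixed origin (mm); default mask centroid.
#' @param scale_mm optional normalization length (mm); default half the
#'   largest coordinate extent.
#' @return object of class `sh_basis`: `matrix` (M x (order+1)^2), `order`,
#'   `origin_mm`, `scale_mm`, `column_labels`, plus a cached QR factorization
#'   and condition number.
#' @export
solid_harmonic_basis <- function(mask_coords, voxel_mm, order = 3L,
                                 origin_mm = NULL, scale_mm = NULL) {
  mask_coords <- as.matrix(mask_coords)
  if (ncol(mask_coords) != 3L) stop("`mask_coords` must be M x 3")
  order <- as.integer(order)
  if (order < 0L || order > 3L) stop("`order` must be between 0 and 3")
  ncols <- (order + 1L)^2
  if (nrow(mask_coords) < ncols)
    stop(sprintf("rank deficient: %d coordinates for %d basis functions",
                 nrow(mask_coords), ncols))
  mm <- mask_coords * voxel_mm
  if (is.null(origin_mm)) origin_mm <- colMeans(mm)
  if (is.null(scale_mm)) {
    scale_mm <- max(apply(mm, 2L, function(v) diff(range(v)))) / 2
    if (scale_mm == 0) scale_mm <- 1
  }
  u <- sweep(mm, 2L, origin_mm) / scale_mm
  B <- .sh_evaluate(u[, 1], u[, 2], u[, 3], order)
  sv <- svd(B, nu = 0, nv = 0)$d
  structure(list(matrix = B, order = order, origin_mm = origin_mm,
                 scale_mm = scale_mm,
                 column_labels = colnames(B),
                 qr = qr(B),
                 condition = sv[1] / sv[length(sv)]),
            class = "sh_basis")
}

#' Least-squares solid-harmonic fit of a single field volume
#'
#' Ordinary least squares of the masked field values against the basis
#' columns; the residual is orthogonal to every column (normal equations).
#'
#' @param field 3D field volume in ppb (or a length-M vector already in mask
#'   scan order).
#' @param basis [solid_harmonic_basis()] built on the same mask voxel list.
#' @param eroded_mask [brain_mask()]; ignored when `field` is a vector.
#' @return named coefficient vector of length `(order+1)^2` (ppb per basis
#'   unit; the `c00` entry is in plain ppb).
#' @export
fit_solid_harmonics <- function(field, basis, eroded_mask = NULL) {
  if (is.array(field) && length(dim(field)) == 3L) {
    if (is.null(eroded_mask)) stop("`eroded_mask` required for a 3D field")
    field <- field[which(eroded_mask)]
  }
  if (length(field) != nrow(basis$matrix))
    stop("field length does not match the basis voxel count")
  if (basis$condition > 1e8)
    warning(sprintf("ill-conditioned basis (condition number %.3g)",
                    basis$condition))
  beta <- qr.coef(basis$qr, field)
  names(beta) <- basis$column_labels
  beta
}

#' Fit a solid-harmonic coefficient series
#'
#' Applies [fit_solid_harmonics()] independently to every timepoint of a
#' field series; row t of the result holds the coefficients of volume t.
#'
#' @param field_series [field_volume_series()] valid on `eroded_mask`, or a
#'   `measurement_matrix`, or a plain M x N matrix in mask scan order.
#' @param basis [solid_harmonic_basis()] built on the same mask.
#' @param eroded_mask [brain_mask()] (needed for a 4D series input).
#' @param tr_s sampling interval (s).
#' @return object of class `sh_series`: `coefficients` (N x (order+1)^2),
#'   `order`, `origin_mm`, `scale_mm`, `tr_s`.
#' @export
fit_series <- function(field_series, basis, eroded_mask = NULL, tr_s = NULL) {
  if (inherits(field_series, "measurement_matrix")) {
    if (is.null(tr_s)) tr_s <- field_series$tr_s
    Y <- field_series$values
  } else if (inherits(field_series, "field_series")) {
    if (is.null(eroded_mask)) eroded_mask <- field_series$valid_mask
    Y <- build_measurement_matrix(field_series, eroded_mask, tr_s %||% 1)$values
  } else {
    Y <- as.matrix(field_series)
  }
  if (nrow(Y) != nrow(basis$matrix))
    stop("field voxel count does not match the basis")
  if (basis$condition > 1e8)
    warning(sprintf("ill-conditioned basis (condition number %.3g)",
                    basis$condition))
  co <- t(qr.coef(basis$qr, Y))
  colnames(co) <- basis$column_labels
  structure(list(coefficients = co, order = basis$order,
                 origin_mm = basis$origin_mm, scale_mm = basis$scale_mm,
                 tr_s = tr_s),
            class = "sh_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sh_series <- function(x, ...) {
  cat(sprintf("<sh_series> %d timepoints x %d coefficients (order %d)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$order))
  invisible(x)
}

#' Extract the zeroth-order respiratory regressor
#'
#' The `c00` (l = 0, m = 0) column of the coefficient series: the spatially
#' uniform part of the fitted respiratory field, in ppb, sampled once per
#' volume.
#'
#' @param series [fit_series()] output.
#' @param tr_s sampling interval (s); defaults to the series'.
#' @return [resp_regressor()].
#' @export
regressor_from_coefficients <- function(series, tr_s = series$tr_s) {
  if (nrow(series$coefficients) < 1L) stop("empty coefficient series")
  if (is.null(tr_s)) stop("`tr_s` unknown; pass it explicitly")
  resp_regressor(series$coefficients[, "c00"], tr_s = tr_s)
}
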