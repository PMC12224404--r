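# Spectral helpers shared by the unwrapping, SHARP and phantom stages.
# Laplacian operators act on an even-symmetric mirror extension of the volume
# (each dimension doubled), which imposes Neumann-like boundaries: the brain
# does not tile periodically and plain periodic FFTs ring at the edges.

.mirror3 <- function(f) {
  d <- dim(f)
  f <- f[c(seq_len(d[1]), rev(seq_len(d[1]))), , , drop = FALSE]
  f <- f[, c(seq_len(d[2]), rev(seq_len(d[2]))), , drop = FALSE]
  f[, , c(seq_len(d[3]), rev(seq_len(d[3]))), drop = FALSE]
}

.crop3 <- function(g, d) g[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]

# Signed FFT frequencies as a fraction of the sampling rate (cycles/sample).
.fftfreq <- function(n) {
  m <- c(0:floor(n / 2), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2))
  m / n
}

# Continuous-spectrum Laplacian eigenvalues -(2*pi*k)^2 on the mirrored grid,
# in rad^2 / voxel^2. Spatial step is one voxel; callers carry physical units.
.lap_eigenvalues <- function(d) {
  dd <- 2L * d
  per <- lapply(dd, function(n) -(2 * pi * .fftfreq(n))^2)
  array(per[[1]], dd) +
    array(rep(per[[2]], each = dd[1]), dd) +
    array(rep(per[[3]], each = dd[1] * dd[2]), dd)
}

# Apply the spectral Laplacian to a 3D volume (mirror boundaries).
.laplacian_apply <- function(f, eig = .lap_eigenvalues(dim(f))) {
  d <- dim(f)
  g <- .mirror3(f)
  Re(.crop3(fft(eig * fft(g), inverse = TRUE), d)) / length(g)
}

# Invert the spectral Laplacian; the nullspace (DC) component is set to zero,
# so the returned solution has zero mean over the mirrored grid.
.laplacian_solve <- function(f, eig = .lap_eigenvalues(dim(f))) {
  d <- dim(f)
  g <- .mirror3(f)
  eig[1, 1, 1] <- 1
  G <- fft(g) / eig
  G[1, 1, 1] <- 0
  Re(.crop3(fft(G, inverse = TRUE), d)) / length(g)
}

# Spherical kernel of given voxel radius, centred at the array origin with
# wraparound, normalized to unit sum: the spherical-mean-value (SMV) filter.
.sphere_kernel <- function(d, radius_vox) {
  idx <- lapply(d, function(n) {
    i <- 0:(n - 1)
    pmin(i, n - i)
  })
  r2 <- outer(outer(idx[[1]]^2, idx[[2]]^2, `+`), idx[[3]]^2, `+`)
  k <- array(as.numeric(r2 <= radius_vox^2 + 1e-9), d)
  k / sum(k)
}

.fft_convolve <- function(f, kernel_fft) {
  Re(fft(kernel_fft * fft(f), inverse = TRUE)) / length(f)
}

#' Erode a brain mask with a spherical structuring element
#'
#' A voxel survives only if the whole sphere of the given radius around it
#' lies inside the input mask. Implemented by FFT convolution with the sphere
#' indicator; exact up to FFT round-off (guarded with a tolerance well below
#' one voxel count).
#'
#' @param mask [brain_mask()] or 3D logical array.
#' @param radius_vox erosion radius in voxels.
#' @return eroded [brain_mask()]; errors if no voxel survives.
#' @export
erode_mask <- function(mask, radius_vox) {
  d <- dim(mask)
  if (radius_vox <= 0) return(brain_mask(mask))
  k <- .sphere_kernel(d, radius_vox)
  cnt <- .fft_convolve(array(as.numeric(mask), d), fft(k))
  out <- mask & (cnt > 1 - 1e-6)
  if (!any(out))
    stop(sprintf("mask too thin: empty after erosion by %g voxels", radius_vox))
  brain_mask(out)
}

# Unit dipole kernel in k-space, D(k) = 1/3 - kz^2/|k|^2, D(0) = 0.
.dipole_kernel <- function(d) {
  fx <- .fftfreq(d[1]); fy <- .fftfreq(d[2]); fz <- .fftfreq(d[3])
  k2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  kz2 <- array(rep(fz^2, each = d[1] * d[2]), d)
  D <- 1 / 3 - kz2 / k2
  D[k2 == 0] <- 0
  D
}

#' Dipole field of a susceptibility distribution
#'
#' Forward field model: convolution of the susceptibility map with the unit
#' dipole kernel, evaluated in k-space (`1/3 - kz^2/|k|^2`, zero at k = 0).
#' With susceptibility in ppb the result is the field offset in ppb.
#'
#' @param chi_ppb 3D susceptibility map in ppb.
#' @return 3D field offset array in ppb.
#' @export
dipole_field_ppb <- function(chi_ppb) {
  if (!is.array(chi_ppb) || length(dim(chi_ppb)) != 3L)
    stop("`chi_ppb` must be a 3D array")
  d <- dim(chi_ppb)
  Re(fft(.dipole_kernel(d) * fft(chi_ppb), inverse = TRUE)) / length(chi_ppb)
}

# 7-point finite-difference Laplacian with mirror (Neumann) boundaries.
# Used in tests and harmonicity diagnostics; exact for cubic polynomials at
# interior points.
.stencil_laplacian <- function(f) {
  d <- dim(f)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  sh <- function(di, dj, dk)
    f[cl(seq_len(d[1]) + di, d[1]), cl(seq_len(d[2]) + dj, d[2]),
      cl(seq_len(d[3]) + dk, d[3]), drop = FALSE]
  sh(1L, 0L, 0L) + sh(-1L, 0L, 0L) + sh(0L, 1L, 0L) + sh(0L, -1L, 0L) +
    sh(0L, 0L, 1L) + sh(0L, 0L, -1L) - 6 * f
}
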