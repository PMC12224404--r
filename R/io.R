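# Readers and writers: NIfTI volumes via RNifti, traces and coefficient
# tables as tab-separated text.

#' Read a 4D phase series from a NIfTI file
#'
#' Values are interpreted as radians; anything outside (-pi, pi] is rewrapped
#' with a warning (scanner exports vary in scaling, so a single internal
#' convention avoids silent unit bugs).
#'
#' @param path NIfTI file (.nii or .nii.gz), 4D.
#' @param tr_s,te_s,b0_t acquisition metadata (required; volume headers do
#'   not reliably carry TE or B0).
#' @param voxel_mm isotropic voxel size; taken from the header when omitted.
#' @return [epi_phase_series()].
#' @export
read_phase_series <- function(path, tr_s, te_s, b0_t, voxel_mm = NULL) {
  if (missing(tr_s) || missing(te_s) || missing(b0_t))
    stop("`tr_s`, `te_s` and `b0_t` are required")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop(sprintf("expected a 4D volume, got %dD", length(dim(img))))
  if (is.null(voxel_mm)) {
    pd <- attr(img, "pixdim")
    voxel_mm <- if (!is.null(pd) && pd[1] > 0) pd[1] else 1
  }
  epi_phase_series(array(as.numeric(img), dim(img)), tr_s = tr_s,
                   te_s = te_s, b0_t = b0_t, voxel_mm = voxel_mm)
}

#' Read a 3D brain mask from a NIfTI file
#'
#' @param path NIfTI file, 3D; nonzero voxels are in-mask.
#' @return [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D mask, got %dD", length(dim(img))))
  brain_mask(array(as.numeric(img) != 0, dim(img)))
}

#' Write a volume (3D or 4D array) to NIfTI
#'
#' @param values numeric or logical array.
#' @param path output file (.nii or .nii.gz).
#' @param voxel_mm isotropic voxel size recorded in the header.
#' @param tr_s sampling interval recorded in the 4th pixdim slot for 4D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, path, voxel_mm = 1, tr_s = 1) {
  nd <- length(dim(values))
  pd <- c(1, rep(voxel_mm, 3), tr_s, 0, 0, 0)  # qfac, dx, dy, dz, dt, ...
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)),
                         reference = list(pixdim = pd), datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write breathing-belt traces
#'
#' Plain two-column tab-separated text `(time_s, amplitude)`; a header line
#' is optional on read and written by default.
#'
#' @param path text file.
#' @param fs_hz nominal sampling rate; estimated from timestamps if omitted.
#' @return [belt_trace()].
#' @export
read_belt <- function(path, fs_hz = NULL) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*[-+0-9.eE]+[\t ,]+[-+0-9.eE]+\\s*$", first)
  d <- read.table(path, header = header, sep = "\t",
                  col.names = c("time_s", "amplitude"))
  belt_trace(d[[1]], d[[2]], fs_hz = fs_hz)
}

#' @rdname read_belt
#' @param belt [belt_trace()] to write.
#' @export
write_belt <- function(belt, path) {
  write.table(data.frame(time_s = belt$timestamps_s,
                         amplitude = belt$amplitude),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write respiratory regressors
#'
#' Tab-separated columns `(time_s, value_ppb)`.
#'
#' @param path text file.
#' @return [resp_regressor()].
#' @export
read_regressor <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  tr <- median(diff(d$time_s))
  resp_regressor(d$value_ppb, tr_s = tr, t0_s = d$time_s[1])
}

#' @rdname read_regressor
#' @param regressor [resp_regressor()] to write.
#' @export
write_regressor <- function(regressor, path) {
  write.table(data.frame(time_s = regressor$timestamps_s,
                         value_ppb = regressor$values),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write solid-harmonic coefficient series
#'
#' Tab-separated columns `(time_s, c00, c1p1, c1m1, c10, ...)`, one row per
#' volume, 16 coefficient columns for order 3, labelled by (l, m).
#'
#' @param path text file.
#' @return object of class `sh_series` (order inferred from the columns).
#' @export
read_coefficients <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  co <- as.matrix(d[, -1, drop = FALSE])
  order <- as.integer(sqrt(ncol(co))) - 1L
  structure(list(coefficients = co, order = order, origin_mm = NULL,
                 scale_mm = NULL, tr_s = median(diff(d$time_s))),
            class = "sh_series")
}

#' @rdname read_coefficients
#' @param series `sh_series` from [fit_series()].
#' @param tr_s sampling interval; defaults to the series'.
#' @export
write_coefficients <- function(series, path, tr_s = series$tr_s) {
  n <- nrow(series$coefficients)
  d <- data.frame(time_s = (seq_len(n) - 1) * tr_s, series$coefficients,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
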