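# Core data types. Light S3 containers: plain lists with a class attribute and
# strict constructors, in the style of base-R imaging/signal packages.

#' Wrap phase values into (-pi, pi]
#'
#' @param x numeric vector or array of phase values in radians.
#' @return values wrapped into the half-open interval (-pi, pi].
#' @examples wrap_phase(c(0, pi, -pi, 3 * pi))
#' @export
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Convert phase at echo time to a field offset in ppb
#'
#' Under the gradient-echo signal model the phase accrued at echo time `te_s`
#' is `2*pi * f * te_s` where `f` is the local frequency offset (Hz). The
#' offset is expressed relative to the main field as parts per billion:
#' `ppb = f / (gamma * b0) * 1e9` with `gamma = 42.577e6` Hz/T.
#'
#' @param phase_rad phase in radians (scalar, vector or array).
#' @param te_s echo time in seconds (> 0).
#' @param b0_t main field strength in tesla (> 0).
#' @return field offset in ppb, same shape as `phase_rad`.
#' @seealso [field_ppb_to_phase()] for the exact inverse.
#' @export
phase_to_field_ppb <- function(phase_rad, te_s, b0_t) {
  if (!is.numeric(te_s) || length(te_s) != 1L || te_s <= 0)
    stop("`te_s` must be a single positive number")
  if (!is.numeric(b0_t) || length(b0_t) != 1L || b0_t <= 0)
    stop("`b0_t` must be a single positive number")
  phase_rad / (2 * pi * te_s) / (.GAMMA_HZ_PER_T * b0_t) * 1e9
}

#' @rdname phase_to_field_ppb
#' @param field_ppb field offset in ppb.
#' @export
field_ppb_to_phase <- function(field_ppb, te_s, b0_t) {
  if (!is.numeric(te_s) || length(te_s) != 1L || te_s <= 0)
    stop("`te_s` must be a single positive number")
  if (!is.numeric(b0_t) || length(b0_t) != 1L || b0_t <= 0)
    stop("`b0_t` must be a single positive number")
  field_ppb * 1e-9 * (.GAMMA_HZ_PER_T * b0_t) * (2 * pi * te_s)
}

#' EPI phase series container
#'
#' A 4D array of wrapped phase (radians, one volume per timepoint) together
#' with the acquisition metadata the processing chain needs. Values are stored
#' in (-pi, pi]; out-of-range input is rewrapped with a warning (values at
#' exactly -pi are mapped to pi silently).
#'
#' @param values 4D numeric array (nx, ny, nz, nt) of phase in radians.
#' @param tr_s repetition time in seconds.
#' @param te_s echo time in seconds.
#' @param b0_t main field strength in tesla.
#' @param voxel_mm isotropic voxel size in mm.
#' @return an object of class `epi_phase_series`.
#' @export
epi_phase_series <- function(values, tr_s, te_s, b0_t, voxel_mm = 2.5) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 4D array (nx, ny, nz, nt)")
  if (dim(values)[4] < 2L) stop("need at least 2 timepoints")
  if (!all(is.finite(values))) stop("phase values must be finite")
  for (nm in c("tr_s", "te_s", "b0_t", "voxel_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm))
  }
  values[values == -pi] <- pi
  if (any(values <= -pi) || any(values > pi)) {
    warning("phase values outside (-pi, pi]; rewrapping")
    values <- wrap_phase(values)
  }
  structure(
    list(values = values, tr_s = tr_s, te_s = te_s, b0_t = b0_t,
         voxel_mm = voxel_mm),
    class = "epi_phase_series")
}

#' @export
print.epi_phase_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<epi_phase_series> %d x %d x %d x %d  TR %.3f s  TE %.3f s  B0 %.1f T  voxel %.2f mm\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$te_s, x$b0_t, x$voxel_mm))
  invisible(x)
}

#' Brain mask
#'
#' @param values 3D logical (or coercible) array; must contain at least one
#'   TRUE voxel.
#' @return logical 3D array of class `brain_mask`.
#' @export
brain_mask <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask must be a 3D array")
  m <- array(as.logical(values) & !is.na(values), dim(values))
  if (!any(m)) stop("mask contains no voxels")
  structure(m, class = c("brain_mask", "array"))
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s, %d voxels\n",
              paste(dim(x), collapse = " x "), sum(x)))
  invisible(x)
}

#' Field volume series
#'
#' A 4D series (or single 3D volume stored with nt = 1) of field offsets in
#' ppb, defined on `valid_mask` and exactly zero elsewhere.
#'
#' @param values 4D numeric array in ppb.
#' @param valid_mask [brain_mask()] on the same spatial grid.
#' @param kind one of "total", "local", "harmonic".
#' @return object of class `field_series`.
#' @export
field_volume_series <- function(values, valid_mask,
                                kind = c("total", "local", "harmonic")) {
  kind <- match.arg(kind)
  if (is.array(values) && length(dim(values)) == 3L)
    dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 3D or 4D array")
  if (!identical(dim(values)[1:3], dim(valid_mask)))
    stop("field and mask grids differ")
  mask4 <- array(valid_mask, dim(values))
  if (!all(is.finite(values[mask4])))
    stop("field values must be finite inside the mask")
  values[!mask4] <- 0
  structure(list(values = values, valid_mask = valid_mask, kind = kind),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field_series:%s> %d x %d x %d, %d timepoint(s), %d mask voxels\n",
              x$kind, d[1], d[2], d[3], d[4], sum(x$valid_mask)))
  invisible(x)
}

#' Respiratory regressor
#'
#' Field offset in ppb sampled once per volume; the zeroth-order solid
#' harmonic coefficient of the respiratory field component.
#'
#' @param values numeric vector (ppb).
#' @param tr_s sampling interval (s).
#' @param t0_s time of the first sample (s).
#' @return object of class `resp_regressor` with `values` and `timestamps_s`.
#' @export
resp_regressor <- function(values, tr_s, t0_s = 0) {
  if (!is.numeric(values) || length(values) < 1L) stop("empty regressor")
  if (tr_s <= 0) stop("`tr_s` must be positive")
  structure(list(values = unname(as.numeric(values)),
                 timestamps_s = t0_s + (seq_along(values) - 1) * tr_s,
                 tr_s = tr_s),
            class = "resp_regressor")
}

#' Breathing-belt trace
#'
#' @param timestamps_s strictly increasing sample times (s).
#' @param amplitude belt amplitude, arbitrary units.
#' @param fs_hz nominal sampling rate (Hz); estimated from the timestamps when
#'   omitted.
#' @return object of class `belt_trace`.
#' @export
belt_trace <- function(timestamps_s, amplitude, fs_hz = NULL) {
  if (length(timestamps_s) < 2L) stop("belt trace needs at least 2 samples")
  if (length(timestamps_s) != length(amplitude))
    stop("timestamps and amplitude lengths differ")
  if (any(diff(timestamps_s) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(fs_hz)) fs_hz <- 1 / median(diff(timestamps_s))
  if (fs_hz <= 0) stop("`fs_hz` must be positive")
  structure(list(timestamps_s = as.numeric(timestamps_s),
                 amplitude = as.numeric(amplitude), fs_hz = fs_hz),
            class = "belt_trace")
}

#' @export
print.belt_trace <- function(x, ...) {
  cat(sprintf("<belt_trace> %d samples, %.1f s, fs ~%.1f Hz\n",
              length(x$amplitude), diff(range(x$timestamps_s)), x$fs_hz))
  invisible(x)
}

#' Respiratory phase trace
#'
#' @param timestamps_s sample times (s).
#' @param phase_rad phase in (-pi, pi].
#' @param method "histogram" or "hilbert".
#' @return object of class `resp_phase_trace`.
#' @export
resp_phase_trace <- function(timestamps_s, phase_rad,
                             method = c("histogram", "hilbert")) {
  method <- match.arg(method)
  phase_rad[phase_rad == -pi] <- pi
  if (any(phase_rad <= -pi) || any(phase_rad > pi))
    stop("phase values must lie in (-pi, pi]")
  structure(list(timestamps_s = as.numeric(timestamps_s),
                 phase_rad = as.numeric(phase_rad), method = method),
            class = "resp_phase_trace")
}

#' Peak set
#'
#' @param times_s event times (s); sorted, duplicates not allowed.
#' @return object of class `peak_set` (a sorted numeric vector).
#' @export
peak_set <- function(times_s = numeric(0)) {
  times_s <- sort(as.numeric(times_s))
  if (anyDuplicated(times_s)) stop("peak times must be distinct")
  structure(times_s, class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks\n", length(x)))
  invisible(x)
}
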