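# Belt preprocessing, respiratory phase synthesis and agreement metrics.

# Accept a belt trace, regressor, phase trace, or plain numeric vector (with
# explicit timestamps) and return list(t, x).
.as_trace <- function(trace, timestamps_s = NULL) {
  if (inherits(trace, "belt_trace"))
    return(list(t = trace$timestamps_s, x = trace$amplitude))
  if (inherits(trace, "resp_regressor"))
    return(list(t = trace$timestamps_s, x = trace$values))
  if (inherits(trace, "resp_phase_trace"))
    return(list(t = trace$timestamps_s, x = trace$phase_rad))
  if (is.numeric(trace)) {
    if (is.null(timestamps_s)) timestamps_s <- seq_along(trace) - 1
    return(list(t = as.numeric(timestamps_s), x = as.numeric(trace)))
  }
  stop("unsupported trace type")
}

#' Preprocess a breathing-belt trace
#'
#' De-spikes the trace (samples deviating from a running median by more than
#' `despike_mad` robust deviations are replaced by that median) and applies a
#' zero-phase Butterworth low-pass. Respiration lives below ~0.7 Hz, so the
#' default 2 Hz cutoff is conservative.
#'
#' @param raw [belt_trace()].
#' @param lowpass_hz low-pass cutoff (Hz); must be below the Nyquist rate.
#' @param despike_mad spike threshold in robust (MAD) deviations.
#' @param median_window_s running-median window length (s).
#' @return [belt_trace()] with the same timestamps.
#' @export
preprocess_belt <- function(raw, lowpass_hz = 2.0, despike_mad = 5.0,
                            median_window_s = 1.0) {
  if (!inherits(raw, "belt_trace")) stop("`raw` must be a belt_trace")
  x <- raw$amplitude
  fs <- 1 / median(diff(raw$timestamps_s))
  if (lowpass_hz >= fs / 2)
    stop(sprintf("lowpass cutoff %.3g Hz is not below Nyquist (%.3g Hz)",
                 lowpass_hz, fs / 2))
  k <- max(3L, round(median_window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(x) %% 2L == 1L) length(x) else length(x) - 1L)
  med <- runmed(x, k, endrule = "median")
  dev <- mad(x - med)
  if (dev > 0) {
    bad <- abs(x - med) > despike_mad * dev
    x[bad] <- med[bad]
  }
  bw <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
  x <- as.numeric(signal::filtfilt(bw, x))
  belt_trace(raw$timestamps_s, x, fs_hz = raw$fs_hz)
}

#' Align a regressor with a belt trace
#'
#' Resamples the belt at the regressor's timestamps shifted by candidate lags
#' and returns the lag maximizing the absolute Pearson correlation (the
#' regressor's sign relative to inspiration is not identifiable, so the
#' absolute value is used). Positive lag means the belt's clock runs ahead:
#' `belt(t + lag)` matches `regressor(t)`.
#'
#' @param regressor [resp_regressor()].
#' @param belt [belt_trace()].
#' @param max_lag_s search range (s), +/-.
#' @param lag_step_s lag grid spacing (s).
#' @return list of class `trace_alignment`: `lag_s`, `correlation` (signed,
#'   at the chosen lag), and `belt_resampled` (belt values at the regressor's
#'   timestamps after applying the lag).
#' @export
align_traces <- function(regressor, belt, max_lag_s = 5.0, lag_step_s = 0.05) {
  rt <- regressor$timestamps_s
  rv <- regressor$values
  bt <- belt$timestamps_s
  if (min(bt) > max(rt) || max(bt) < min(rt))
    stop("regressor and belt time ranges do not overlap")
  lags <- seq(-max_lag_s, max_lag_s, by = lag_step_s)
  score <- vapply(lags, function(L) {
    bv <- approx(bt, belt$amplitude, xout = rt + L)$y
    ok <- !is.na(bv)
    if (sum(ok) < 8L) return(NA_real_)
    if (sd(bv[ok]) == 0 || sd(rv[ok]) == 0) return(0)
    abs(cor(rv[ok], bv[ok]))
  }, numeric(1))
  if (all(is.na(score))) stop("insufficient overlap between traces")
  best <- which.max(score)
  lag <- lags[best]
  bv <- approx(bt, belt$amplitude, xout = rt + lag)$y
  ok <- !is.na(bv)
  rho <- if (sd(bv[ok]) > 0 && sd(rv[ok]) > 0) cor(rv[ok], bv[ok]) else 0
  structure(list(lag_s = lag, correlation = rho, belt_resampled = bv),
            class = "trace_alignment")
}

# Dominant period of a uniformly sampled trace from the first off-zero local
# maximum of the autocorrelation; NA when no such maximum exists.
.dominant_period_s <- function(x, dt) {
  n <- length(x)
  if (sd(x) == 0 || n < 4L) return(NA_real_)
  ac <- as.numeric(acf(x, lag.max = floor(n / 2), plot = FALSE,
                       demean = TRUE)$acf)
  # ac[1] is lag 0; search lags 1 .. lag.max-1 for the first local maximum
  for (k in 2:(length(ac) - 1L)) {
    if (ac[k] > ac[k - 1L] && ac[k] >= ac[k + 1L]) return((k - 1L) * dt)
  }
  NA_real_
}

# Core peak finder on a uniformly sampled trace. Rules (deterministic):
#   candidates: x[i] > x[i-1] and x[i] >= x[i+1] (first sample of a plateau);
#   prominence: height above the higher of the two flanking minima, walking
#     outwards until a strictly higher sample or the trace edge;
#   threshold: prominence >= prominence_frac * IQR(x);
#   separation: at least `separation_frac` of the dominant period between
#     kept peaks, resolved greedily from the highest peak down (ties towards
#     the earlier peak);
#   refinement: parabolic interpolation through the three samples around each
#     kept peak (offset clamped to +/- half a sample).
.find_peaks <- function(x, t, prominence_frac = 0.2, separation_frac = 0.5,
                        refine = TRUE) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  if (diff(range(x)) == 0) return(peak_set())
  dt <- median(diff(t))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(peak_set())
  iqr <- IQR(x)
  prom <- vapply(cand, function(i) {
    j <- i; ml <- x[i]
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; ml <- min(ml, x[j]) }
    k <- i; mr <- x[i]
    while (k < n && x[k + 1L] <= x[i]) { k <- k + 1L; mr <- min(mr, x[k]) }
    x[i] - max(ml, mr)
  }, numeric(1))
  cand <- cand[prom >= prominence_frac * iqr]
  if (!length(cand)) return(peak_set())
  min_sep <- separation_frac * .dominant_period_s(x, dt)
  if (is.na(min_sep)) min_sep <- 0
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(t[i] - t[kept]) >= min_sep * (1 - 1e-12)))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  times <- t[kept]
  if (refine) {
    inner <- kept > 1L & kept < n
    i <- kept[inner]
    denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    delta <- ifelse(denom == 0, 0, 0.5 * (x[i - 1L] - x[i + 1L]) / denom)
    delta <- pmin(pmax(delta, -0.5), 0.5)
    times[inner] <- t[i] + delta * dt
  }
  peak_set(times)
}

#' Detect respiratory peaks in a uniformly sampled trace
#'
#' Local maxima exceeding a prominence threshold of `prominence_frac` times
#' the trace's interquartile range, separated by at least half the dominant
#' period (taken from the autocorrelation's first off-zero maximum). Peak
#' times are refined by parabolic interpolation through the neighbouring
#' samples. A constant trace yields an empty peak set. Troughs can be
#' detected by negating the trace.
#'
#' @param trace [belt_trace()], [resp_regressor()], [resp_phase_trace()] or a
#'   numeric vector.
#' @param timestamps_s sample times for a numeric `trace` (default unit
#'   spacing).
#' @param prominence_frac prominence threshold as a fraction of the IQR.
#' @param separation_frac minimum peak separation as a fraction of the
#'   dominant period.
#' @param refine parabolic sub-sample refinement of peak times.
#' @return [peak_set()].
#' @export
detect_peaks <- function(trace, timestamps_s = NULL, prominence_frac = 0.2,
                         separation_frac = 0.5, refine = TRUE) {
  tr <- .as_trace(trace, timestamps_s)
  .find_peaks(tr$x, tr$t, prominence_frac, separation_frac, refine)
}

#' Match peaks across two traces
#'
#' Greedy nearest-in-time one-to-one matching: candidate pairs within
#' `window_s` are accepted in order of increasing time difference, each peak
#' used at most once. The default window is half the volume TR of a 1.15 s
#' protocol (0.575 s). The overlap fraction uses the larger peak count as the
#' denominator (the stricter convention).
#'
#' @param a,b [peak_set()] objects.
#' @param window_s maximum |time difference| for a match (s).
#' @return list with `pairs` (n x 2 matrix of indices into `a` and `b`) and
#'   `overlap_fraction` = matched / max(|a|, |b|).
#' @export
match_peaks <- function(a, b, window_s = 0.575) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) {
    return(list(pairs = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
                overlap_fraction = if (na == 0L && nb == 0L) 1 else 0))
  }
  d <- abs(outer(as.numeric(a), as.numeric(b), `-`))
  idx <- which(d <= window_s, arr.ind = TRUE)
  pairs <- matrix(integer(0), 0, 2)
  if (nrow(idx)) {
    ord <- order(d[idx], idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (!used_a[i] && !used_b[j]) {
        pairs <- rbind(pairs, c(i, j))
        used_a[i] <- TRUE; used_b[j] <- TRUE
      }
    }
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("a", "b")
  list(pairs = pairs, overlap_fraction = nrow(pairs) / max(na, nb))
}

#' Peak agreement report
#'
#' Respiratory periods are the successive differences of the matched peak
#' times within each trace; `period_rmse_s` is the root-mean-square error of
#' the paired period differences, and `mean_peak_error_s` the mean absolute
#' time difference over matched pairs. With fewer than two matched pairs the
#' period metrics are reported as `NA`; the overlap fraction is always
#' reported.
#'
#' @param a,b [peak_set()] objects.
#' @param pairs optional result of [match_peaks()]; computed with `window_s`
#'   when omitted.
#' @param window_s matching window passed to [match_peaks()].
#' @param lag_applied_s lag already applied to align the traces (recorded in
#'   the report).
#' @return list of class `agreement_report`: `overlap_fraction`,
#'   `period_rmse_s`, `mean_peak_error_s`, `n_matched`, `lag_applied_s`,
#'   `mean_period_a_s`, `mean_period_b_s`.
#' @export
agreement_report <- function(a, b, pairs = NULL, window_s = 0.575,
                             lag_applied_s = 0) {
  if (is.null(pairs)) pairs <- match_peaks(a, b, window_s)
  pm <- pairs$pairs
  ta <- as.numeric(a)[pm[, 1]]
  tb <- as.numeric(b)[pm[, 2]]
  ord <- order(ta)
  ta <- ta[ord]; tb <- tb[ord]
  if (length(ta) >= 2L) {
    pa <- diff(ta); pb <- diff(tb)
    period_rmse <- sqrt(mean((pa - pb)^2))
    mp_a <- mean(pa); mp_b <- mean(pb)
  } else {
    period_rmse <- NA_real_; mp_a <- NA_real_; mp_b <- NA_real_
  }
  structure(list(
    overlap_fraction = pairs$overlap_fraction,
    period_rmse_s = period_rmse,
    mean_peak_error_s = if (length(ta)) mean(abs(ta - tb)) else NA_real_,
    n_matched = nrow(pm),
    lag_applied_s = lag_applied_s,
    mean_period_a_s = mp_a,
    mean_period_b_s = mp_b), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> overlap %.1f%% (%d matched), ",
                     "period RMSE %.3f s, mean peak error %.3f s\n"),
              100 * x$overlap_fraction, x$n_matched, x$period_rmse_s,
              x$mean_peak_error_s))
  invisible(x)
}

# Slope sign with zero-slope samples carried over from the last nonzero sign
# (breath-hold plateaus have no defined phase direction; mirroring the
# limitation rather than inventing one). Leading zeros take the first
# nonzero sign.
.slope_sign <- function(x) {
  n <- length(x)
  sl <- numeric(n)
  if (n >= 3L) sl[2:(n - 1L)] <- x[3:n] - x[1:(n - 2L)]
  sl[1L] <- x[2L] - x[1L]
  sl[n] <- x[n] - x[n - 1L]
  sg <- sign(sl)
  nz <- which(sg != 0)
  if (!length(nz)) stop("constant trace: respiratory phase undefined")
  first <- nz[1L]
  if (first > 1L) sg[seq_len(first - 1L)] <- sg[first]
  for (i in seq_len(n)[-1]) if (sg[i] == 0) sg[i] <- sg[i - 1L]
  sg
}

#' Histogram-based respiratory phase
#'
#' RETROICOR-style phase: the amplitude histogram of the trace (over
#' `n_bins` equal-width bins spanning its range) gives a cumulative
#' distribution; the phase at time t is `pi * sign(dR/dt) * CDF(R(t))`, so
#' equal time is spent per amplitude quantile. At the global maximum
#' `|phase| = pi`; near the global minimum it approaches 0. Output lies in
#' (-pi, pi].
#'
#' @param trace uniformly sampled trace (same types as [detect_peaks()]).
#' @param timestamps_s sample times for a numeric `trace`.
#' @param n_bins number of histogram bins.
#' @return [resp_phase_trace()] with `method = "histogram"`.
#' @export
respiratory_phase_histogram <- function(trace, timestamps_s = NULL,
                                        n_bins = 100L) {
  tr <- .as_trace(trace, timestamps_s)
  x <- tr$x
  if (diff(range(x)) == 0)
    stop("constant trace: respiratory phase undefined")
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  H <- tabulate(bin, nbins = n_bins)
  cdf <- cumsum(H) / sum(H)
  phi <- pi * .slope_sign(x) * cdf[bin]
  resp_phase_trace(tr$t, phi, method = "histogram")
}

#' Hilbert-transform respiratory phase
#'
#' De-means the trace, forms the analytic signal via the FFT and returns its
#' instantaneous phase angle in (-pi, pi].
#'
#' @inheritParams respiratory_phase_histogram
#' @return [resp_phase_trace()] with `method = "hilbert"`.
#' @export
respiratory_phase_hilbert <- function(trace, timestamps_s = NULL) {
  tr <- .as_trace(trace, timestamps_s)
  x <- tr$x
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples")
  if (diff(range(x)) == 0)
    stop("constant trace: respiratory phase undefined")
  x <- x - mean(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  analytic <- fft(h * fft(x), inverse = TRUE) / n
  resp_phase_trace(tr$t, Arg(analytic), method = "hilbert")
}
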