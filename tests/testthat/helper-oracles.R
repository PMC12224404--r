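# Fixture builders and independent oracles. Everything here is written from
# first principles (plain loops, direct formulas) so that it can cross-check
# the package's vectorized / spectral implementations.

ellipsoid_mask <- function(d, semi = pmax(3, round(0.375 * d))) {
  ctr <- (d - 1) / 2
  m <- array(FALSE, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    m[i, j, k] <- ((i - 1 - ctr[1]) / semi[1])^2 +
      ((j - 1 - ctr[2]) / semi[2])^2 +
      ((k - 1 - ctr[3]) / semi[3])^2 <= 1
  }
  brain_mask(m)
}

grid_arrays <- function(d) {
  list(x = array(rep(0:(d[1] - 1), d[2] * d[3]), d),
       y = array(rep(rep(0:(d[2] - 1), each = d[1]), d[3]), d),
       z = array(rep(0:(d[3] - 1), each = d[1] * d[2]), d))
}

# 7-point finite-difference Laplacian, clamped (mirror) boundaries.
oracle_stencil_laplacian <- function(f) {
  d <- dim(f)
  cl <- function(i, n) min(max(i, 1L), n)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    out[i, j, k] <-
      f[cl(i + 1L, d[1]), j, k] + f[cl(i - 1L, d[1]), j, k] +
      f[i, cl(j + 1L, d[2]), k] + f[i, cl(j - 1L, d[2]), k] +
      f[i, j, cl(k + 1L, d[3])] + f[i, j, cl(k - 1L, d[3])] - 6 * f[i, j, k]
  }
  out
}

# Dipole field by direct k-space construction (independent of the package's
# kernel code).
oracle_dipole_field <- function(chi) {
  d <- dim(chi)
  fr <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / n
  }
  D <- array(0, d)
  fx <- fr(d[1]); fy <- fr(d[2]); fz <- fr(d[3])
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    k2 <- fx[i]^2 + fy[j]^2 + fz[k]^2
    D[i, j, k] <- if (k2 == 0) 0 else 1 / 3 - fz[k]^2 / k2
  }
  Re(fft(D * fft(chi), inverse = TRUE)) / length(chi)
}

# Exhaustive-scan peak finder following the documented rules of
# detect_peaks(), written as plain loops.
oracle_peaks <- function(x, t, prominence_frac = 0.2, separation_frac = 0.5,
                         refine = TRUE) {
  n <- length(x)
  if (diff(range(x)) == 0) return(numeric(0))
  dt <- median(diff(t))
  cand <- integer(0)
  for (i in 2:(n - 1)) if (x[i] > x[i - 1] && x[i] >= x[i + 1])
    cand <- c(cand, i)
  if (!length(cand)) return(numeric(0))
  keep <- integer(0)
  iqr <- unname(quantile(x, 0.75) - quantile(x, 0.25))
  for (i in cand) {
    j <- i; ml <- x[i]
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; ml <- min(ml, x[j]) }
    k <- i; mr <- x[i]
    while (k < n && x[k + 1] <= x[i]) { k <- k + 1; mr <- min(mr, x[k]) }
    if (x[i] - max(ml, mr) >= prominence_frac * iqr) keep <- c(keep, i)
  }
  if (!length(keep)) return(numeric(0))
  # dominant period: first off-zero local maximum of the autocorrelation
  xm <- x - mean(x)
  maxlag <- floor(n / 2)
  ac <- numeric(maxlag + 1)
  for (L in 0:maxlag)
    ac[L + 1] <- sum(xm[1:(n - L)] * xm[(1 + L):n]) / sum(xm^2)
  per <- NA_real_
  for (L in 2:maxlag)
    if (ac[L + 1] > ac[L] && ac[L + 1] >= ac[L + 2]) { per <- L * dt; break }
  min_sep <- if (is.na(per)) 0 else separation_frac * per
  ord <- keep[order(-x[keep], keep)]
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in acc) if (abs(t[i] - t[j]) < min_sep * (1 - 1e-12)) ok <- FALSE
    if (ok) acc <- c(acc, i)
  }
  acc <- sort(acc)
  times <- t[acc]
  if (refine) {
    for (q in seq_along(acc)) {
      i <- acc[q]
      if (i > 1 && i < n) {
        den <- x[i - 1] - 2 * x[i] + x[i + 1]
        del <- if (den == 0) 0 else 0.5 * (x[i - 1] - x[i + 1]) / den
        del <- min(max(del, -0.5), 0.5)
        times[q] <- t[i] + del * dt
      }
    }
  }
  times
}

# Brute-force histogram respiratory phase (explicit bin counting).
oracle_histogram_phase <- function(x, n_bins = 100L) {
  n <- length(x)
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / n_bins
  bin <- integer(n)
  for (i in 1:n) {
    b <- floor((x[i] - lo) / width) + 1L
    bin[i] <- min(max(b, 1L), n_bins)
  }
  H <- integer(n_bins)
  for (i in 1:n) H[bin[i]] <- H[bin[i]] + 1L
  cdf <- cumsum(H) / n
  sl <- numeric(n)
  for (i in 1:n) {
    sl[i] <- if (i == 1) x[2] - x[1]
    else if (i == n) x[n] - x[n - 1]
    else x[i + 1] - x[i - 1]
  }
  sg <- sign(sl)
  nz <- which(sg != 0)
  if (nz[1] > 1) sg[1:(nz[1] - 1)] <- sg[nz[1]]
  for (i in 2:n) if (sg[i] == 0) sg[i] <- sg[i - 1]
  phi <- pi * sg * cdf[bin]
  phi[phi == -pi] <- pi
  phi
}
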