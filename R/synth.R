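# Ground-truth phantom generator: breathing waveforms, dipole local fields,
# solid-harmonic background modulation, wrapped noisy EPI phase and a
# simulated belt trace.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Breathing segment specification
#'
#' One block of a breathing protocol. Defaults per kind mirror a controlled
#' protocol: shallow breaths (short period, reduced depth), deep breaths
#' (long period, increased depth), free breathing near the typical adult
#' resting period of ~4.8 s with ~20% breath-to-breath period jitter, and a
#' breath-hold at end-expiration level.
#'
#' @param kind one of "shallow", "deep", "free", "hold".
#' @param duration_s segment duration (s).
#' @param period_s nominal breath period (s); ignored for holds.
#' @param amplitude breath depth (arbitrary units; the phantom maps it to
#'   ppb through its background gains).
#' @param period_jitter_fraction uniform per-breath period jitter, in
#'   \[0, 0.5\].
#' @return list of class `breath_segment`.
#' @export
breath_segment <- function(kind = c("free", "shallow", "deep", "hold"),
                           duration_s,
                           period_s = switch(kind, shallow = 2.5, deep = 6,
                                             free = 4.8, hold = Inf),
                           amplitude = switch(kind, shallow = 0.5, deep = 1.5,
                                              free = 1, hold = 0),
                           period_jitter_fraction = switch(kind, free = 0.2,
                                                           hold = 0, 0.1)) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (kind != "hold" && period_s <= 0) stop("`period_s` must be positive")
  if (period_jitter_fraction < 0 || period_jitter_fraction > 0.5)
    stop("`period_jitter_fraction` must lie in [0, 0.5]")
  structure(list(kind = kind, duration_s = duration_s, period_s = period_s,
                 amplitude = amplitude,
                 period_jitter_fraction = period_jitter_fraction),
            class = "breath_segment")
}

#' Controlled breathing protocol
#'
#' Four segments: shallow breaths, deep breaths, free breathing, and a
#' breath-hold whose duration is drawn uniformly in \[10, 20\] s.
#'
#' @param seed RNG seed for the hold duration.
#' @param free_duration_s duration of the free-breathing segment (s).
#' @return list of [breath_segment()] objects.
#' @export
control_protocol_segments <- function(seed = 1L, free_duration_s = 90) {
  hold_s <- .with_seed(seed, runif(1, 10, 20))
  list(breath_segment("shallow", duration_s = 25),
       breath_segment("deep", duration_s = 60),
       breath_segment("free", duration_s = free_duration_s),
       breath_segment("hold", duration_s = hold_s))
}

#' Generate a ground-truth breathing waveform
#'
#' Concatenates the segments; each breath is one raised-cosine cycle
#' `A * (1 - cos(2*pi*t/T)) / 2` with its period jittered per breath by the
#' segment's jitter fraction (uniform). Cycles start and end at the
#' end-expiration level 0, and whole breaths are packed into each segment
#' (any remainder shorter than a breath stays at end-expiration), so the
#' waveform is continuous at every boundary. Holds are constant at 0.
#'
#' @param segments list of [breath_segment()] (a single segment may be passed
#'   bare).
#' @param fs_hz sampling rate of the returned trace (Hz); must satisfy
#'   `fs_hz > 2 / min(period)`.
#' @param seed RNG seed for the period jitter.
#' @return object of class `breath_waveform`: `timestamps_s`, `values`,
#'   `fun` (vectorized evaluator for arbitrary times), `breaths` (data frame
#'   of start/period/amplitude), `duration_s`, `fs_hz`.
#' @export
generate_breathing_waveform <- function(segments, fs_hz = 500, seed = 1L) {
  if (inherits(segments, "breath_segment")) segments <- list(segments)
  if (!length(segments)) stop("empty segment list")
  finite_periods <- vapply(segments, function(s)
    if (s$kind == "hold") Inf else s$period_s, numeric(1))
  if (any(is.finite(finite_periods)) &&
      fs_hz <= 2 / min(finite_periods[is.finite(finite_periods)]))
    stop("`fs_hz` too low to sample the fastest breath period")

  breaths <- .with_seed(seed, {
    rows <- list()
    t0 <- 0
    for (s in segments) {
      if (s$kind != "hold") {
        st <- t0
        end <- t0 + s$duration_s
        repeat {
          Tk <- s$period_s *
            (1 + s$period_jitter_fraction * runif(1, -1, 1))
          if (st + Tk > end + 1e-9) break
          rows[[length(rows) + 1L]] <- c(st, Tk, s$amplitude)
          st <- st + Tk
        }
      }
      t0 <- t0 + s$duration_s
    }
    if (length(rows)) {
      m <- do.call(rbind, rows)
      data.frame(start_s = m[, 1], period_s = m[, 2], amplitude = m[, 3])
    } else {
      data.frame(start_s = numeric(0), period_s = numeric(0),
                 amplitude = numeric(0))
    }
  })
  duration <- sum(vapply(segments, `[[`, numeric(1), "duration_s"))
  fun <- function(t) {
    out <- numeric(length(t))
    if (!nrow(breaths)) return(out)
    i <- findInterval(t, breaths$start_s)
    ok <- i >= 1L
    tau <- t[ok] - breaths$start_s[i[ok]]
    Tk <- breaths$period_s[i[ok]]
    A <- breaths$amplitude[i[ok]]
    v <- ifelse(tau < Tk, A * (1 - cos(2 * pi * tau / Tk)) / 2, 0)
    out[ok] <- v
    out
  }
  ts <- seq(0, duration, by = 1 / fs_hz)
  structure(list(timestamps_s = ts, values = fun(ts), fun = fun,
                 breaths = breaths, duration_s = duration, fs_hz = fs_hz,
                 segments = segments, seed = seed),
            class = "breath_waveform")
}

#' @export
print.breath_waveform <- function(x, ...) {
  cat(sprintf("<breath_waveform> %.1f s, %d breaths, fs %.0f Hz\n",
              x$duration_s, nrow(x$breaths), x$fs_hz))
  invisible(x)
}

# Default background gains (ppb per unit waveform) for the 16 solid-harmonic
# columns. The zeroth-order gain of 2.5 ppb matches typical zeroth-order
# respiratory excursions at 3 T; higher orders are set so the peak-to-trough
# excursion inside the phantom mask spans a few negative to ~+10 ppb,
# dominated by the low orders (the z term is strongest, as chest motion
# mostly modulates the through-slice gradient).
.default_gains <- function() {
  c(c00 = 2.5,
    c1p1 = 1.2, c1m1 = -0.8, c10 = 5.0,
    c2m2 = 1.5, c2p1 = -1.0, c2m1 = 2.0, c2p2 = 0.8, c20 = 3.5,
    c3m3 = 0.5, c3m2 = -0.4, c3m1 = 0.8, c30 = 1.5, c3p1 = 0.6,
    c3p2 = -0.5, c3p3 = 0.3)
}

# Default susceptibility sources (0-based voxel centres): a tissue-scale
# inclusion inside the brain (static local field) and a strong source outside
# the mask whose dipole field is harmonic inside it (static background,
# steep enough to wrap the phase near the brain edge).
.default_sources <- function(dims3) {
  ctr <- (dims3 - 1) / 2
  list(list(center = round(ctr + c(4, -2, 0)), radius_vox = 3,
            dchi_ppb = 100),
       list(center = c(dims3[1] - 2, round(ctr[2]), round(ctr[3])),
            radius_vox = 2, dchi_ppb = 3000))
}

#' Phantom specification
#'
#' Defaults emulate the study protocol at desk scale: a 32 x 32 x 20 grid of
#' 2.5 mm voxels, TR 1.15 s, TE 30 ms at 3 T, 120 volumes of free breathing
#' with a 4.8 s mean period, a static dipole local field plus a strong
#' external (harmonic) source, a solid-harmonic background modulated by the
#' breathing waveform with excursions of a few ppb to ~+10 ppb, and complex
#' Gaussian noise at 2% of the magnitude (typical EPI SNR ~50).
#'
#' @param dims grid dimensions (nx, ny, nz, nt).
#' @param voxel_mm isotropic voxel size (mm).
#' @param tr_s,te_s,b0_t acquisition metadata.
#' @param susceptibility_sources list of `list(center, radius_vox, dchi_ppb)`
#'   spheres (0-based voxel centres).
#' @param background_gains length-16 vector of ppb per unit waveform.
#' @param waveform list of [breath_segment()]; default one free-breathing
#'   segment covering the scan.
#' @param noise_sd complex-noise SD relative to unit magnitude.
#' @param mask_semi_axes ellipsoid semi-axes of the brain mask, in voxels.
#' @param seed RNG seed (waveform jitter and noise).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(32L, 32L, 20L, 120L), voxel_mm = 2.5,
                         tr_s = 1.15, te_s = 0.030, b0_t = 3.0,
                         susceptibility_sources = .default_sources(dims[1:3]),
                         background_gains = .default_gains(),
                         waveform = list(breath_segment("free",
                                           duration_s = dims[4] * tr_s)),
                         noise_sd = 0.02,
                         mask_semi_axes = pmax(3, round(0.375 * dims[1:3])),
                         seed = 1L) {
  if (length(dims) != 4L) stop("`dims` must be (nx, ny, nz, nt)")
  if (any(dims[1:3] < c(16L, 16L, 8L)))
    stop("grid must be at least 16 x 16 x 8")
  if (dims[4] < 2L) stop("need at least 2 volumes")
  if (any(c(tr_s, te_s, b0_t) <= 0)) stop("tr_s, te_s, b0_t must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (length(background_gains) != 16L)
    stop("`background_gains` must have 16 entries")
  structure(list(dims = as.integer(dims), voxel_mm = voxel_mm, tr_s = tr_s,
                 te_s = te_s, b0_t = b0_t,
                 susceptibility_sources = susceptibility_sources,
                 background_gains = background_gains, waveform = waveform,
                 noise_sd = noise_sd, mask_semi_axes = mask_semi_axes,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# 0-based voxel coordinate arrays for a grid.
.grid_coords <- function(d) {
  list(x = array(rep(0:(d[1] - 1), d[2] * d[3]), d),
       y = array(rep(rep(0:(d[2] - 1), each = d[1]), d[3]), d),
       z = array(rep(0:(d[3] - 1), each = d[1] * d[2]), d))
}

#' Simulate a phantom EPI phase series with known ground truth
#'
#' Builds an ellipsoidal brain mask, a static local field from spherical
#' susceptibility inclusions (frequency-space dipole-kernel convolution), and
#' a time-varying harmonic background `B(r, t) = w(t) * sum_lm g_lm S_lm(r)`
#' driven by the breathing waveform. The complex EPI signal is
#' `mask * exp(i * phase) + noise` with the phase accrued at TE; the exported
#' phase is the angle of the noisy signal, wrapped into (-pi, pi] by
#' construction.
#'
#' @param spec [phantom_spec()].
#' @return list with `phase` ([epi_phase_series()]), `mask` ([brain_mask()])
#'   and `truth`: `waveform` (the [generate_breathing_waveform()] object),
#'   `waveform_volumes` (waveform at volume times), `coefficients` (N x 16
#'   true background coefficient series, ppb), `local_field_ppb` (static
#'   dipole field) and `background_pattern_ppb` (static spatial pattern
#'   multiplying the waveform).
#' @export
simulate_phantom_epi <- function(spec = phantom_spec()) {
  d3 <- spec$dims[1:3]
  nt <- spec$dims[4]
  g <- .grid_coords(d3)
  ctr <- (d3 - 1) / 2
  semi <- spec$mask_semi_axes
  mask <- brain_mask(((g$x - ctr[1]) / semi[1])^2 +
                     ((g$y - ctr[2]) / semi[2])^2 +
                     ((g$z - ctr[3]) / semi[3])^2 <= 1)

  chi <- array(0, d3)
  for (s in spec$susceptibility_sources) {
    cc <- s$center
    if (any(cc < 0) || any(cc > d3 - 1))
      stop("susceptibility source centre outside the grid")
    inside <- (g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2 <=
      s$radius_vox^2
    chi[inside] <- chi[inside] + s$dchi_ppb
  }
  local_field <- dipole_field_ppb(chi)

  # Background spatial pattern: solid harmonics in the same normalized frame
  # the fitting stage uses (mask centroid origin, half largest mask extent).
  mm <- cbind(g$x[mask], g$y[mask], g$z[mask]) * spec$voxel_mm
  origin <- colMeans(mm)
  scale <- max(apply(mm, 2, function(v) diff(range(v)))) / 2
  all_mm <- cbind(as.vector(g$x), as.vector(g$y), as.vector(g$z)) *
    spec$voxel_mm
  u <- sweep(all_mm, 2, origin) / scale
  S <- .sh_evaluate(u[, 1], u[, 2], u[, 3], order = 3L)
  bg_pattern <- array(S %*% spec$background_gains, d3)

  out <- .with_seed(spec$seed, {
    wave <- generate_breathing_waveform(spec$waveform, fs_hz = 500,
                                        seed = spec$seed)
    w_vol <- wave$fun((0:(nt - 1)) * spec$tr_s)
    phase <- array(0, c(d3, nt))
    nvox <- prod(d3)
    for (t in seq_len(nt)) {
      f <- local_field + w_vol[t] * bg_pattern
      ph <- wrap_phase(field_ppb_to_phase(f, spec$te_s, spec$b0_t))
      sig <- as.numeric(mask) * exp(1i * ph)
      if (spec$noise_sd > 0)
        sig <- sig + complex(real = rnorm(nvox, 0, spec$noise_sd),
                             imaginary = rnorm(nvox, 0, spec$noise_sd))
      phase[, , , t] <- Arg(sig)
    }
    list(wave = wave, w_vol = w_vol, phase = phase)
  })

  list(phase = epi_phase_series(out$phase, tr_s = spec$tr_s,
                                te_s = spec$te_s, b0_t = spec$b0_t,
                                voxel_mm = spec$voxel_mm),
       mask = mask,
       truth = list(waveform = out$wave,
                    waveform_volumes = out$w_vol,
                    coefficients = outer(out$w_vol, spec$background_gains),
                    local_field_ppb = local_field,
                    background_pattern_ppb = bg_pattern,
                    spec = spec))
}

#' Simulate a breathing-belt trace from a ground-truth waveform
#'
#' `belt = scale * waveform + slow sinusoidal drift + white noise + spikes`.
#' Belt units are arbitrary; only the shape matters downstream.
#'
#' @param waveform [generate_breathing_waveform()] output.
#' @param fs_hz belt sampling rate (Hz); 500 Hz matches a scanner
#'   respiratory physiology sensor.
#' @param amplitude_scale positive gain applied to the waveform.
#' @param drift_amplitude amplitude of the sinusoidal baseline drift.
#' @param drift_period_s period of the baseline drift (s).
#' @param noise_sd white-noise SD.
#' @param n_spikes number of impulsive outliers at seeded times.
#' @param spike_amplitude spike magnitude as a multiple of the waveform
#'   amplitude range.
#' @param seed RNG seed.
#' @return [belt_trace()].
#' @export
simulate_belt_from_waveform <- function(waveform, fs_hz = 500,
                                        amplitude_scale = 1,
                                        drift_amplitude = 0.2,
                                        drift_period_s = 60,
                                        noise_sd = 0.02,
                                        n_spikes = 10,
                                        spike_amplitude = 10,
                                        seed = 1L) {
  if (amplitude_scale <= 0) stop("`amplitude_scale` must be positive")
  t <- seq(0, waveform$duration_s, by = 1 / fs_hz)
  base <- amplitude_scale * waveform$fun(t)
  rng <- diff(range(base))
  if (rng == 0) rng <- 1
  .with_seed(seed, {
    x <- base +
      drift_amplitude * sin(2 * pi * t / drift_period_s + runif(1, 0, 2 * pi)) +
      rnorm(length(t), 0, noise_sd)
    if (n_spikes > 0) {
      at <- sample(length(t), min(n_spikes, length(t)))
      x[at] <- x[at] + spike_amplitude * rng *
        sample(c(-1, 1), length(at), replace = TRUE) * runif(length(at), 0.5, 1)
    }
    belt_trace(t, x, fs_hz = fs_hz)
  })
}
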