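# Belt preprocessing, peak metrics and respiratory phase synthesis.

test_that("preprocessing is near-identity on a clean sinusoid", {
  t <- seq(0, 60, by = 1 / 500)
  x <- sin(2 * pi * 0.25 * t)
  out <- preprocess_belt(belt_trace(t, x, 500))
  expect_gt(cor(out$amplitude, x), 0.999)
  expect_equal(out$timestamps_s, t)
  expect_error(preprocess_belt(belt_trace(t, x, 500), lowpass_hz = 300),
               "Nyquist")
})

test_that("inserted spikes are removed to within 5% RMS", {
  set.seed(71)
  t <- seq(0, 60, by = 1 / 500)
  clean <- sin(2 * pi * 0.25 * t)
  x <- clean
  at <- sample(seq(500, length(t) - 500), 10)
  x[at] <- x[at] + 10 * sample(c(-1, 1), 10, replace = TRUE)
  out <- preprocess_belt(belt_trace(t, x, 500))
  expect_lt(sqrt(mean((out$amplitude - clean)^2)),
            0.05 * sqrt(mean(clean^2)))
})

test_that("alignment recovers an injected belt clock offset", {
  set.seed(72)
  wave <- generate_breathing_waveform(breath_segment("free", 120), seed = 4)
  reg <- resp_regressor(wave$fun((0:90) * 1.15), tr_s = 1.15)
  belt0 <- belt_trace(wave$timestamps_s, wave$values, 500)
  al0 <- align_traces(reg, belt0)
  expect_equal(al0$lag_s, 0, tolerance = 1e-9)
  # belt recorded on a clock running 2.3 s ahead
  belt_sh <- belt_trace(wave$timestamps_s + 2.3, wave$values, 500)
  al <- align_traces(reg, belt_sh)
  expect_lt(abs(al$lag_s - 2.3), 1.15 / 2)
  # sign-flipped regressor gives the same lag (absolute correlation)
  reg_f <- resp_regressor(-reg$values, tr_s = 1.15)
  expect_equal(align_traces(reg_f, belt_sh)$lag_s, al$lag_s)
  bad <- belt_trace(wave$timestamps_s + 1e5, wave$values, 500)
  expect_error(align_traces(reg, bad), "overlap")
})

test_that("sinusoid peaks land at the analytic times", {
  fs <- 50
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  pk <- detect_peaks(sin(2 * pi * 0.25 * t), t)
  expect_length(pk, 15)
  expect_lt(max(abs(as.numeric(pk) - (1 + 4 * (0:14)))), 1 / fs)
  expect_length(detect_peaks(rep(1, 100), seq_len(100)), 0)
})

test_that("detect_peaks equals the exhaustive-scan oracle on random breathing", {
  for (seed in 1:100) {
    wave <- generate_breathing_waveform(
      breath_segment("free", 40, period_s = runif(1, 2.5, 6)),
      fs_hz = 8, seed = seed)
    set.seed(seed + 5000)
    x <- wave$values + rnorm(length(wave$values), sd = 0.05)
    got <- detect_peaks(x, wave$timestamps_s)
    want <- oracle_peaks(x, wave$timestamps_s)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
})

test_that("peak matching is greedy one-to-one within the window", {
  a <- peak_set(seq(2, 58, by = 4))
  self <- match_peaks(a, a)
  expect_equal(self$overlap_fraction, 1.0)
  shifted <- peak_set(as.numeric(a) + 0.6)
  expect_equal(match_peaks(a, shifted, window_s = 0.575)$overlap_fraction, 0)
  inside <- peak_set(as.numeric(a) + 0.5)
  expect_equal(match_peaks(a, inside, window_s = 0.575)$overlap_fraction, 1)
  # symmetry of the overlap fraction
  b <- peak_set(c(1.9, 6.2, 14.1, 30.3))
  expect_equal(match_peaks(a, b)$overlap_fraction,
               match_peaks(b, a)$overlap_fraction)
})

test_that("agreement report reproduces the direct formulas", {
  a <- peak_set(seq(2, 118, by = 4))
  expect_equal(agreement_report(a, a)$period_rmse_s, 0)
  expect_equal(agreement_report(a, a)$mean_peak_error_s, 0)
  set.seed(73)
  jit <- rnorm(length(a), sd = 0.1)
  b <- peak_set(as.numeric(a) + jit)
  rep <- agreement_report(a, b, window_s = 0.575)
  expect_equal(rep$n_matched, length(a))
  expect_equal(rep$mean_peak_error_s, mean(abs(jit)))
  expect_equal(rep$period_rmse_s, sqrt(mean(diff(jit)^2)))
  expect_equal(rep$mean_period_a_s, 4, tolerance = 1e-12)
  # single matched pair: period metrics undefined, overlap still reported
  r1 <- agreement_report(peak_set(2), peak_set(2.1))
  expect_true(is.na(r1$period_rmse_s))
  expect_equal(r1$overlap_fraction, 1)
})

test_that("an exactly periodic trace yields its period", {
  fs <- 25
  t <- seq(0, 80 - 1 / fs, by = 1 / fs)
  pk <- detect_peaks(cos(2 * pi * t / 4), t)
  rep <- agreement_report(pk, pk)
  expect_equal(rep$mean_period_a_s, 4, tolerance = 1 / fs)
})

test_that("histogram phase matches the brute-force oracle on a sinusoid", {
  t <- seq(0, 40, by = 0.05)
  x <- sin(2 * pi * 0.25 * t)
  got <- respiratory_phase_histogram(x, t)
  expect_equal(got$phase_rad, oracle_histogram_phase(x), tolerance = 1e-12)
  expect_true(all(got$phase_rad > -pi & got$phase_rad <= pi))
  # |phase| = pi at the global maximum; at the global minimum it is bounded
  # by pi times the occupancy of the lowest histogram bin
  imax <- which.max(x); imin <- which.min(x)
  expect_equal(abs(got$phase_rad[imax]), pi)
  lowest_bin <- mean(x <= min(x) + diff(range(x)) / 100)
  expect_lte(abs(got$phase_rad[imin]), pi * lowest_bin + 1e-12)
  expect_error(respiratory_phase_histogram(rep(2, 50)), "constant")
})

test_that("a symmetric triangle wave gives |phase| linear in amplitude", {
  t <- seq(0, 40, by = 0.01)
  x <- 2 * abs((0.25 * t) %% 1 - 0.5)   # uniform amplitude distribution
  ph <- respiratory_phase_histogram(x, t, n_bins = 100)
  u <- (x - min(x)) / diff(range(x))    # analytic uniform CDF
  expect_lt(max(abs(abs(ph$phase_rad) / pi - u)), 2 / 100 + 1e-6)
})

test_that("histogram phase is monotone on rising stretches and affine-invariant", {
  set.seed(74)
  wave <- generate_breathing_waveform(breath_segment("free", 60), fs_hz = 20,
                                      seed = 9)
  x <- wave$values
  ph <- respiratory_phase_histogram(x, wave$timestamps_s)$phase_rad
  sl <- c(0, diff(x))
  rising <- which(sl[-1] > 0 & sl[-length(sl)] > 0)
  ord <- rising[order(x[rising])]
  expect_true(all(diff(ph[ord]) >= -1e-12))
  # affine invariance up to one histogram bin (bin edges shift in float)
  ph2 <- respiratory_phase_histogram(3.2 * x + 7, wave$timestamps_s)$phase_rad
  expect_lt(max(abs(ph2 - ph)), 2 * pi / 100 + 1e-9)
})

test_that("Hilbert phase recovers tone and chirp frequencies", {
  dt <- 0.05
  t <- seq(0, 120, by = dt)
  ph <- respiratory_phase_hilbert(cos(2 * pi * 0.25 * t), t)
  expect_true(all(ph$phase_rad > -pi & ph$phase_rad <= pi))
  un <- cumsum(c(ph$phase_rad[1], wrap_phase(diff(ph$phase_rad))))
  interior <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  slope <- coef(lm(un[interior] ~ t[interior]))[2]
  expect_lt(abs(slope - 2 * pi * 0.25) / (2 * pi * 0.25), 0.01)
  # two-segment piecewise-constant frequency
  t1 <- seq(0, 60 - dt, by = dt)
  x2 <- c(cos(2 * pi * 0.2 * t1), cos(2 * pi * 0.4 * t1))
  t2 <- seq(0, by = dt, length.out = length(x2))
  ph2 <- respiratory_phase_hilbert(x2, t2)$phase_rad
  inst <- wrap_phase(diff(ph2)) / (2 * pi * dt)
  seg1 <- inst[200:900]; seg2 <- inst[1400:2200]
  expect_lt(max(abs(seg1 - 0.2) / 0.2), 0.05)
  expect_lt(max(abs(seg2 - 0.4) / 0.4), 0.05)
  # affine invariance
  ph3 <- respiratory_phase_hilbert(5 * cos(2 * pi * 0.25 * t) - 2, t)
  expect_equal(ph3$phase_rad, ph$phase_rad, tolerance = 1e-9)
  expect_error(respiratory_phase_hilbert(rep(1, 50)), "constant")
})
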