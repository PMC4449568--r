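test_that("DC extraction has unit DC gain and strong stopband attenuation", {
  fs <- 100
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  # constant in, constant out, exactly
  const <- waveform(rep(87.3, length(tt)), fs = fs)
  expect_equal(lowpass_dc(const)$value, rep(87.3, length(tt)), tolerance = 1e-12)
  # 1 Hz oscillation suppressed below 2% of its amplitude
  A <- 20
  x <- waveform(90 + A * sin(2 * pi * 1 * tt), fs = fs)
  y <- lowpass_dc(x)
  mid <- y$value[y$time_s > 5 & y$time_s < 55]
  expect_lt((max(mid) - min(mid)) / 2, 0.02 * A)
  # mean preserved to < 0.1 %
  expect_lt(abs(mean(y$value) - mean(x$value)) / mean(x$value), 0.001)
  # idempotence on an already band-limited signal, away from the ends: the
  # filter's slowest pole decays with a ~2 s e-folding, so reflection-pad
  # transients are negligible ~15 s in
  y2 <- lowpass_dc(y)
  interior <- y$time_s > 15 & y$time_s < 45
  expect_lt(max(abs(y2$value[interior] - y$value[interior])), 1e-3 * A)
  # cutoff must be supportable
  expect_error(lowpass_dc(waveform(1:10, fs = 0.3)), class = "nicp_error_input")
})

test_that("DC extraction preserves the mean of pulsatile recordings", {
  for (seed in 1:3) {
    abp <- synth_abp(synth_config(duration = 60, seed = seed))
    dc <- lowpass_dc(abp)
    expect_lt(abs(mean(dc$value) - mean(abp$value)) / mean(abp$value), 0.001)
  }
})

test_that("beat detection finds one onset per cycle and rejects flat signals", {
  abp <- synth_abp(synth_config(duration = 30, heart_rate = 60, hr_jitter = 0,
                                noise_std = 0, seed = 4))
  expect_true(abs(nrow(detect_beats(abp)) - 30) <= 1)
  expect_error(detect_beats(waveform(rep(5, 1000), fs = 100)),
    class = "nicp_error_detection")
  # robust to additive noise at 5% of the pulse amplitude
  noisy <- waveform(abp$value + rnorm(nrow(abp), 0, 0.05 * 40), fs = 100)
  expect_true(abs(nrow(detect_beats(noisy)) - 30) <= 2)
})

test_that("detected beat intervals track the generated heart rate", {
  abp <- synth_abp(synth_config(duration = 60, heart_rate = 75, hr_jitter = 0.05,
                                noise_std = 0, seed = 12))
  beats <- detect_beats(abp)
  expect_lt(abs(mean(diff(beats$onset_s)) - 0.8) / 0.8, 0.02)
})

test_that("beat features follow the end-diastolic convention and scale equivariantly", {
  # triangular beats ramping 40 -> 80 -> 40 at 1 Hz
  fs <- 100
  phase <- ((seq_len(10 * fs) - 1) / fs) %% 1
  tri <- 40 + 80 * ifelse(phase < 0.5, phase, 1 - phase)
  w <- waveform(tri, fs = fs)
  feats <- beat_features(w, detect_beats(w))
  expect_equal(max(feats$systolic), 80, tolerance = 1)
  expect_equal(median(feats$diastolic), 40, tolerance = 1)
  # mean equals the arithmetic sample mean over the beat
  b <- detect_beats(w)
  j <- 2
  expect_equal(
    feats$mean_value[j],
    mean(tri[b$onset_idx[j]:(b$onset_idx[j + 1] - 1)])
  )
  # scaling the signal scales all features by the same factor
  w3 <- waveform(3 * tri, fs = fs)
  f3 <- beat_features(w3, detect_beats(w3))
  expect_equal(f3$systolic, 3 * feats$systolic, tolerance = 1e-9)
  expect_equal(f3$diastolic, 3 * feats$diastolic, tolerance = 1e-9)
  expect_equal(f3$mean_value, 3 * feats$mean_value, tolerance = 1e-9)
})

test_that("the ABP-CBFv time shift is recovered to one sample", {
  abp <- synth_abp(synth_config(duration = 30, noise_std = 0, hr_jitter = 0.03, seed = 21))
  fs <- wave_fs(abp)
  # identical signals: zero shift exactly
  expect_equal(estimate_time_shift(abp, abp), 0)
  # scaled copy: zero shift
  scaled <- waveform(abp$value * 0.8, fs = fs)
  expect_lt(abs(estimate_time_shift(abp, scaled)), 1 / fs + 1e-12)
  # ABP delayed 80 ms relative to CBFv
  k <- round(0.08 * fs)
  delayed <- waveform(c(rep(abp$value[1], k), abp$value[1:(nrow(abp) - k)]), fs = fs)
  tau <- estimate_time_shift(delayed, abp)
  expect_lt(abs(tau - 0.08), 1 / fs + 1e-12)
  # same construction with 2% noise, across seeds
  for (seed in 1:5) {
    noisy <- withr::with_seed(seed, waveform(
      delayed$value + rnorm(nrow(delayed), 0, 0.02 * 40), fs = fs))
    expect_lt(abs(estimate_time_shift(noisy, abp) - 0.08), 0.01 + 1e-12)
  }
})

test_that("apply_time_shift advances the trace per the alignment convention", {
  fs <- 100
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- waveform(sin(2 * pi * tt), fs = fs)
  y <- apply_time_shift(x, 0.25) # quarter period of 1 Hz -> cosine
  mid <- 100:800
  expect_equal(y$value[mid], cos(2 * pi * tt[mid]), tolerance = 1e-3)
})
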