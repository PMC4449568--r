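test_that("synthetic ABP hits the configured mean and beat count", {
  abp <- synth_abp(synth_config(
    duration = 60, fs = 100, heart_rate = 60, mean_abp = 90,
    pulse_pressure = 40, hr_jitter = 0, noise_std = 0, seed = 11
  ))
  expect_gt(mean(abp$value), 88)
  expect_lt(mean(abp$value), 92)
  beats <- detect_beats(abp)
  expect_true(abs(nrow(beats) - 60) <= 1)
  # single systolic peak per beat: in-beat maximum is unique and interior
  feats <- beat_features(abp, beats)
  expect_true(all(feats$systolic > feats$diastolic))
})

test_that("degenerate pulse pressure yields a constant trace at the mean", {
  abp <- synth_abp(synth_config(
    duration = 10, pulse_pressure = 0, noise_std = 0, seed = 2
  ))
  expect_equal(abp$value, rep(90, nrow(abp)))
})

test_that("identical config and seed reproduce bit-identical waveforms", {
  cfg <- synth_config(duration = 20, seed = 42)
  expect_identical(synth_abp(cfg)$value, synth_abp(cfg)$value)
  trial <- function() synth_vm_trial(synth_config(duration = 45, vm_window = c(15, 30), seed = 9))
  a <- trial(); b <- trial()
  expect_identical(a$abp$value, b$abp$value)
  expect_identical(a$cbfv$value, b$cbfv$value)
  expect_identical(a$icp_true$value, b$icp_true$value)
})

test_that("beat count stays within one of duration * heart_rate / 60 without jitter", {
  for (hr in c(50, 75, 100)) {
    abp <- synth_abp(synth_config(
      duration = 30, heart_rate = hr, hr_jitter = 0, noise_std = 0, seed = hr
    ))
    expect_true(abs(nrow(detect_beats(abp)) - 30 * hr / 60) <= 1)
  }
})

test_that("the VM episode shifts the ABP mean by the configured offset", {
  cfg <- synth_config(
    duration = 45, vm_window = c(15, 30), vm_abp_delta = 10,
    noise_std = 0, hr_jitter = 0, seed = 3
  )
  abp <- synth_abp(cfg)
  rest <- mean(abp$value[abp$time_s < 14])
  vm <- mean(abp$value[abp$time_s >= 17 & abp$time_s < 29])
  expect_equal(vm - rest, 10, tolerance = 0.15)
})

test_that("raising the venous source during VM raises true ICP, and only then", {
  base <- synth_config(duration = 45, vm_window = c(15, 30), vm_abp_delta = 0, seed = 5)
  seg <- segment_trial(45, base$fs)
  for (delta in c(5, 10, 20)) {
    cfg <- base; cfg$vm_pvs_delta <- delta
    pm <- phase_means(synth_vm_trial(cfg)$icp_true, seg)
    expect_gt(pm$vm_mean, pm$rest_mean)
  }
  cfg0 <- base; cfg0$vm_pvs_delta <- 0
  pm0 <- phase_means(synth_vm_trial(cfg0)$icp_true, seg)
  expect_lt(abs(pm0$vm_mean - pm0$rest_mean), 0.2)
})

test_that("the simulated VM ICP rise is bounded by the steady-state response and matches an independent integrator", {
  cfg <- synth_config(
    duration = 45, vm_window = c(15, 30), vm_pvs_delta = 10, vm_abp_delta = 0,
    noise_std = 0, hr_jitter = 0, seed = 8
  )
  trial <- synth_vm_trial(cfg)
  seg <- segment_trial(45, cfg$fs)
  pm <- phase_means(trial$icp_true, seg)
  rise <- pm$vm_mean - pm$rest_mean
  # the steady-state response to the perturbed source bounds the 15-s rise:
  # the slow CSF mode has not settled within the maneuver window
  ss_rise <- oracle_steady_state(cfg$mean_abp, pvs_offset = 10)$Pic -
    oracle_steady_state(cfg$mean_abp, pvs_offset = 0)$Pic
  expect_gt(rise, 0.2 * ss_rise)
  expect_lt(rise, ss_rise)
  # independent dynamic oracle: integrate the same circuit with lsoda
  p <- ursino_params()
  m <- nicp:::ursino_matrices(p)
  A <- solve(m$M, -m$G); B <- solve(m$M, m$S)
  abp <- trial$abp
  paf <- stats::approxfun(abp$time_s, abp$value, rule = 2)
  off <- stats::approxfun(abp$time_s,
    nicp:::vm_offset(abp$time_s, cfg$vm_window, cfg$vm_pvs_delta, cfg$duration),
    rule = 2)
  x0 <- solve(m$G, m$S %*% c(mean(abp$value), p$Pcv))
  out <- deSolve::ode(
    y = drop(x0), times = abp$time_s,
    func = function(t, x, parms) list(drop(A %*% x + B %*% c(paf(t), p$Pcv + off(t)))),
    method = "lsoda", rtol = 1e-9, atol = 1e-9
  )
  ref_icp <- waveform(out[, 6], fs = cfg$fs, units = "mmHg")
  pm_ref <- phase_means(ref_icp, seg)
  expect_equal(rise, pm_ref$vm_mean - pm_ref$rest_mean, tolerance = 1e-3)
})

test_that("invalid generator configurations name the offending field", {
  expect_error(synth_config(duration = -1), regexp = "duration", class = "nicp_error_config")
  expect_error(synth_config(fs = 0), regexp = "fs", class = "nicp_error_config")
  expect_error(synth_config(pulse_pressure = -5), regexp = "pulse_pressure",
    class = "nicp_error_config")
  expect_error(synth_config(vm_window = c(50, 70), duration = 45), regexp = "vm_window",
    class = "nicp_error_config")
  expect_error(synth_vm_trial(synth_config(duration = 60)), class = "nicp_error_config")
})
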