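#' Configuration for the synthetic waveform generator
#'
#' Defines the study conditions the generator emulates: a pulsatile ABP
#' recording at a physiological mean and pulse pressure, optionally with a
#' Valsalva-maneuver (VM) episode that perturbs systemic pressure and raises
#' the central venous / sinus source pressure of the intracranial circuit.
#'
#' @param duration recording length, seconds.
#' @param fs sampling rate, samples/second.
#' @param heart_rate beats/minute.
#' @param mean_abp time-averaged ABP, mmHg.
#' @param pulse_pressure systolic minus diastolic ABP, mmHg.
#' @param hr_jitter fractional standard deviation of the beat-to-beat
#'   interval (0 = metronomic).
#' @param noise_std additive white measurement noise on ABP, mmHg.
#' @param cbfv_noise_std additive white noise on synthetic CBFv, cm/s.
#' @param vm_window `c(start, end)` of the VM episode in seconds, or `NULL`
#'   for no maneuver.
#' @param vm_abp_delta systemic pressure offset during the VM, mmHg.
#' @param vm_pvs_delta venous-sinus / central-venous source pressure rise
#'   during the VM, mmHg (drives the true-ICP increase).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output. `NULL` draws from the session RNG.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration = 60, fs = 100, heart_rate = 70,
                         mean_abp = 90, pulse_pressure = 40,
                         hr_jitter = 0.02, noise_std = 1, cbfv_noise_std = 1,
                         vm_window = NULL, vm_abp_delta = 10,
                         vm_pvs_delta = 10, seed = NULL) {
  cfg <- list(
    duration = duration, fs = fs, heart_rate = heart_rate,
    mean_abp = mean_abp, pulse_pressure = pulse_pressure,
    hr_jitter = hr_jitter, noise_std = noise_std,
    cbfv_noise_std = cbfv_noise_std, vm_window = vm_window,
    vm_abp_delta = vm_abp_delta, vm_pvs_delta = vm_pvs_delta, seed = seed
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  pos1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_config(sprintf("`%s` must be a single positive number.", field))
    }
  }
  pos1("duration"); pos1("fs"); pos1("heart_rate")
  for (field in c("pulse_pressure", "hr_jitter", "noise_std", "cbfv_noise_std")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop_config(sprintf("`%s` must be a single non-negative number.", field))
    }
  }
  if (cfg$hr_jitter > 0.2) {
    stop_config("`hr_jitter` above 0.2 would allow non-physiological beat intervals.")
  }
  if (!is.numeric(cfg$mean_abp) || length(cfg$mean_abp) != 1 || !is.finite(cfg$mean_abp)) {
    stop_config("`mean_abp` must be a single finite number.")
  }
  if (!is.null(cfg$vm_window)) {
    vw <- cfg$vm_window
    if (!is.numeric(vw) || length(vw) != 2 || any(!is.finite(vw)) ||
        vw[1] >= vw[2] || vw[1] < 0 || vw[2] > cfg$duration) {
      stop_config("`vm_window` must be c(start, end) within [0, duration].")
    }
  }
  invisible(cfg)
}

# Asymmetric-Gaussian single-peak pulse shape over beat phase [0, 1):
# fast systolic upstroke (sd 0.09 of the beat) peaking at 25% of the cycle,
# slower monotone diastolic runoff (sd 0.35).
pulse_shape <- function(phi) {
  sg <- ifelse(phi <= 0.25, 0.09, 0.35)
  exp(-(phi - 0.25)^2 / (2 * sg^2))
}

# Full-cycle mean of the pulse shape. Beats are centred by this constant —
# not by the mean of their visible samples — so a beat truncated by the
# record boundary keeps its natural above/below-mean character instead of
# being artificially re-centred, which would bias boundary-adjacent
# analysis windows.
pulse_shape_mean <- mean(pulse_shape(seq(0, 1, length.out = 20001)[-20001]))

# Beat onset times covering [0, duration]; lengths jittered multiplicatively,
# truncated at 3 sd so intervals stay positive (hr_jitter is capped at 0.2).
# The recording starts at a uniformly random beat phase: real recordings do
# not begin at a beat onset, and a deterministic start phase would make the
# partial-beat content of fixed protocol windows systematic instead of
# averaging out across trials.
draw_onsets <- function(cfg) {
  t_beat <- 60 / cfg$heart_rate
  on <- -stats::runif(1) * t_beat
  while (on[length(on)] < cfg$duration + t_beat) {
    k <- max(8, ceiling((cfg$duration + 2 * t_beat - on[length(on)]) / t_beat * 1.5))
    z <- pmax(pmin(rnorm(k), 3), -3)
    on <- c(on, on[length(on)] + cumsum(t_beat * (1 + cfg$hr_jitter * z)))
  }
  on[seq_len(which(on >= cfg$duration + t_beat)[1])]
}

# Piecewise-linear plateau offset: 1 s up-ramp starting at the window onset,
# plateau, 1 s down-ramp starting at the window end.
vm_offset <- function(time_s, vm_window, delta, duration) {
  if (is.null(vm_window) || delta == 0) return(numeric(length(time_s)))
  vs <- vm_window[1]; ve <- vm_window[2]
  knots_t <- c(-1, vs, min(vs + 1, ve), ve, min(ve + 1, duration + 1), duration + 2)
  knots_v <- c(0, 0, delta, delta, 0, 0)
  approx(knots_t, knots_v, xout = time_s, rule = 2)$y
}

#' Synthesize a pulsatile arterial blood pressure waveform
#'
#' Each beat is an asymmetric-Gaussian pulse with a single systolic peak and
#' a monotone diastolic runoff, scaled to the configured pulse pressure and
#' centred so that every full cardiac cycle averages to `mean_abp` (before
#' the optional VM offset and measurement noise). The recording starts at a
#' random beat phase, as a real recording does. A VM episode, if
#' configured, adds `vm_abp_delta` with 1 s linear ramps at each edge.
#'
#' @param config a [synth_config()].
#' @return An ABP [waveform()] in mmHg.
#' @examples
#' abp <- synth_abp(synth_config(duration = 10, seed = 1))
#' mean(abp$value)
#' @export
synth_abp <- function(config) {
  config <- if (inherits(config, "synth_config")) config else do.call(synth_config, config)
  local_seed_if(config$seed)
  synth_abp_impl(config)
}

synth_abp_impl <- function(cfg) {
  n <- round(cfg$duration * cfg$fs)
  tt <- (0:(n - 1)) / cfg$fs
  on <- draw_onsets(cfg)
  bi <- findInterval(tt, on)
  phi <- (tt - on[bi]) / (on[bi + 1] - on[bi])
  g <- pulse_shape(phi)
  x <- cfg$mean_abp + cfg$pulse_pressure * (g - pulse_shape_mean)
  x <- x + vm_offset(tt, cfg$vm_window, cfg$vm_abp_delta, cfg$duration)
  if (cfg$noise_std > 0) x <- x + rnorm(n, 0, cfg$noise_std)
  w <- waveform(x, fs = cfg$fs, units = "mmHg")
  attr(w, "onsets_s") <- on[on >= 0 & on < cfg$duration]
  w
}

#' Synthesize a 45-second Valsalva-maneuver trial
#'
#' Generates ABP with [synth_abp()], then drives the full Ursino circuit
#' ([ursino_simulate()]) with that ABP while `vm_pvs_delta` is added to the
#' central venous source during the VM window; the simulated arterial inflow
#' gives CBF, and CBFv = CBF / alpha plus measurement noise. The returned
#' true ICP is the simulated intracranial node pressure, so its rise during
#' the maneuver follows from the circuit, not from an imposed shape.
#'
#' @param config a [synth_config()] with `duration = 45` and
#'   `vm_window = c(15, 30)` (the fixed trial protocol).
#' @param params [ursino_params()] for the reference circuit.
#' @param alpha CBF-to-CBFv proportionality, (ml/s)/(cm/s).
#' @return A list with elements `abp`, `cbfv`, `icp_true` ([waveform()]s)
#'   and `sim` (the full [ursino_simulate()] result).
#' @export
synth_vm_trial <- function(config = synth_config(duration = 45, vm_window = c(15, 30)),
                           params = ursino_params(), alpha = 0.15) {
  config <- if (inherits(config, "synth_config")) config else do.call(synth_config, config)
  if (abs(config$duration - 45) > 1e-9 ||
      is.null(config$vm_window) ||
      any(abs(config$vm_window - c(15, 30)) > 1e-9)) {
    stop_config("A VM trial requires duration = 45 s and vm_window = c(15, 30).")
  }
  local_seed_if(config$seed)
  abp <- synth_abp_impl(config)
  pvs <- vm_offset(abp$time_s, config$vm_window, config$vm_pvs_delta, config$duration)
  sim <- ursino_simulate(abp, params = params, pvs_offset = pvs)
  cbfv_val <- sim$Q_cbf / alpha
  if (config$cbfv_noise_std > 0) {
    cbfv_val <- cbfv_val + rnorm(length(cbfv_val), 0, config$cbfv_noise_std)
  }
  list(
    abp = abp,
    cbfv = waveform(cbfv_val, fs = config$fs, units = "cm/s"),
    icp_true = waveform(sim$Pic, fs = config$fs, units = "mmHg"),
    sim = sim
  )
}

local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop_config("`seed` must be a single integer or NULL.")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}
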