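#' Segment the 45-second rest / Valsalva / rest trial
#'
#' The fixed trial protocol: rest for 15 s, Valsalva maneuver for 15 s,
#' rest for 15 s. The first 5 s of the maneuver and the first 10 s of the
#' later rest are excluded from analysis as uncertain transition states, so
#' the analysis windows are `[20, 30)` s (VM) and `[40, 45)` s (late rest).
#' Sample windows are half-open and 0-based: window `[a, b)` seconds maps
#' to samples `[a * fs, b * fs)`.
#'
#' @param duration trial length, seconds; must be 45 (the protocol is
#'   fixed, other durations are rejected).
#' @param fs sampling rate, Hz.
#' @return A tibble with one row per phase window (`rest1`, `vm_full`,
#'   `vm_analysis`, `rest2_full`, `rest2_analysis`): `start_s`, `end_s`,
#'   `start_idx`, `end_idx`.
#' @examples
#' segment_trial(45, 100)
#' @export
segment_trial <- function(duration, fs) {
  if (!is.numeric(duration) || length(duration) != 1 || abs(duration - 45) > 1e-9) {
    stop_input("The trial protocol is fixed at 45 s (15 rest / 15 VM / 15 rest).")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop_input("`fs` must be positive.")
  seg <- tibble(
    phase = c("rest1", "vm_full", "vm_analysis", "rest2_full", "rest2_analysis"),
    start_s = c(0, 15, 20, 30, 40),
    end_s = c(15, 30, 30, 45, 45)
  )
  seg$start_idx <- as.integer(round(seg$start_s * fs))
  seg$end_idx <- as.integer(round(seg$end_s * fs))
  seg
}

# Resample an ICP series (or a waveform) onto a time grid: linear
# interpolation for per-sample series, previous-value hold for per-beat
# step functions.
resample_icp <- function(x, t_grid) {
  val <- if ("icp_mmHg" %in% names(x)) x$icp_mmHg else x$value
  method <- if (identical(attr(x, "granularity"), "beat")) "constant" else "linear"
  approx(x$time_s, val, xout = t_grid, method = method, f = 0, rule = 2)$y
}

#' Root-mean-square error between two ICP series
#'
#' Resamples both series onto the time grid of the finer one over their
#' overlap (linear interpolation for per-sample series, previous-value hold
#' for per-beat step series) and returns the RMSE.
#'
#' @param est,ref ICP series (from an estimator) or [waveform()]s (e.g. a
#'   simulated reference trace).
#' @return RMSE in mmHg.
#' @examples
#' a <- waveform(rep(10, 200), fs = 10, units = "mmHg")
#' b <- waveform(rep(11, 200), fs = 10, units = "mmHg")
#' icp_rmse(a, b)
#' @export
icp_rmse <- function(est, ref) {
  t_lo <- max(min(est$time_s), min(ref$time_s))
  t_hi <- min(max(est$time_s), max(ref$time_s))
  if (t_lo >= t_hi) stop_input("The two series do not overlap in time.")
  fs_e <- 1 / median(diff(est$time_s))
  fs_r <- 1 / median(diff(ref$time_s))
  src <- if (fs_e >= fs_r) est else ref
  grid <- src$time_s[src$time_s >= t_lo & src$time_s <= t_hi]
  sqrt(mean((resample_icp(est, grid) - resample_icp(ref, grid))^2))
}

#' Per-phase mean ICP of a trial
#'
#' Mean estimated ICP over the resting window (`rest1`, the first 15 s,
#' uncontaminated by maneuver recovery) and over the VM analysis window
#' (`[20, 30)` s). The late-rest analysis window mean is returned as well.
#' Per-beat series contribute the beats whose onset falls inside a window;
#' per-sample series contribute their samples.
#'
#' @param icp an ICP series covering the trial.
#' @param seg a segmentation from [segment_trial()].
#' @return A tibble with `rest_mean`, `vm_mean`, `rest2_mean` (mmHg).
#' @export
phase_means <- function(icp, seg) {
  win_mean <- function(phase) {
    row <- seg[seg$phase == phase, ]
    sel <- icp$time_s >= row$start_s & icp$time_s < row$end_s
    if (!any(sel)) {
      stop_input(sprintf("No ICP points fall inside the %s window.", phase))
    }
    val <- if ("icp_mmHg" %in% names(icp)) icp$icp_mmHg else icp$value
    mean(val[sel])
  }
  tibble(
    rest_mean = win_mean("rest1"),
    vm_mean = win_mean("vm_analysis"),
    rest2_mean = win_mean("rest2_analysis")
  )
}

#' One-tailed paired t-test for a Valsalva-induced ICP rise
#'
#' Tests whether the per-trial VM-phase means exceed the paired resting
#' means: with `d = vm - rest`, `t = mean(d) / (sd(d) / sqrt(n))` on
#' `n - 1` degrees of freedom and an upper-tail p-value. Delegates to
#' [stats::t.test()] with `alternative = "greater"`.
#'
#' @param rest,vm paired per-trial phase means, mmHg; equal length, n >= 2.
#' @return A tibble with `n`, `t`, `df`, `p`, `significant`
#'   (`p < 0.05`).
#' @examples
#' paired_t_one_tailed(c(1, 2, 3), c(2, 3, 5))
#' @export
paired_t_one_tailed <- function(rest, vm) {
  if (length(rest) != length(vm)) stop_input("`rest` and `vm` must be paired (equal length).")
  if (length(rest) < 2) stop_input("The paired t-test needs at least 2 trials.")
  d <- vm - rest
  if (sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    stop_numeric("Zero-variance differences: the paired t statistic is degenerate (infinite).")
  }
  ht <- tryCatch(
    stats::t.test(vm, rest, paired = TRUE, alternative = "greater"),
    error = function(e) stop_numeric(sprintf("Paired t-test failed: %s", conditionMessage(e)))
  )
  tibble(
    n = length(rest),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    significant = ht$p.value < 0.05
  )
}

#' Generate a batch of synthetic Valsalva trials
#'
#' Convenience wrapper producing `n_trials` independent [synth_vm_trial()]
#' runs with per-trial seeds derived from `seed`.
#'
#' @param n_trials number of trials.
#' @param config base [synth_config()] (duration 45, VM window 15-30 s).
#' @param seed integer; trial `i` uses seed `seed + i`.
#' @param hr_range per-trial resting heart rate is drawn uniformly from
#'   this range (beats/minute), emulating the trial-to-trial heart-rate
#'   variability of repeated recordings. Without it every trial would cut
#'   the fixed protocol windows at identical beat phases, a phase-locked
#'   artifact real repeated trials do not have. `NULL` keeps
#'   `config$heart_rate` for every trial.
#' @param params,alpha passed to [synth_vm_trial()].
#' @return A list of trials, each a list with `abp`, `cbfv`, `icp_true`.
#' @export
synth_vm_trials <- function(n_trials = 20,
                            config = synth_config(duration = 45, vm_window = c(15, 30)),
                            seed = 1, hr_range = c(60, 80),
                            params = ursino_params(), alpha = 0.15) {
  config <- if (inherits(config, "synth_config")) config else do.call(synth_config, config)
  map(seq_len(n_trials), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed) + i
    if (!is.null(hr_range)) {
      cfg$heart_rate <- withr::with_seed(
        cfg$seed + 499979L,
        stats::runif(1, hr_range[1], hr_range[2])
      )
    }
    synth_vm_trial(cfg, params = params, alpha = alpha)
  })
}

#' Run the Valsalva detection experiment over a set of trials
#'
#' The validation harness: estimates ICP on every 45-s trial with each
#' requested method, computes per-trial rest / VM phase means, summarizes
#' each method's phases as mean +/- sd, and applies the one-tailed paired
#' t-test of VM > rest across trials. Trials on which a method fails are
#' dropped for that method with the reason recorded.
#'
#' @param trials a list of trials, each a list with `abp` and `cbfv`
#'   waveforms (e.g. from [synth_vm_trials()]).
#' @param methods subset of `"sr"`, `"pi"`, `"kashif"`.
#' @param sr,pi,kashif parameter objects for the three estimators. The
#'   two-element window defaults to 5 s here: a 60 s constancy window
#'   cannot subdivide a 45 s trial.
#' @return An object of class `vm_experiment`; see [tidy.vm_experiment()],
#'   [glance.vm_experiment()] and the print method.
#' @examples
#' \donttest{
#' trials <- synth_vm_trials(5, seed = 1)
#' run_vm_experiment(trials, methods = "sr")
#' }
#' @export
run_vm_experiment <- function(trials, methods = c("sr", "pi", "kashif"),
                              sr = sr_params(), pi = pi_params(),
                              kashif = kashif_params(window_s = 5)) {
  methods <- match.arg(methods, several.ok = TRUE)
  estimate_one <- function(method, trial) {
    switch(method,
      sr = sr_estimate(trial$abp, trial$cbfv, params = sr),
      pi = pi_estimate(trial$cbfv, params = pi),
      kashif = kashif_estimate(trial$abp, trial$cbfv, params = kashif)
    )
  }
  per_trial <- list()
  dropped <- list()
  for (method in methods) {
    for (i in seq_along(trials)) {
      trial <- trials[[i]]
      fs <- wave_fs(as_waveform(trial$abp))
      seg <- segment_trial(nrow(trial$abp) / fs, fs)
      res <- tryCatch(
        phase_means(estimate_one(method, trial), seg),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        dropped <- c(dropped, list(tibble(
          method = method, trial = i, reason = conditionMessage(res)
        )))
      } else {
        per_trial <- c(per_trial, list(tibble(method = method, trial = i, res)))
      }
    }
  }
  per_trial <- if (length(per_trial)) list_rbind(per_trial) else
    tibble(method = character(), trial = integer(),
           rest_mean = numeric(), vm_mean = numeric(), rest2_mean = numeric())
  dropped <- if (length(dropped)) list_rbind(dropped) else
    tibble(method = character(), trial = integer(), reason = character())

  tests <- map(methods, function(method) {
    d <- per_trial[per_trial$method == method, ]
    if (nrow(d) < 2) {
      return(tibble(method = method, n = nrow(d), t = NA_real_, df = NA_real_,
                    p = NA_real_, significant = NA,
                    note = "t-test skipped: fewer than 2 usable trials"))
    }
    tt <- tryCatch(paired_t_one_tailed(d$rest_mean, d$vm_mean), error = function(e) e)
    if (inherits(tt, "error")) {
      tibble(method = method, n = nrow(d), t = NA_real_, df = NA_real_,
             p = NA_real_, significant = NA, note = conditionMessage(tt))
    } else {
      tibble(method = method, tt, note = NA_character_)
    }
  })
  tests <- list_rbind(tests)

  summary <- per_trial |>
    group_by(method) |>
    summarise(
      n_trials = n(),
      rest = sprintf("%.1f ± %.1f", mean(rest_mean), sd(rest_mean)),
      vm = sprintf("%.1f ± %.1f", mean(vm_mean), sd(vm_mean)),
      .groups = "drop"
    ) |>
    left_join(select(tests, all_of(c("method", "p", "significant"))), by = "method") |>
    mutate(vm = ifelse(!is.na(significant) & significant, paste0(vm, "*"), vm))

  structure(
    list(trials = per_trial, tests = tests, summary = summary, dropped = dropped),
    class = "vm_experiment"
  )
}

#' @describeIn run_vm_experiment per-trial phase means as a tibble.
#' @param x a `vm_experiment`.
#' @param ... unused.
#' @export
tidy.vm_experiment <- function(x, ...) x$trials

#' @describeIn run_vm_experiment per-method t-test results as a tibble.
#' @export
glance.vm_experiment <- function(x, ...) x$tests

#' @export
print.vm_experiment <- function(x, ...) {
  cat("Valsalva detection experiment\n")
  cat(sprintf("  %d usable trial-method runs, %d dropped\n\n",
              nrow(x$trials), nrow(x$dropped)))
  cat("Estimated ICP, mean ± sd (mmHg); * marks p < 0.05 (one-tailed paired t)\n")
  df <- as.data.frame(x$summary[, c("method", "n_trials", "rest", "vm")])
  names(df) <- c("method", "trials", "resting state", "VM state")
  print(df, row.names = FALSE)
  bad <- x$tests[!is.na(x$tests$note), ]
  if (nrow(bad) > 0) {
    for (i in seq_len(nrow(bad))) cat(sprintf("note [%s]: %s\n", bad$method[i], bad$note[i]))
  }
  invisible(x)
}
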