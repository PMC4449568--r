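#' Zero-phase low-pass DC-trend extraction
#'
#' Extracts the slowly varying (DC) component of a waveform with a 4th-order
#' Butterworth low-pass applied forward and backward (zero phase, so the DC
#' trend is not delayed relative to the maneuver timing). The filter gain is
#' normalized to exactly 1 at DC, the signal mean is removed before
#' filtering and restored afterwards, and the ends are extended by odd
#' reflection before the two passes, so a constant input is reproduced
#' exactly and edge transients are negligible.
#'
#' @param x a [waveform()] (or data frame with `time_s`, `value`).
#' @param cutoff cutoff frequency, Hz.
#' @return A waveform on the same grid containing the DC trend.
#' @examples
#' w <- synth_abp(synth_config(duration = 30, noise_std = 0, seed = 1))
#' dc <- lowpass_dc(w)
#' c(mean(w$value), mean(dc$value))
#' @export
lowpass_dc <- function(x, cutoff = 0.2) {
  x <- as_waveform(x)
  fs <- wave_fs(x)
  if (cutoff <= 0) stop_input("`cutoff` must be positive.")
  if (fs <= 2 * cutoff) {
    stop_input(sprintf("Sampling rate %g Hz cannot support a %g Hz cutoff.", fs, cutoff))
  }
  bf <- signal::butter(4, 2 * cutoff / fs, type = "low")
  y <- zerophase_filter(bf$b, bf$a, x$value, pad = ceiling(3 * fs / cutoff))
  waveform(y, fs = fs, t0 = wave_t0(x), units = wave_units(x))
}

# Forward-backward IIR filtering with exact unit DC gain, mean removal and
# even (mirror) reflection end padding. Mirror padding preserves the local
# DC level of a pulsatile signal at the boundary (odd reflection about the
# first sample would shift the padded DC by twice the sample-to-trend
# distance, which is large when a recording starts at diastole). The
# recursions run through stats::filter (C implementations): FIR part by
# one-sided convolution, AR part by the recursive filter.
zerophase_filter <- function(b, a, x, pad, unit_dc = TRUE) {
  if (unit_dc) b <- b * sum(a) / sum(b) # force DC gain exactly 1 (low-pass only)
  n <- length(x)
  p <- min(n - 1, pad)
  xm <- mean(x)
  xd <- x - xm
  ext <- c(rev(xd[2:(p + 1)]), xd, rev(xd[(n - p):(n - 1)]))
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(p + 1):(p + n)] + xm
}

iir_filter <- function(b, a, x) {
  nb <- length(b)
  n <- length(x)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(n + nb - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive"))
  }
  v / a[1]
}

#' Detect cardiac beats in a pulsatile waveform
#'
#' Peak-finding on the derivative of the 0.5-10 Hz band-passed signal with a
#' 0.3 s refractory period; the beat onset is the pre-upstroke minimum of
#' the raw signal and the systolic index the in-beat maximum. Robust to
#' additive noise of a few percent of the pulse amplitude.
#'
#' @param x a pulsatile [waveform()] with at least 2 beats.
#' @return A beat table: tibble with `beat`, `onset_idx`, `onset_s`,
#'   `systolic_idx`. Feature columns are added by [beat_features()].
#' @export
detect_beats <- function(x) {
  x <- as_waveform(x)
  fs <- wave_fs(x)
  v <- x$value
  n <- length(v)
  amp <- diff(range(v))
  if (amp < 1e-8 * max(1, abs(mean(v)))) {
    stop_detection("No pulsatility detected: the signal is constant.")
  }
  bf <- signal::butter(2, c(0.5, min(10, 0.45 * fs)) / (fs / 2), type = "pass")
  xb <- zerophase_filter(bf$b, bf$a, v, pad = 3 * fs, unit_dc = FALSE)
  d <- c(0, diff(xb)) * fs
  thr <- 0.3 * quantile(d[d > 0], 0.95, names = FALSE)
  if (!is.finite(thr) || thr <= 0) stop_detection("No upstrokes found in the signal.")
  core <- 2:(n - 1)
  cand <- core[d[core] > thr & d[core] >= d[core - 1] & d[core] >= d[core + 1]]
  if (length(cand) < 2) stop_detection("Fewer than 2 beats detected.")
  # refractory: greedy accept, keeping the larger upstroke within 0.3 s
  refr <- round(0.3 * fs)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= refr) {
      keep <- c(keep, i)
    } else if (d[i] > d[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 2) stop_detection("Fewer than 2 beats detected.")
  # onset: minimum of the raw signal in the 0.25 s before the upstroke peak
  back <- round(0.25 * fs)
  onset <- vapply(keep, function(i) {
    lo <- max(1L, as.integer(i - back))
    lo + which.min(v[lo:i]) - 1L
  }, integer(1))
  onset <- unique(onset)
  sys_idx <- vapply(seq_along(onset), function(j) {
    hi <- if (j < length(onset)) onset[j + 1] - 1L else n
    onset[j] + which.max(v[onset[j]:hi]) - 1L
  }, integer(1))
  tibble(
    beat = seq_along(onset),
    onset_idx = onset,
    onset_s = x$time_s[onset],
    systolic_idx = sys_idx
  )
}

#' Per-beat waveform features
#'
#' Fills the beat table with the features the pulsatility index needs:
#' systolic = in-beat maximum, diastolic = value at the next beat onset
#' (end-diastolic convention), mean = sample mean over the beat. The last
#' (incomplete) beat has no following onset and is dropped.
#'
#' @param x the [waveform()] the beats were detected on.
#' @param beats a beat table from [detect_beats()].
#' @return The beat table with columns `systolic`, `diastolic`, `mean_value`
#'   added (units of `x`); one row fewer than `beats`.
#' @export
beat_features <- function(x, beats) {
  x <- as_waveform(x)
  v <- x$value
  nb <- nrow(beats)
  if (nb < 2) stop_input("Need at least 2 onsets to form one complete beat.")
  on <- beats$onset_idx
  out <- beats[-nb, ]
  nxt <- on[-1]
  out$systolic <- vapply(seq_len(nb - 1), function(j) max(v[on[j]:(nxt[j] - 1)]), numeric(1))
  out$diastolic <- v[nxt]
  out$mean_value <- vapply(seq_len(nb - 1), function(j) mean(v[on[j]:(nxt[j] - 1)]), numeric(1))
  out
}

#' Time shift between peripheral ABP and CBFv
#'
#' The peripheral (radial or finger) pressure pulse arrives later than the
#' middle-cerebral-artery flow pulse. The shift is estimated as the median
#' over matched beats of (ABP systolic-peak time minus CBFv systolic-peak
#' time); a positive value means ABP lags CBFv. [apply_time_shift()] then
#' advances the pressure trace, `P_MCA(t) = P_r(t + tau)`.
#'
#' @param abp,cbfv pulsatile [waveform()]s overlapping in time.
#' @return `estimate_time_shift()`: the shift tau in seconds.
#' @export
estimate_time_shift <- function(abp, cbfv) {
  abp <- as_waveform(abp)
  cbfv <- as_waveform(cbfv)
  ta <- systolic_peak_times(abp)
  tc <- systolic_peak_times(cbfv)
  half <- 0.5 * median(diff(tc))
  j <- vapply(ta, function(t) {
    k <- which.min(abs(tc - t))
    if (abs(tc[k] - t) <= half) k else NA_integer_
  }, integer(1))
  matched <- !is.na(j)
  if (mean(matched) < 0.5) {
    stop_detection("Beat matching failed for more than half of the ABP beats.")
  }
  median(ta[matched] - tc[j[matched]])
}

# Systolic peak times, re-localized on a lightly smoothed copy so that
# measurement noise on a flat systolic summit does not scatter the argmax.
systolic_peak_times <- function(x) {
  fs <- wave_fs(x)
  beats <- detect_beats(x)
  bf <- signal::butter(2, min(15, 0.45 * fs) / (fs / 2), type = "low")
  sm <- zerophase_filter(bf$b, bf$a, x$value, pad = round(fs))
  half <- round(0.12 * fs)
  n <- length(sm)
  idx <- vapply(beats$systolic_idx, function(i) {
    lo <- max(1L, as.integer(i - half)); hi <- min(n, as.integer(i + half))
    lo + which.max(sm[lo:hi]) - 1L
  }, integer(1))
  x$time_s[idx]
}

#' @rdname estimate_time_shift
#' @param x waveform to shift.
#' @param tau shift in seconds; the result samples `x` at `t + tau` on the
#'   original grid (edge values held).
#' @return `apply_time_shift()`: a waveform on the original grid.
#' @export
apply_time_shift <- function(x, tau) {
  x <- as_waveform(x)
  y <- approx(x$time_s, x$value, xout = x$time_s + tau, rule = 2)$y
  waveform(y, fs = wave_fs(x), t0 = wave_t0(x), units = wave_units(x))
}
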