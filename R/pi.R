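#' Pulsatility-index regression parameters
#'
#' The comparator estimator maps the Gosling pulsatility index of each CBFv
#' beat to ICP through a fixed linear regression `ICP = a * PI + b`. The
#' default coefficients place resting estimates inside the normal 5-15 mmHg
#' range.
#'
#' @param a slope, mmHg per PI unit.
#' @param b intercept, mmHg.
#' @return A list of class `pi_params`.
#' @export
pi_params <- function(a = 5.305, b = 4) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a)) stop_config("`a` must be a single finite number.")
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b)) stop_config("`b` must be a single finite number.")
  structure(list(a = a, b = b), class = "pi_params")
}

#' Gosling pulsatility index and its ICP regression
#'
#' `pi_index()` computes PI = (systolic - diastolic) / mean from per-beat
#' CBFv features (peak systolic, end-diastolic and mean velocity);
#' `pi_to_icp()` maps PI to ICP through the linear regression.
#'
#' @param systolic,diastolic,mean peak systolic, end-diastolic and mean
#'   velocity of a beat, cm/s (vectorised).
#' @return `pi_index()`: dimensionless PI; `pi_to_icp()`: ICP in mmHg.
#' @examples
#' pi_to_icp(pi_index(80, 40, 60))
#' @export
pi_index <- function(systolic, diastolic, mean) {
  if (any(mean <= 0)) stop_input("Mean velocity must be positive to form a pulsatility index.")
  (systolic - diastolic) / mean
}

#' @rdname pi_index
#' @param pi_val pulsatility index (dimensionless, non-negative).
#' @param params [pi_params()].
#' @export
pi_to_icp <- function(pi_val, params = pi_params()) {
  params$a * pi_val + params$b
}

#' Estimate ICP beat-by-beat from the pulsatility index
#'
#' Detects beats on the CBFv trace, extracts per-beat systolic /
#' end-diastolic / mean velocities, forms the pulsatility index and maps it
#' to ICP. One estimate per beat, timestamped at the beat onset; beats with
#' non-positive mean velocity are dropped.
#'
#' @param cbfv pulsatile CBFv [waveform()], cm/s.
#' @param params [pi_params()].
#' @return A per-beat ICP series (tibble with `time_s`, `icp_mmHg`, `pi`).
#' @export
pi_estimate <- function(cbfv, params = pi_params()) {
  cbfv <- as_waveform(cbfv)
  feats <- beat_features(cbfv, detect_beats(cbfv))
  ok <- feats$mean_value > 0
  if (!all(ok)) {
    inform(sprintf("Dropped %d beat(s) with non-positive mean CBFv.", sum(!ok)))
    feats <- feats[ok, ]
  }
  if (nrow(feats) == 0) stop_detection("No usable beats for the PI estimate.")
  pi_val <- pi_index(feats$systolic, feats$diastolic, feats$mean_value)
  new_icp_series(feats$onset_s, pi_to_icp(pi_val, params),
    method = "pi", granularity = "beat",
    extra = list(pi = pi_val)
  )
}
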