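#' Parameters of the two-element model estimator
#'
#' The comparator two-element estimator models the path from
#' middle-cerebral-artery pressure to ICP as one arterial resistance `R_a`
#' in parallel with one compliance `C_a`, identified beat by beat, with ICP
#' assumed constant over an estimation window.
#'
#' @param window_s length of the ICP-constancy window, seconds. The
#'   long default reflects the method's characterization; it can be reduced
#'   to roughly one beat.
#' @param alpha CBFv-to-CBF proportionality used when the flow input is a
#'   velocity in cm/s, (ml/s)/(cm/s).
#' @param dpdt_tol pair-matching tolerance on dP/dt, as a fraction of the
#'   within-beat dP/dt range.
#' @return A list of class `kashif_params`.
#' @export
kashif_params <- function(window_s = 60, alpha = 0.15, dpdt_tol = 0.05) {
  if (!is.numeric(window_s) || length(window_s) != 1 || !is.finite(window_s) || window_s <= 0) {
    stop_config("`window_s` must be a single positive number.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    stop_config("`alpha` must be a single positive number.")
  }
  if (!is.numeric(dpdt_tol) || length(dpdt_tol) != 1 || !is.finite(dpdt_tol) ||
      dpdt_tol <= 0 || dpdt_tol >= 1) {
    stop_config("`dpdt_tol` must be in (0, 1).")
  }
  structure(list(window_s = window_s, alpha = alpha, dpdt_tol = dpdt_tol),
            class = "kashif_params")
}

# Central-difference derivative on a uniform grid.
gradient_fs <- function(x, fs) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
}

#' Estimate ICP with the two-element (resistance-compliance) model
#'
#' Beat-by-beat identification of the two-element model
#' `Q = (P_MCA - P_ic)/R_a + C_a dP_MCA/dt`:
#' \enumerate{
#' \item the peripheral pressure is advanced by the estimated transit shift
#'   so it stands in for `P_MCA` ([estimate_time_shift()]);
#' \item `C_a` is identified on the systolic upstroke (top quartile of
#'   dP/dt within the beat), where flow is dominated by the compliance
#'   branch, by regressing Q on dP/dt with an intercept that absorbs the
#'   quasi-constant resistive flow during the brief upstroke;
#' \item the compliance-compensated flow `Qhat = Q - C_a dP/dt` isolates the
#'   resistive branch, and `R_a` is read off two in-beat time instants with
#'   near-equal dP/dt chosen to maximize their flow difference,
#'   `R_a = (P(t1) - P(t2)) / (Qhat(t1) - Qhat(t2))`;
#' \item the beat's ICP is `mean(P_MCA) - R_a * mean(Qhat)`;
#' \item per-beat estimates are averaged over consecutive windows of
#'   `window_s`, within which ICP is assumed constant.
#' }
#' Beats with no valid instant pair or a degenerate flow difference are
#' skipped (with a message); if all beats fail the estimation errors.
#'
#' @param abp peripheral ABP [waveform()], mmHg.
#' @param cbfv CBFv [waveform()] in cm/s, or a volumetric flow trace in
#'   ml/s with `cbfv_is_flow = TRUE`.
#' @param params [kashif_params()].
#' @param cbfv_is_flow if `TRUE`, skip the alpha velocity-to-flow scaling.
#' @param tau time shift in seconds applied to `abp` to obtain `P_MCA`;
#'   `NULL` (default) estimates it from matched systolic peaks. Pass 0 when
#'   the pressure input is already MCA-referenced.
#' @return A per-beat ICP series: `time_s` (beat onset), `icp_mmHg` (the
#'   window-mean estimate), plus the per-beat identification `c_a`
#'   (ml/mmHg), `r_a` (mmHg s/ml) and `icp_beat` (mmHg).
#' @export
kashif_estimate <- function(abp, cbfv, params = kashif_params(), cbfv_is_flow = FALSE,
                            tau = NULL) {
  abp <- as_waveform(abp)
  cbfv <- as_waveform(cbfv)
  fs <- check_same_grid(abp, cbfv, "ABP and CBFv")
  if (nrow(abp) / fs < params$window_s) {
    stop_input(sprintf("Need at least window_s = %g s of data.", params$window_s))
  }
  if (is.null(tau)) tau <- estimate_time_shift(abp, cbfv)
  p_mca <- if (tau == 0) abp else apply_time_shift(abp, tau)
  q <- if (cbfv_is_flow) cbfv$value else params$alpha * cbfv$value

  fits <- kashif_fit_beats(p_mca, waveform(q, fs = fs, t0 = wave_t0(p_mca), units = "ml/s"),
                           params = params)
  est <- fits[!is.na(fits$icp_beat), ]
  if (nrow(est) == 0) stop_detection("Every beat was degenerate; no two-element estimate possible.")
  if (nrow(est) < nrow(fits)) {
    inform(sprintf("Skipped %d degenerate beat(s).", nrow(fits) - nrow(est)))
  }
  win <- floor((est$time_s - est$time_s[1]) / params$window_s)
  icp_win <- stats::ave(est$icp_beat, win)
  new_icp_series(est$time_s, icp_win,
    method = "kashif", granularity = "beat",
    extra = list(c_a = est$c_a, r_a = est$r_a, icp_beat = est$icp_beat)
  )
}

#' Per-beat two-element identification
#'
#' The beat-level core of [kashif_estimate()], exposed for inspection: for
#' each complete beat it returns the compliance identified on the systolic
#' upstroke, the resistance from the matched-slope instant pair, and the
#' beat ICP. Beats where a step is degenerate carry `NA` in the affected
#' columns (a beat with no resistive-flow contrast, e.g. capacitor-only
#' data, still reports its compliance).
#'
#' @param p_mca MCA-referenced pressure [waveform()], mmHg.
#' @param q volumetric flow [waveform()] on the same grid, ml/s.
#' @param params [kashif_params()].
#' @return A tibble with one row per complete beat: `time_s` (onset),
#'   `c_a`, `r_a`, `icp_beat`.
#' @export
kashif_fit_beats <- function(p_mca, q, params = kashif_params()) {
  p_mca <- as_waveform(p_mca)
  q <- as_waveform(q)
  fs <- check_same_grid(p_mca, q, "pressure and flow")
  qv <- q$value
  dp <- gradient_fs(p_mca$value, fs)
  beats <- detect_beats(p_mca)
  on <- beats$onset_idx
  n_beats <- nrow(beats) - 1
  if (n_beats < 1) stop_detection("Need at least one complete beat.")

  fit_beat <- function(j) {
    ix <- on[j]:(on[j + 1] - 1)
    pb <- p_mca$value[ix]; qb <- qv[ix]; dpb <- dp[ix]
    out <- tibble(time_s = p_mca$time_s[on[j]],
                  c_a = NA_real_, r_a = NA_real_, icp_beat = NA_real_)
    up <- dpb >= quantile(dpb, 0.75, names = FALSE)
    if (sum(up) < 3 || sd(dpb[up]) == 0) return(out)
    out$c_a <- stats::.lm.fit(cbind(1, dpb[up]), qb[up])$coefficients[2]
    qhat <- qb - out$c_a * dpb
    rng <- diff(range(dpb))
    if (rng <= 0) return(out)
    dd <- abs(outer(dpb, dpb, "-"))
    dq <- abs(outer(qhat, qhat, "-"))
    dq[dd >= params$dpdt_tol * rng] <- -Inf
    diag(dq) <- -Inf
    best <- max(dq)
    if (!is.finite(best) || best < 1e-6) return(out)
    w <- which(dq == best, arr.ind = TRUE)[1, ]
    ra <- (pb[w[1]] - pb[w[2]]) / (qhat[w[1]] - qhat[w[2]])
    if (!is.finite(ra) || ra <= 0) return(out)
    out$r_a <- ra
    out$icp_beat <- mean(pb) - ra * mean(qhat)
    out
  }
  list_rbind(map(seq_len(n_beats), fit_beat))
}
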