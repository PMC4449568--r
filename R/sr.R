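#' Constants of the simplified-resistance (SR) ICP estimator
#'
#' The SR estimator reduces the intracranial circuit to two resistive
#' sub-circuits valid for DC (low-pass filtered) signals: an arterial
#' resistance `R_a` between systemic pressure and the capillary node, and a
#' CSF formation/outflow divider (`R_f`, `R_o`) between the capillary node
#' and the venous sinus pressure `P_vs`. `alpha` converts Doppler CBFv
#' (cm/s) to volumetric CBF (ml/s); `cutoff` is the low-pass corner defining
#' the DC trend.
#'
#' @param R_a intracranial arterial resistance, mmHg s/ml.
#' @param P_vs venous sinus pressure, mmHg.
#' @param R_f CSF formation resistance, mmHg s/ml.
#' @param R_o CSF outflow resistance, mmHg s/ml.
#' @param alpha CBFv-to-CBF proportionality, (ml/s)/(cm/s).
#' @param cutoff DC-trend low-pass cutoff, Hz.
#' @return A list of class `sr_params`.
#' @export
sr_params <- function(R_a = 6, P_vs = 6, R_f = 2380, R_o = 523,
                      alpha = 0.15, cutoff = 0.2) {
  p <- list(R_a = R_a, P_vs = P_vs, R_f = R_f, R_o = R_o,
            alpha = alpha, cutoff = cutoff)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_config(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  structure(p, class = "sr_params")
}

#' SR closed forms: capillary pressure, ICP, and CBFv-to-CBF conversion
#'
#' The three elementwise formulas composing the SR estimator:
#' `sr_capillary_pressure()` computes `P_c = P_a - R_a * Q_CBF` (pressure
#' drop across the arterial resistance), `sr_icp()` computes
#' `P_ic = P_vs + (P_c - P_vs) * R_o / (R_f + R_o)` (the CSF divider, a
#' linear interpolation between capillary and sinus pressure), and
#' `cbfv_to_cbf()` converts velocity to flow, `Q_CBF = alpha * CBFv`.
#'
#' @param pa_dc DC arterial pressure, mmHg.
#' @param q_cbf cerebral blood flow, ml/s.
#' @param params [sr_params()].
#' @return Numeric vector of the same length as the input.
#' @examples
#' sr_capillary_pressure(100, cbfv_to_cbf(77.8)) # 29.98 mmHg
#' sr_icp(30) # 10.32 mmHg
#' @export
sr_capillary_pressure <- function(pa_dc, q_cbf, params = sr_params()) {
  if (any(!is.finite(pa_dc)) || any(!is.finite(q_cbf))) {
    stop_input("`pa_dc` and `q_cbf` must be finite.")
  }
  pa_dc - params$R_a * q_cbf
}

#' @rdname sr_capillary_pressure
#' @param p_c capillary pressure, mmHg.
#' @export
sr_icp <- function(p_c, params = sr_params()) {
  if (any(!is.finite(p_c))) stop_input("`p_c` must be finite.")
  params$P_vs + (p_c - params$P_vs) * params$R_o / (params$R_f + params$R_o)
}

#' @rdname sr_capillary_pressure
#' @param cbfv cerebral blood flow velocity, cm/s.
#' @export
cbfv_to_cbf <- function(cbfv, params = sr_params()) {
  if (any(!is.finite(cbfv))) stop_input("`cbfv` must be finite.")
  if (any(cbfv < 0)) {
    warn("Negative CBFv values passed through to the flow conversion.")
  }
  params$alpha * cbfv
}

# ICP estimate series: tibble (time_s, icp_mmHg) tagged with the producing
# method and its granularity ("sample" or "beat").
new_icp_series <- function(time_s, icp, method, granularity, extra = NULL) {
  out <- tibble(time_s = time_s, icp_mmHg = icp)
  if (!is.null(extra)) out <- tibble(out, !!!extra)
  structure(out,
    method = method, granularity = granularity,
    class = c("nicp_icp", class(tibble()))
  )
}

#' @export
print.nicp_icp <- function(x, ...) {
  cat(sprintf(
    "<ICP estimate: %s method, per-%s, %d points>\n",
    attr(x, "method"), attr(x, "granularity"), nrow(x)
  ))
  NextMethod()
}

#' Estimate ICP with the simplified-resistance (SR) method
#'
#' The full SR pipeline: low-pass both inputs to their DC trends, convert
#' CBFv to CBF, compute the capillary pressure from the arterial resistance
#' drop, and read ICP off the CSF formation/outflow divider. The output is
#' per-sample on the input grid.
#'
#' @param abp ABP [waveform()], mmHg.
#' @param cbfv CBFv [waveform()], cm/s (a flow trace in ml/s can be passed
#'   by setting `cbfv_is_flow = TRUE`, skipping the alpha conversion).
#' @param params [sr_params()].
#' @param cbfv_is_flow if `TRUE`, `cbfv` already contains volumetric flow.
#' @return A per-sample ICP series (tibble with `time_s`, `icp_mmHg`).
#' @examples
#' trial <- synth_vm_trial(synth_config(duration = 45, vm_window = c(15, 30), seed = 1))
#' icp <- sr_estimate(trial$abp, trial$cbfv)
#' @export
sr_estimate <- function(abp, cbfv, params = sr_params(), cbfv_is_flow = FALSE) {
  abp <- as_waveform(abp)
  cbfv <- as_waveform(cbfv)
  check_same_grid(abp, cbfv, "ABP and CBFv")
  pa_dc <- lowpass_dc(abp, cutoff = params$cutoff)$value
  v_dc <- lowpass_dc(cbfv, cutoff = params$cutoff)$value
  q <- if (cbfv_is_flow) v_dc else cbfv_to_cbf(v_dc, params)
  icp <- sr_icp(sr_capillary_pressure(pa_dc, q, params), params)
  new_icp_series(abp$time_s, icp, method = "sr", granularity = "sample")
}
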