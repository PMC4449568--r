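# Independent oracles and fixture builders used across the suite.

# Brute-force resistive steady state by Gauss-Seidel nodal relaxation: each
# node is repeatedly set to the conductance-weighted average of its
# neighbours until the Kirchhoff residual certifies convergence. Shares no
# code path with the package's linear nodal solve.
oracle_steady_state <- function(pa, p = ursino_params(), pvs_offset = 0,
                                tol = 1e-11, max_iter = 400000L) {
  pcv <- p$Pcv + pvs_offset
  x <- stats::setNames(as.list(rep((pa + pcv) / 2, 5)),
                       c("P1", "Pc", "Pv", "Pvs", "Pic"))
  g <- lapply(p[c("R1", "R2", "Rpv", "Rdv", "Rve", "Rf", "Ro")], function(r) 1 / r)
  for (it in seq_len(max_iter)) {
    x$P1 <- (g$R1 * pa + g$R2 * x$Pc) / (g$R1 + g$R2)
    x$Pc <- (g$R2 * x$P1 + g$Rpv * x$Pv + g$Rf * x$Pic) / (g$R2 + g$Rpv + g$Rf)
    x$Pv <- (g$Rpv * x$Pc + g$Rdv * x$Pvs) / (g$Rpv + g$Rdv)
    x$Pvs <- (g$Rdv * x$Pv + g$Ro * x$Pic + g$Rve * pcv) / (g$Rdv + g$Ro + g$Rve)
    x$Pic <- (g$Rf * x$Pc + g$Ro * x$Pvs) / (g$Rf + g$Ro)
    if (it %% 500 == 0 &&
        max(abs(kcl_residuals(x, pa, p, pvs_offset))) < tol) {
      break
    }
  }
  stopifnot(max(abs(kcl_residuals(x, pa, p, pvs_offset))) < 1e-10)
  x
}

# Kirchhoff current residuals (ml/s) of a steady-state solution row.
kcl_residuals <- function(row, pa, p = ursino_params(), pvs_offset = 0) {
  pcv <- p$Pcv + pvs_offset
  c(
    (row$P1 - pa) / p$R1 + (row$P1 - row$Pc) / p$R2,
    (row$Pc - row$P1) / p$R2 + (row$Pc - row$Pv) / p$Rpv + (row$Pc - row$Pic) / p$Rf,
    (row$Pv - row$Pc) / p$Rpv + (row$Pv - row$Pvs) / p$Rdv,
    (row$Pvs - row$Pv) / p$Rdv + (row$Pvs - row$Pic) / p$Ro + (row$Pvs - pcv) / p$Rve,
    (row$Pic - row$Pc) / p$Rf + (row$Pic - row$Pvs) / p$Ro
  )
}

# Two-element model fixture: pulsatile MCA pressure plus the flow the model
# prescribes for known (C_a, R_a, ICP), with small sensor-scale noise.
two_element_data <- function(seed, duration = 60, fs = 100,
                             c_a = 0.15, r_a = 6, icp = 10,
                             flow_noise = 0.02) {
  p <- synth_abp(synth_config(
    duration = duration, fs = fs, heart_rate = 72, mean_abp = 95,
    pulse_pressure = 40, hr_jitter = 0.03, noise_std = 0, seed = seed
  ))
  n <- nrow(p)
  dp <- c(p$value[2] - p$value[1],
          (p$value[3:n] - p$value[1:(n - 2)]) / 2,
          p$value[n] - p$value[n - 1]) * fs
  q <- (p$value - icp) / r_a + c_a * dp
  if (flow_noise > 0) {
    q <- q + withr::with_seed(seed + 77L, rnorm(n, 0, flow_noise))
  }
  list(p_mca = p, q = waveform(q, fs = fs, units = "ml/s"))
}

# Per-seed median recovered parameters from the two-element estimator.
recover_two_element <- function(seed, window_s = 60, ...) {
  d <- two_element_data(seed, ...)
  est <- suppressMessages(kashif_estimate(
    d$p_mca, d$q,
    params = kashif_params(window_s = window_s),
    cbfv_is_flow = TRUE, tau = 0
  ))
  c(c_a = median(est$c_a), r_a = median(est$r_a), icp = median(est$icp_beat))
}

# Reference one-tailed paired t computed from the closed formula.
oracle_paired_t <- function(rest, vm) {
  d <- vm - rest
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = stats::pt(t, n - 1, lower.tail = FALSE))
}
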