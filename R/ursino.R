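#' Parameters of the lumped-parameter Ursino intracranial circuit
#'
#' The linear, time-invariant electrical analogue of intracranial hemo- and
#' hydro-dynamics: an arterial series path (R1, R2) from the systemic
#' arterial terminal to the capillary node, a venous path (Rpv, Rdv, Rve) to
#' the central venous terminal, a high-resistance CSF loop (formation Rf
#' from the capillary node into the intracranial space, outflow Ro to the
#' venous sinus), and compliances C1, C2, Cvi referenced to the intracranial
#' node, with Cic and Cve to ambient. Resistances are in mmHg s/ml,
#' compliances in ml/mmHg, Pcv in mmHg. Defaults are the standard
#' parameterization of the model.
#'
#' @param R1,R2 proximal/distal arterial resistance.
#' @param C1,C2 proximal/distal arterial compliance.
#' @param Rf,Ro CSF formation and outflow resistance.
#' @param Rpv,Rdv,Rve proximal venous, bridging vein, extracranial venous
#'   resistance.
#' @param Cvi,Cve proximal/extracranial venous compliance.
#' @param Pcv central venous pressure.
#' @param Cic intracranial compliance.
#' @return A list of class `ursino_params`.
#' @export
ursino_params <- function(R1 = 2.4, C1 = 0.03, R2 = 3.64, C2 = 0.06,
                          Rf = 2380, Ro = 526, Rpv = 0.88, Cvi = 0.46,
                          Rdv = 0.614, Rve = 0.16, Cve = 2.34,
                          Pcv = 4, Cic = 0.95) {
  p <- list(
    R1 = R1, C1 = C1, R2 = R2, C2 = C2, Rf = Rf, Ro = Ro, Rpv = Rpv,
    Cvi = Cvi, Rdv = Rdv, Rve = Rve, Cve = Cve, Pcv = Pcv, Cic = Cic
  )
  for (nm in setdiff(names(p), "Pcv")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_config(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  if (!is.numeric(p$Pcv) || length(p$Pcv) != 1 || !is.finite(p$Pcv)) {
    stop_config("`Pcv` must be a single finite number.")
  }
  structure(p, class = "ursino_params")
}

# Nodal conductance matrix G, source-injection matrix S (columns: Pa, Pcv)
# and compliance "mass" matrix M for node order (P1, Pc, Pv, Pvs, Pic).
# KCL at each node reads M dx/dt + G x = S u with u = (Pa, Pcv + offset).
ursino_matrices <- function(p) {
  g1 <- 1 / p$R1; g2 <- 1 / p$R2; gpv <- 1 / p$Rpv; gf <- 1 / p$Rf
  go <- 1 / p$Ro; gdv <- 1 / p$Rdv; gve <- 1 / p$Rve
  G <- rbind(
    c(g1 + g2,      -g2,            0,          0,              0),
    c(-g2,           g2 + gpv + gf, -gpv,       0,              -gf),
    c(0,            -gpv,            gpv + gdv, -gdv,           0),
    c(0,             0,             -gdv,        gdv + go + gve, -go),
    c(0,            -gf,             0,         -go,             gf + go)
  )
  S <- cbind(c(g1, 0, 0, 0, 0), c(0, 0, 0, gve, 0))
  M <- rbind(
    c(p$C1,  0,     0,      0,     -p$C1),
    c(0,     p$C2,  0,      0,     -p$C2),
    c(0,     0,     p$Cvi,  0,     -p$Cvi),
    c(0,     0,     0,      p$Cve,  0),
    c(-p$C1, -p$C2, -p$Cvi, 0,      p$C1 + p$C2 + p$Cvi + p$Cic)
  )
  list(G = G, S = S, M = M)
}

node_names <- c("P1", "Pc", "Pv", "Pvs", "Pic")

#' Resistive steady state of the Ursino circuit
#'
#' Open-circuits every compliance and solves the purely resistive network by
#' linear nodal analysis. This is the DC limit of the circuit and serves as
#' the analytic oracle for the dynamic simulator and for the SR reduction.
#'
#' @param pa arterial terminal pressure, mmHg (vectorised).
#' @param params [ursino_params()].
#' @param pvs_offset additive offset on the central venous source, mmHg.
#' @return A tibble with one row per `pa`: node pressures `P1`, `Pc`, `Pv`,
#'   `Pvs`, `Pic` (mmHg) and arterial inflow `Q_cbf` (ml/s).
#' @examples
#' ursino_steady_state(100)
#' @export
ursino_steady_state <- function(pa, params = ursino_params(), pvs_offset = 0) {
  if (!is.numeric(pa) || any(!is.finite(pa))) stop_input("`pa` must be finite.")
  m <- ursino_matrices(params)
  u <- rbind(pa, params$Pcv + pvs_offset + numeric(length(pa)))
  x <- tryCatch(solve(m$G, m$S %*% u),
    error = function(e) stop_numeric(sprintf("Singular resistive network: %s", conditionMessage(e)))
  )
  out <- as_tibble(setNames(as.data.frame(t(x)), node_names))
  out$pa <- pa
  out$Q_cbf <- (pa - out$P1) / params$R1
  out[, c("pa", node_names, "Q_cbf")]
}

#' Simulate the Ursino circuit driven by an ABP waveform
#'
#' Integrates the linear ODE system of the circuit (states are the five node
#' pressures carrying compliance charge) driven by the arterial pressure at
#' one terminal and the central venous pressure (plus an optional offset
#' trace, e.g. a Valsalva episode) at the other. Because the network is
#' linear and time-invariant, the integration uses the exact first-order-hold
#' discretization of the state equations: the matrix exponential of the
#' augmented system is computed once for the sampling interval, and the
#' state is propagated sample by sample with the input interpolated linearly
#' within each step. This is exact for piecewise-linear inputs regardless of
#' the three-orders-of-magnitude spread between CSF and vascular resistances
#' that makes the system stiff for explicit integrators.
#'
#' The initial state is the resistive steady state at the first ABP sample,
#' so reported traces carry no startup transient.
#'
#' @param abp ABP [waveform()] in mmHg, uniformly sampled, longer than 2 s.
#' @param params [ursino_params()].
#' @param pvs_offset optional numeric vector (or waveform) on the same grid
#'   as `abp`, added to the central venous source pressure.
#' @return A tibble of class `ursino_sim`: `time_s`, node pressures `P1`,
#'   `Pc`, `Pv`, `Pvs`, `Pic` (mmHg) and arterial inflow `Q_cbf` (ml/s).
#' @examples
#' abp <- synth_abp(synth_config(duration = 10, noise_std = 0, seed = 1))
#' sim <- ursino_simulate(abp)
#' range(sim$Pic)
#' @export
ursino_simulate <- function(abp, params = ursino_params(), pvs_offset = NULL) {
  abp <- as_waveform(abp)
  fs <- wave_fs(abp)
  n <- nrow(abp)
  if (n / fs <= 2) stop_input("`abp` must be longer than 2 s.")
  if (!is.null(pvs_offset)) {
    if (is.data.frame(pvs_offset)) {
      check_same_grid(abp, as_waveform(pvs_offset), "ABP and pvs_offset")
      pvs_offset <- pvs_offset$value
    }
    if (length(pvs_offset) != n || any(!is.finite(pvs_offset))) {
      stop_input("`pvs_offset` must be finite and on the same grid as `abp`.")
    }
  } else {
    pvs_offset <- numeric(n)
  }

  m <- ursino_matrices(params)
  A <- solve(m$M, -m$G)
  B <- solve(m$M, m$S)
  U <- rbind(abp$value, params$Pcv + pvs_offset)
  # Initial state: resistive steady state at the record-mean arterial
  # pressure and the initial venous offset. Initializing at the first raw
  # sample (typically diastolic, well below the DC trend) would excite the
  # very slow CSF mode (Cic against Rf/Ro, time constant of hundreds of
  # seconds) and superimpose a drift on the whole recording; the DC
  # operating point leaves stationary pulsatile inputs transient-free.
  x0 <- solve(m$G, m$S %*% c(mean(abp$value), U[2, 1]))
  X <- lti_foh_sim(A, B, x0, U, dt = 1 / fs)
  if (!all(is.finite(X))) {
    stop_numeric("Circuit integration produced non-finite node pressures; check parameter magnitudes.")
  }
  out <- as_tibble(setNames(as.data.frame(t(X)), node_names))
  out <- tibble(time_s = abp$time_s, !!!out)
  out$Q_cbf <- (abp$value - out$P1) / params$R1
  structure(out, fs = fs, class = c("ursino_sim", class(tibble())))
}

# Exact FOH discretization of x' = A x + B u via the Van Loan augmented
# exponential: exp([[A,B,0],[0,0,I],[0,0,0]] dt) yields the state transition
# matrix and the zero/first-order input convolution integrals.
lti_foh_sim <- function(A, B, x0, U, dt) {
  n <- nrow(A); m <- ncol(B); N <- ncol(U)
  Fa <- matrix(0, n + 2 * m, n + 2 * m)
  Fa[1:n, 1:n] <- A * dt
  Fa[1:n, n + (1:m)] <- B * dt
  Fa[n + (1:m), n + m + (1:m)] <- diag(m) * dt
  E <- as.matrix(Matrix::expm(Fa))
  Ad <- E[1:n, 1:n, drop = FALSE]
  G0 <- E[1:n, n + (1:m), drop = FALSE]
  G1 <- E[1:n, n + m + (1:m), drop = FALSE] / dt
  B0 <- G0 - G1
  X <- matrix(0, n, N)
  X[, 1] <- x0
  for (k in seq_len(N - 1)) {
    X[, k + 1] <- Ad %*% X[, k] + B0 %*% U[, k] + G1 %*% U[, k + 1]
  }
  X
}
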