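#' Physical constants of the quench-kinetics model
#'
#' @param K_I Iodide binding affinity of the halide-sensitive
#'   YFP(H148Q/I152L) chromophore (mM); default 1.9 mM.
#' @param RT_over_F Thermal voltage RT/F (mV); 25.7 mV near room temperature.
#' @param z_iodide Iodide valence (-1).
#' @param cell_volume_pL Effective well-mixed cell volume (pL).
#' @param faraday Faraday constant (C/mol).
#' @param iodide_out Extracellular iodide after addition (mM).
#' @param dt Sampling interval of the acquisition (s); images every 2 s.
#' @return List of class `kinetics_constants`.
#' @export
kinetics_constants <- function(K_I = 1.9, RT_over_F = 25.7, z_iodide = -1,
                               cell_volume_pL = 1, faraday = 96485,
                               iodide_out = 100, dt = 2) {
  stopifnot_scalar_pos(K_I, "K_I")
  stopifnot_scalar_pos(cell_volume_pL, "cell_volume_pL")
  structure(list(K_I = K_I, RT_over_F = RT_over_F, z_iodide = z_iodide,
                 cell_volume_pL = cell_volume_pL, faraday = faraday,
                 iodide_out = iodide_out, dt = dt),
            class = "kinetics_constants")
}

#' Parameters of the quench forward model
#'
#' The four free parameters of the steady-state protocol: CFTR conductance at
#' steady state (`G_CFTR`, nS); membrane potential immediately prior to iodide
#' addition (`V_M`, mV); and the amplitude (`G_trans`, nS) and decay time
#' constant (`tau_trans`, s) of a transient endogenous non-CFTR anion
#' conductance.
#'
#' @param G_CFTR CFTR steady-state conductance (nS), >= 0.
#' @param V_M Membrane potential (mV).
#' @param G_trans Transient endogenous conductance amplitude (nS), >= 0.
#' @param tau_trans Transient decay time constant (s), > 0.
#' @return List of class `quench_params`.
#' @export
quench_params <- function(G_CFTR, V_M, G_trans = 0, tau_trans = 5) {
  if (G_CFTR < 0) stop("`G_CFTR` must be >= 0")
  if (G_trans < 0) stop("`G_trans` must be >= 0")
  stopifnot_scalar_pos(tau_trans, "tau_trans")
  structure(list(G_CFTR = G_CFTR, V_M = V_M, G_trans = G_trans,
                 tau_trans = tau_trans), class = "quench_params")
}

#' Intracellular iodide from normalized fluorescence
#'
#' Inverts the chromophore binding equilibrium:
#' `[I-]_in = K_I * (1 - F) / F`, where `F` is YFP fluorescence normalized to
#' the pre-iodide frame. Zero at `F = 1`, strictly decreasing in `F`, and
#' equal to `K_I` at half-quench.
#'
#' @param f Normalized fluorescence values in (0, 1]. Values above 1 (noise)
#'   are clipped to 1 with a warning; values <= 0 are an error
#'   (fully quenched, concentration unidentifiable).
#' @param constants A [kinetics_constants()] object.
#' @return Intracellular iodide concentration(s), mM.
#' @export
#' @examples
#' iodide_inside(0.5)  # == K_I == 1.9 mM
iodide_inside <- function(f, constants = kinetics_constants()) {
  if (any(f <= 0)) {
    stop("quench-saturated: F(t) <= 0; iodide concentration unidentifiable")
  }
  if (any(f > 1)) {
    warning("clipping F(t) > 1 to 1")
    f <- pmin(f, 1)
  }
  constants$K_I * (1 - f) / f
}

#' Normalized fluorescence from intracellular iodide
#'
#' The forward direction of the binding equilibrium: the fraction of
#' anion-free chromophore `K_I / (K_I + [I-]_in)`. Exact inverse of
#' [iodide_inside()].
#'
#' @param iodide Intracellular iodide (mM), >= 0.
#' @param constants A [kinetics_constants()] object.
#' @return Normalized fluorescence in (0, 1].
#' @export
fluorescence_from_iodide <- function(iodide, constants = kinetics_constants()) {
  constants$K_I / (constants$K_I + iodide)
}

# Goldman-Hodgkin-Katz driving term for iodide (valence -1).
#
# Returns W = phi / phi' (mV), where phi(V) is the GHK current shape and phi'
# its voltage derivative, both evaluated at V with the instantaneous
# concentrations. Scaling the flux by G/phi' makes the small-signal slope
# conductance at V equal G, so the current is I = G * W (nS * mV = pA).
ghk_driving <- function(cin, cout, v_m, vt) {
  v <- if (abs(v_m) < 1e-4) 1e-4 else v_m  # avoid 0/0 at V = 0
  E <- exp(v / vt)
  N <- cin - cout * E
  D <- 1 - E
  phi <- v * N / D
  dphi <- N / D + v * E * (cin - cout) / (vt * D^2)
  phi / dphi
}

# Instantaneous d[I-]_in/dt (mM/s) of the forward model at time t after
# iodide addition; used by the ODE right-hand side and by dense-grid oracles.
model_rate <- function(t, cin, params, constants) {
  g <- params$G_CFTR + params$G_trans * exp(-t / params$tau_trans)
  w <- ghk_driving(cin, constants$iodide_out, params$V_M, constants$RT_over_F)
  g * w * 1000 / (constants$faraday * constants$cell_volume_pL)
}

#' Simulate a noise-free quench time course
#'
#' Integrates the single-compartment forward model from `[I-]_in = 0` at the
#' moment of iodide addition (t = 0). The total anion conductance decays from
#' `G_CFTR + G_trans` to `G_CFTR` with time constant `tau_trans`; the iodide
#' current follows a Goldman-Hodgkin-Katz flux law scaled so that the
#' small-signal slope conductance at the (constant) membrane potential `V_M`
#' equals the instantaneous total conductance. The observable is the fraction
#' of anion-free chromophore `F(t) = K_I / (K_I + [I-]_in(t))`, which starts
#' at 1 and is non-increasing while iodide flows inward; its long-time limit
#' is set by the electrochemical equilibrium
#' `[I-]_eq = iodide_out * exp(V_M / RT_over_F)`.
#'
#' @param params A [quench_params()] object.
#' @param constants A [kinetics_constants()] object.
#' @param duration Simulated time after iodide addition (s).
#' @param dt_sample Sampling interval (s); default the acquisition rate (2 s).
#' @return A `quench_trace` (see [normalize_trace()]) with fields `times`,
#'   `f_norm`, `iodide_in`, `t_iodide = 0`, plus the generating parameters.
#' @export
simulate_quench <- function(params, constants = kinetics_constants(),
                            duration = 40, dt_sample = constants$dt) {
  stopifnot_scalar_pos(duration, "duration")
  times <- seq(0, duration, by = dt_sample)
  rhs <- function(t, y, p) {
    list(model_rate(t, y[1], params, constants))
  }
  sol <- deSolve::ode(y = c(cin = 0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf(
      "integrator failed (G_CFTR=%g, V_M=%g, G_trans=%g, tau_trans=%g)",
      params$G_CFTR, params$V_M, params$G_trans, params$tau_trans))
  }
  cin <- pmax(sol[, "cin"], 0)
  structure(list(
    times = times, f_norm = fluorescence_from_iodide(cin, constants),
    iodide_in = cin, t_iodide = 0, t_activation = NA_real_,
    iodide_out = constants$iodide_out, f_mcherry_well = NA_real_,
    params = params
  ), class = "quench_trace")
}

#' Electrochemical equilibrium of intracellular iodide
#'
#' Closed-form long-time limit of the forward model with constant membrane
#' potential: the GHK flux vanishes when
#' `[I-]_in = iodide_out * exp(V_M / RT_over_F)`.
#'
#' @param v_m Membrane potential (mV).
#' @param constants A [kinetics_constants()] object.
#' @return Equilibrium intracellular iodide (mM).
#' @export
iodide_equilibrium <- function(v_m, constants = kinetics_constants()) {
  constants$iodide_out * exp(v_m / constants$RT_over_F)
}
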