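#' aEIF right-hand sides
#'
#' Derivatives of the adaptive exponential integrate-and-fire model,
#'
#' \deqn{C_m dV/dt = -g_L (V - E_L) + g_L \Delta_T \exp((V - V_{th})/\Delta_T) + I - w}
#' \deqn{\tau_w dw/dt = a (V - E_L) - w}
#'
#' with total input current \eqn{I = I_{bg} + I_{syn}}. The exponential term
#' is evaluated at \eqn{\min(V, V_{peak})} so that it cannot overflow; the
#' clip is transparent for any V below the spike-detection ceiling.
#'
#' @param V Membrane potential (mV).
#' @param w Adaptation current (pA).
#' @param params Neuron parameter row (fields `C_m_pF`, `g_L_nS`, `E_L_mV`,
#'   `V_th_mV`, `Delta_T_mV`, `tau_w_ms`, `a_nS`, `b_pA`, `V_r_mV`,
#'   `I_bg_pA`).
#' @param I_syn Synaptic current (pA), positive = depolarizing.
#' @param v_peak_mult Spike-ceiling multiplier on the slope factor.
#' @return List with `dV` (mV/ms) and `dw` (pA/ms).
#' @export
aeif_derivatives <- function(V, w, params, I_syn = 0, v_peak_mult = 5) {
  if (!all(is.finite(c(V, w, I_syn))))
    stop("non-finite neuron state or current")
  vpk <- v_peak(params, v_peak_mult)
  vexp <- pmin(V, vpk)
  I <- params$I_bg_pA + I_syn
  # nS * mV = pA; pA / pF = mV/ms
  dV <- (-params$g_L_nS * (V - params$E_L_mV) +
           params$g_L_nS * params$Delta_T_mV *
             exp((vexp - params$V_th_mV) / params$Delta_T_mV) +
           I - w) / params$C_m_pF
  dw <- (params$a_nS * (V - params$E_L_mV) - w) / params$tau_w_ms
  list(dV = dV, dw = dw)
}

#' Spike detection and reset
#'
#' If the integrated membrane potential has reached the spike-detection
#' ceiling \eqn{V_{peak}}, the neuron is deemed to have spiked and the reset
#' rule is applied: \eqn{V \to V_r}, \eqn{w \to w + b}. Otherwise the state
#' is returned unchanged. When the parameter row carries a floor
#' `w_min_pA` (used for cell types with a depolarizing spike afterpotential,
#' i.e. negative b, whose aftercurrent saturates), the adaptation current is
#' clamped at that floor.
#'
#' @inheritParams aeif_derivatives
#' @return List with `V`, `w`, and logical `spiked`.
#' @export
apply_reset <- function(V, w, params, v_peak_mult = 5) {
  w_min <- if (is.null(params$w_min_pA)) -Inf else params$w_min_pA
  if (V >= v_peak(params, v_peak_mult)) {
    list(V = params$V_r_mV, w = max(w + params$b_pA, w_min), spiked = TRUE)
  } else {
    list(V = V, w = max(w, w_min), spiked = FALSE)
  }
}

#' Voltage gate of the NMDA receptor
#'
#' Sigmoidal magnesium-block gate
#' \deqn{s(V) = 1.08 \, (1 + 0.19 \exp(-0.064 V))^{-1}}
#' for NMDA; AMPA and GABA_A conductances are ungated (gate value 1).
#'
#' @param V Postsynaptic membrane potential (mV); vectorized.
#' @param receptor `"AMPA"`, `"NMDA"` or `"GABAA"`.
#' @return Gate value(s) in (0, 1.08].
#' @export
nmda_gate <- function(V, receptor = "NMDA") {
  receptor <- match.arg(receptor, c("AMPA", "NMDA", "GABAA"))
  if (receptor != "NMDA") return(rep(1, length(V)))
  1.08 / (1 + 0.19 * exp(-0.064 * V))
}

#' Synaptic current from an explicit spike list
#'
#' Conductance-based double-exponential synapse: each presynaptic spike at
#' \eqn{t_{sp}} with short-term-plasticity efficacy \eqn{a_n} contributes,
#' for \eqn{t > t_{sp} + \tau_D},
#' \deqn{g^{max} s(V) \, a_n (e^{-(t - t_{sp} - \tau_D)/\tau_{off}} -
#'       e^{-(t - t_{sp} - \tau_D)/\tau_{on}}) (V - E_{rev}).}
#' The sign convention follows the conductance form: the returned value is
#' positive for an outward (hyperpolarizing) current, so the membrane
#' equation receives it negated.
#'
#' @param spec List with `g_max_nS`, `E_rev_mV`, `tau_on_ms`, `tau_off_ms`,
#'   `tau_D_ms`, `receptor`.
#' @param spike_times Presynaptic spike times (ms), ascending.
#' @param efficacies Per-spike STP efficacies, same length.
#' @param t Evaluation time (ms).
#' @param V_post Postsynaptic potential (mV).
#' @return Current in pA (outward positive).
#' @export
synaptic_current <- function(spec, spike_times, efficacies, t, V_post) {
  if (spec$tau_on_ms >= spec$tau_off_ms)
    stop("synapse misconfigured: tau_on must be below tau_off")
  stopifnot(length(spike_times) == length(efficacies))
  if (length(spike_times) == 0) return(0)
  el <- t - spike_times - spec$tau_D_ms
  active <- el > 0
  if (!any(active)) return(0)
  el <- el[active]
  kern <- exp(-el / spec$tau_off_ms) - exp(-el / spec$tau_on_ms)
  gate <- nmda_gate(V_post, spec$receptor)
  spec$g_max_nS * gate * sum(efficacies[active] * kern) *
    (V_post - spec$E_rev_mV)
}

#' Time of peak of the double-exponential kernel
#'
#' Closed-form maximizer of
#' \eqn{e^{-t/\tau_{off}} - e^{-t/\tau_{on}}}, measured from kernel onset:
#' \eqn{t^* = \tau_{on}\tau_{off}/(\tau_{off}-\tau_{on}) \cdot
#'       \ln(\tau_{off}/\tau_{on})}.
#'
#' @param tau_on,tau_off Kernel time constants (ms), `tau_off > tau_on`.
#' @return Time of the conductance peak after onset (ms).
#' @export
kernel_peak_time <- function(tau_on, tau_off) {
  tau_on * tau_off / (tau_off - tau_on) * log(tau_off / tau_on)
}

#' Initialize a short-term-plasticity state
#'
#' Tsodyks-Markram dynamics track a utilization variable u (facilitation)
#' and a resource variable R (depression). The default initialization is
#' \eqn{u_1 = U, R_1 = 1}, so the first spike of a train has efficacy
#' \eqn{a_1 = U}. The alternative convention \eqn{R_1 = 1 - U} (first
#' efficacy \eqn{U(1-U)}) is available behind `r1_complement`.
#'
#' @param params List with `U`, `tau_facil_ms`, `tau_rec_ms`.
#' @param r1_complement Use the \eqn{R_1 = 1 - U} convention.
#' @return List with `u`, `R`, `t_last` (-Inf before any spike).
#' @export
stp_init <- function(params, r1_complement = FALSE) {
  stopifnot(params$U > 0, params$U < 1,
            params$tau_facil_ms > 0, params$tau_rec_ms > 0)
  list(u = params$U, R = if (r1_complement) 1 - params$U else 1,
       t_last = -Inf)
}

#' Advance a short-term-plasticity state by one presynaptic spike
#'
#' With inter-spike interval \eqn{\Delta t}, utilization is facilitated and
#' resources recover:
#' \deqn{u_{n+1} = u_n e^{-\Delta t/\tau_{facil}} +
#'       U (1 - u_n e^{-\Delta t/\tau_{facil}})}
#' \deqn{R_{n+1} = R_n (1 - u_{n+1}) e^{-\Delta t/\tau_{rec}} +
#'       1 - e^{-\Delta t/\tau_{rec}}}
#' and the spike's efficacy is \eqn{a_{n+1} = u_{n+1} R_{n+1}} (the R update
#' uses the freshly facilitated u). The first spike of a train keeps the
#' initialization values, so its efficacy is \eqn{u_1 R_1}.
#'
#' @param state List with `u`, `R`, `t_last` (see [stp_init()]).
#' @param params List with `U`, `tau_facil_ms`, `tau_rec_ms`.
#' @param t_spike Time of the presynaptic spike (ms); must exceed `t_last`.
#' @return List with the updated `state` and the spike's `efficacy`.
#' @export
stp_advance <- function(state, params, t_spike) {
  if (t_spike <= state$t_last)
    stop("presynaptic spikes must be strictly increasing in time")
  if (is.infinite(state$t_last)) {
    state$t_last <- t_spike
    return(list(state = state, efficacy = state$u * state$R))
  }
  dt <- t_spike - state$t_last
  ef <- exp(-dt / params$tau_facil_ms)
  er <- exp(-dt / params$tau_rec_ms)
  u_new <- state$u * ef + params$U * (1 - state$u * ef)
  R_new <- state$R * (1 - u_new) * er + 1 - er
  state$u <- u_new
  state$R <- R_new
  state$t_last <- t_spike
  list(state = state, efficacy = u_new * R_new)
}

#' Efficacies of a whole presynaptic spike train
#'
#' Convenience wrapper running [stp_advance()] over an ascending spike-time
#' vector.
#'
#' @inheritParams stp_advance
#' @param times Ascending spike times (ms).
#' @param r1_complement Passed to [stp_init()].
#' @return Numeric vector of per-spike efficacies \eqn{a_n = u_n R_n}.
#' @export
stp_train <- function(params, times, r1_complement = FALSE) {
  st <- stp_init(params, r1_complement)
  vapply(times, function(t) {
    res <- stp_advance(st, params, t)
    st <<- res$state
    res$efficacy
  }, numeric(1))
}
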