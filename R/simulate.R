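#' Simulation settings
#'
#' @param duration Total simulated time (ms). Must cover the last stimulus
#'   offset plus the 160 ms readout window.
#' @param dt Integration step (ms), default 0.05.
#' @param record Neuron id set to keep in the returned raster, or `NULL`
#'   for all neurons.
#' @return List of class `pfc_sim_config`.
#' @export
simulation_config <- function(duration, dt = 0.05, record = NULL) {
  stopifnot(dt > 0, duration > 0)
  structure(list(duration = duration, dt = dt, record = record),
            class = "pfc_sim_config")
}

#' Run the network simulation
#'
#' Advances the whole network with explicit Euler steps at `cfg$dt`. Per
#' step, delayed synaptic events (with short-term-plasticity efficacy
#' frozen at emission time) and external stimulus spikes are delivered to
#' the postsynaptic receptor conductances, synaptic and background
#' currents are computed, all neurons are updated, and V_peak crossings
#' are reset and their spikes enqueued at t + tau_D per synapse. The
#' result is bitwise deterministic given (network, stimulus, config).
#'
#' @param net A `pfc_network`.
#' @param stim Data frame with `neuron`, `time_ms` (external stimulus
#'   spikes onto layer 2/3 PCs), or `NULL`.
#' @param cfg A [simulation_config()].
#' @param stim_weight_nS Conductance of the dedicated stimulation synapse
#'   (AMPA kinetics, no STP). Default from the network's configuration.
#' @return A `pfc_raster`: list with `events` (data frame `id`, `time_ms`,
#'   time-sorted), `duration`, `dt`, and the final `V`/`w` states indexed
#'   like `net$neurons`.
#' @export
run_simulation <- function(net, stim, cfg,
                           stim_weight_nS = net$cfg_options$stim_weight_nS) {
  stopifnot(inherits(net, "pfc_network"), inherits(cfg, "pfc_sim_config"),
            nrow(net$neurons) > 0)
  nn <- net$neurons
  idx <- match(seq_len(max(nn$id)), nn$id)       # id -> row, NA if ablated

  syn <- net$synapses
  syn_list <- list(
    pre0 = idx[syn$pre] - 1L, post0 = idx[syn$post] - 1L,
    delay_steps = as.integer(round(syn$delay_ms / cfg$dt)),
    g_ampa_nS = syn$g_ampa_nS, g_nmda_nS = syn$g_nmda_nS,
    g_gabaa_nS = syn$g_gabaa_nS, U = syn$U,
    tau_facil_ms = syn$tau_facil_ms, tau_rec_ms = syn$tau_rec_ms)

  rec <- c("AMPA", "NMDA", "GABAA")
  # receptor kinetics in fixed engine order
  rt <- receptor_table(net)
  rt <- rt[match(rec, rt$receptor), ]

  if (is.null(stim) || nrow(stim) == 0) {
    stim <- data.frame(neuron = integer(), time_ms = numeric())
  } else {
    keep <- stim$neuron %in% nn$id
    stim <- stim[keep, ]
  }

  n_steps <- as.integer(ceiling(cfg$duration / cfg$dt))
  res <- run_network_cpp(
    neurons = as.list(nn[c("C_m_pF", "g_L_nS", "E_L_mV", "V_th_mV",
                           "Delta_T_mV", "tau_w_ms", "a_nS", "b_pA",
                           "V_r_mV", "V_peak_mV", "I_bg_pA",
                           "w_min_pA")]),
    synapses = syn_list,
    receptors = as.list(rt[c("tau_on_ms", "tau_off_ms", "E_rev_mV")]),
    stim_neuron = idx[stim$neuron] - 1L,
    stim_time = stim$time_ms,
    stim_weight = stim_weight_nS,
    dt = cfg$dt, n_steps = n_steps,
    stp_r1_complement = isTRUE(net$cfg_options$stp_r1_complement == 1))

  events <- data.frame(id = nn$id[res$id], time_ms = res$time_ms)
  if (!is.null(cfg$record))
    events <- events[events$id %in% cfg$record, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, duration = cfg$duration, dt = cfg$dt,
                 V = res$V, w = res$w),
            class = "pfc_raster")
}

# receptor kinetics attached to the network's parent configuration; falls
# back to the packaged defaults when the network predates the accessor
receptor_table <- function(net) {
  if (!is.null(net$receptors)) return(net$receptors)
  utils::read.delim(system.file("extdata", "receptors.tsv",
                                package = "pfcmaint"),
                    stringsAsFactors = FALSE)
}

#' Population firing rate in time bins
#'
#' @param raster A `pfc_raster` or its `events` data frame.
#' @param ids Neuron ids defining the population.
#' @param bin_ms Bin width (default 50 ms).
#' @param duration Total duration (taken from the raster when available).
#' @return Data frame with `t0`, `t1` and `rate_hz` (mean per-neuron rate).
#' @export
population_rate <- function(raster, ids, bin_ms = 50, duration = NULL) {
  ev <- if (inherits(raster, "pfc_raster")) raster$events else raster
  if (is.null(duration)) duration <- raster$duration
  ev <- ev[ev$id %in% ids, ]
  breaks <- seq(0, duration, by = bin_ms)
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)
  counts <- hist(ev$time_ms, breaks = breaks, plot = FALSE)$counts
  widths <- diff(breaks)
  data.frame(t0 = breaks[-length(breaks)], t1 = breaks[-1],
             rate_hz = counts / length(ids) / (widths / 1000))
}

#' @export
print.pfc_raster <- function(x, ...) {
  cat(sprintf("pfc_raster: %d spikes over %.0f ms (dt = %g ms)\n",
              nrow(x$events), x$duration, x$dt))
  invisible(x)
}
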