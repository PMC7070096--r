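# Small hand-built fixtures and independent reference implementations used
# as oracles across the test files. The reference network integrator uses
# the explicit spike-sum form of the synaptic conductance (a different
# algorithm than the engine's auxiliary-state method).

toy_params <- function(...) {
  p <- list(C_m_pF = 100, g_L_nS = 10, E_L_mV = -70, V_th_mV = -50,
            Delta_T_mV = 2, tau_w_ms = 100, a_nS = 0, b_pA = 0,
            V_r_mV = -60, I_bg_pA = 0, w_min_pA = -Inf)
  mods <- list(...)
  p[names(mods)] <- mods
  p$V_peak_mV <- p$V_th_mV + 5 * p$Delta_T_mV
  p
}

default_receptors <- function() {
  data.frame(receptor = c("AMPA", "NMDA", "GABAA"),
             tau_on_ms = c(0.5, 2, 0.5), tau_off_ms = c(2, 100, 8),
             E_rev_mV = c(0, 0, -75))
}

# Assemble a pfc_network by hand from parameter lists and a synapse table.
toy_net <- function(params_list, synapses = NULL, stim_weight = 1) {
  neurons <- do.call(rbind, lapply(seq_along(params_list), function(i) {
    p <- params_list[[i]]
    data.frame(id = i, column = 1L, type = "PC", layer = "L23",
               C_m_pF = p$C_m_pF, g_L_nS = p$g_L_nS, E_L_mV = p$E_L_mV,
               V_th_mV = p$V_th_mV, Delta_T_mV = p$Delta_T_mV,
               tau_w_ms = p$tau_w_ms, a_nS = p$a_nS, b_pA = p$b_pA,
               V_r_mV = p$V_r_mV, I_bg_pA = p$I_bg_pA,
               V_peak_mV = p$V_peak_mV, w_min_pA = p$w_min_pA)
  }))
  if (is.null(synapses))
    synapses <- data.frame(pre = integer(), post = integer(),
                           g_ampa_nS = numeric(), g_nmda_nS = numeric(),
                           g_gabaa_nS = numeric(), delay_ms = numeric(),
                           U = numeric(), tau_facil_ms = numeric(),
                           tau_rec_ms = numeric())
  structure(list(neurons = neurons, synapses = synapses, seed = 0L,
                 n_columns = 1L,
                 cfg_options = list(stim_weight_nS = stim_weight,
                                    stp_r1_complement = 0),
                 receptors = default_receptors()),
            class = "pfc_network")
}

toy_synapse <- function(pre, post, gA = 0, gN = 0, gG = 0, delay = 1,
                        U = 0.25, tf = 500, tr = 200) {
  data.frame(pre = pre, post = post, g_ampa_nS = gA, g_nmda_nS = gN,
             g_gabaa_nS = gG, delay_ms = delay, U = U,
             tau_facil_ms = tf, tau_rec_ms = tr)
}

# Independent reference integrator: explicit Euler with the same
# deliver -> currents -> integrate -> reset ordering, but synaptic
# conductances evaluated by the explicit double-exponential spike sum.
ref_sim <- function(net, stim, dt, duration) {
  nn <- net$neurons
  N <- nrow(nn)
  syn <- net$synapses
  rec <- default_receptors()
  n_steps <- ceiling(duration / dt)
  V <- nn$E_L_mV
  w <- rep(0, N)
  # arrivals: list of (time, post, receptor, weight)
  arr_t <- numeric(0); arr_post <- integer(0); arr_rec <- integer(0)
  arr_w <- numeric(0)
  add_arrival <- function(time, post, r, wt) {
    arr_t <<- c(arr_t, time); arr_post <<- c(arr_post, post)
    arr_rec <<- c(arr_rec, r); arr_w <<- c(arr_w, wt)
  }
  if (!is.null(stim) && nrow(stim) > 0)
    for (k in seq_len(nrow(stim)))
      add_arrival(round(stim$time_ms[k] / dt) * dt, stim$neuron[k], 1L,
                  net$cfg_options$stim_weight_nS)
  stp <- if (nrow(syn) > 0)
    lapply(seq_len(nrow(syn)), function(k)
      stp_init(list(U = syn$U[k], tau_facil_ms = syn$tau_facil_ms[k],
                    tau_rec_ms = syn$tau_rec_ms[k])))
  spikes_id <- integer(0); spikes_t <- numeric(0)
  for (s in seq_len(n_steps) - 1L) {
    t <- s * dt
    for (i in seq_len(N)) {
      gsum <- c(0, 0, 0)
      sel <- arr_post == i & arr_t <= t
      if (any(sel)) for (r in 1:3) {
        rs <- sel & arr_rec == r
        if (any(rs)) {
          el <- t - arr_t[rs]
          gsum[r] <- sum(arr_w[rs] * (exp(-el / rec$tau_off_ms[r]) -
                                        exp(-el / rec$tau_on_ms[r])))
        }
      }
      sN <- 1.08 / (1 + 0.19 * exp(-0.064 * V[i]))
      Isyn <- gsum[1] * (rec$E_rev_mV[1] - V[i]) +
        sN * gsum[2] * (rec$E_rev_mV[2] - V[i]) +
        gsum[3] * (rec$E_rev_mV[3] - V[i])
      d <- aeif_derivatives(V[i], w[i], as.list(nn[i, ]), Isyn)
      Vn <- V[i] + dt * d$dV
      wn <- max(w[i] + dt * d$dw, nn$w_min_pA[i])
      if (Vn >= nn$V_peak_mV[i]) {
        ts <- t + dt
        V[i] <- nn$V_r_mV[i]; w[i] <- max(wn + nn$b_pA[i], nn$w_min_pA[i])
        spikes_id <- c(spikes_id, i); spikes_t <- c(spikes_t, ts)
        if (nrow(syn) > 0) for (k in which(syn$pre == i)) {
          res <- stp_advance(stp[[k]],
                             list(U = syn$U[k],
                                  tau_facil_ms = syn$tau_facil_ms[k],
                                  tau_rec_ms = syn$tau_rec_ms[k]), ts)
          stp[[k]] <- res$state
          if (syn$g_ampa_nS[k] > 0)
            add_arrival(ts + syn$delay_ms[k], syn$post[k], 1L,
                        res$efficacy * syn$g_ampa_nS[k])
          if (syn$g_nmda_nS[k] > 0)
            add_arrival(ts + syn$delay_ms[k], syn$post[k], 2L,
                        res$efficacy * syn$g_nmda_nS[k])
          if (syn$g_gabaa_nS[k] > 0)
            add_arrival(ts + syn$delay_ms[k], syn$post[k], 3L,
                        res$efficacy * syn$g_gabaa_nS[k])
        }
      } else {
        V[i] <- Vn; w[i] <- wn
      }
    }
  }
  list(events = data.frame(id = spikes_id, time_ms = spikes_t),
       V = V, w = w)
}

# quick small config for builder tests: scaled-down column
mini_config <- function(n = 200) {
  cfg <- pfc_config()
  cfg$options$n_per_column <- n
  cfg
}
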