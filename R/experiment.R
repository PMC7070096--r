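#' Describe an experiment condition
#'
#' Protocol "a" is one column, one stimulation; "b" one column, five
#' stimulations; "c" two to four columns, five stimulations (the same
#' pattern is delivered to every column's layer 2/3 PCs).
#'
#' @param protocol `"a"`, `"b"` or `"c"`.
#' @param n_columns Number of columns (protocol "c" needs at least 2).
#' @param ablation An [ablation_spec()] (or target strings); empty = intact.
#' @param repeats Independent repeats; each redraws the connectivity
#'   realization (default 15).
#' @param base_seed Base connectivity seed; repeat r uses `base_seed + r`,
#'   so conditions sharing `base_seed` are seed-paired.
#' @return List of class `pfc_protocol`.
#' @export
experiment_protocol <- function(protocol = c("a", "b", "c"), n_columns = 1L,
                                ablation = ablation_spec(), repeats = 15L,
                                base_seed = 20200313L) {
  protocol <- match.arg(protocol)
  if (is.character(ablation)) ablation <- ablation_spec(ablation)
  if (protocol == "c" && n_columns < 2)
    stop("protocol c requires at least 2 columns")
  if (protocol != "c" && n_columns != 1)
    stop("protocols a and b are single-column")
  stopifnot(repeats >= 1)
  structure(list(protocol = protocol, n_columns = as.integer(n_columns),
                 ablation = ablation, repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed)),
            class = "pfc_protocol")
}

protocol_duration <- function(protocol) {
  onsets <- stim_onsets(protocol)
  max(onsets) + 20 - 1 + 160     # last stimulus offset + 160 ms readout
}

#' Calibrate the stimulation-synapse conductance
#'
#' Sweeps a logarithmic weight grid on the intact network and returns the
#' smallest weight for which at least `target` of the stimulated layer 2/3
#' PCs spike at least once during a single 20 ms stimulation window. The
#' calibrated weight is then frozen across all ablation conditions of a
#' study.
#'
#' @param net Intact `pfc_network`.
#' @param pattern Binary stimulus matrix.
#' @param target Required fraction of stimulated PCs spiking (default 0.95).
#' @param grid Candidate weights in nS, ascending.
#' @param dt Integration step (ms).
#' @return The calibrated weight (nS).
#' @export
calibrate_stimulus_weight <- function(net, pattern, target = 0.95,
                                      grid = 0.25 * 2^(0:8), dt = 0.05) {
  map <- pc_index_map(net, column = 1L)
  stim <- encode_to_spikes(pattern, map, onsets = 51)
  targets <- unique(stim$neuron)
  cfg <- simulation_config(duration = 75, dt = dt)
  for (wg in sort(grid)) {
    ras <- run_simulation(net, stim, cfg, stim_weight_nS = wg)
    ev <- ras$events
    hit <- unique(ev$id[ev$time_ms > 51 & ev$time_ms <= 71])
    if (length(intersect(hit, targets)) / length(targets) >= target)
      return(wg)
  }
  stop("stimulation-weight grid exhausted without reaching target reliability")
}

#' Run one experiment condition
#'
#' For each repeat r: build the network with seed `base_seed + r`, apply
#' the ablation, encode the stimulus pattern for the protocol's windows
#' (replicated to every column), simulate, decode each readout window per
#' column, and score accuracy against that column's input. Per-column
#' accuracies are averaged within a trial.
#'
#' @param proto An [experiment_protocol()].
#' @param cfg A [pfc_config()].
#' @param pattern Binary stimulus matrix (default [make_triangle_pattern()]).
#' @param stim_weight_nS Stimulation-synapse weight; default from config
#'   (see [calibrate_stimulus_weight()]).
#' @param label Condition label carried into the report.
#' @return List of class `pfc_report`: accuracy matrix (`repeats` rows,
#'   one column per readout window), aggregate statistics, seeds, config
#'   snapshot, and the last trial's raster for inspection.
#' @export
run_condition <- function(proto, cfg, pattern = make_triangle_pattern(),
                          stim_weight_nS = cfg$options$stim_weight_nS,
                          label = NULL) {
  windows <- readout_windows(proto$protocol)
  onsets <- stim_onsets(proto$protocol)
  sim_cfg <- simulation_config(duration = protocol_duration(proto$protocol),
                               dt = cfg$options$dt_ms)
  acc <- matrix(NA_real_, proto$repeats, length(windows))
  post_rate_hz <- numeric(proto$repeats)
  seeds <- proto$base_seed + seq_len(proto$repeats)
  last_raster <- NULL
  for (r in seq_len(proto$repeats)) {
    net <- if (proto$n_columns == 1) build_column(cfg, seeds[r])
           else build_multicolumn(cfg, proto$n_columns, seeds[r])
    net <- apply_ablation(net, proto$ablation)
    maps <- lapply(seq_len(proto$n_columns), function(ci)
      pc_index_map(net, column = ci))
    stim <- do.call(rbind, lapply(maps, function(m)
      encode_to_spikes(pattern, m, onsets)))
    ras <- run_simulation(net, stim, sim_cfg, stim_weight_nS = stim_weight_nS)
    for (wi in seq_along(windows)) {
      col_acc <- vapply(maps, function(m)
        accuracy(pattern, decode_window(ras, m, windows[[wi]])), numeric(1))
      acc[r, wi] <- mean(col_acc)
    }
    # L2/3 PC population rate of column 1 over the final 100 ms: the
    # post-stimulus persistent/epileptiform firing measure
    ev <- ras$events
    post_rate_hz[r] <- sum(ev$id %in% maps[[1]] &
                             ev$time_ms > ras$duration - 100) / 900 / 0.1
    last_raster <- ras
  }
  structure(list(label = label, protocol = proto, accuracy = acc,
                 aggregate = aggregate_trials(acc), seeds = seeds,
                 windows = windows, pattern = pattern,
                 stim_weight_nS = stim_weight_nS,
                 post_rate_hz = post_rate_hz,
                 last_raster = last_raster),
            class = "pfc_report")
}

#' Run a named study (a set of seed-paired conditions)
#'
#' All conditions share the same base seed (so repeat r uses the same
#' connectivity realization across conditions) and the same stimulation
#' weight, calibrated once on the intact network.
#'
#' @param conditions Named list of [experiment_protocol()]s.
#' @param cfg A [pfc_config()].
#' @param pattern Binary stimulus matrix.
#' @param calibrate Calibrate the stimulation weight on an intact column
#'   before running (default: use the configured weight).
#' @return Named list of `pfc_report`s with an `accuracy_table` attribute
#'   (condition x window means and SEMs).
#' @export
run_study <- function(conditions, cfg, pattern = make_triangle_pattern(),
                      calibrate = FALSE) {
  stopifnot(length(names(conditions)) == length(conditions))
  wg <- cfg$options$stim_weight_nS
  if (calibrate) {
    intact <- build_column(cfg, conditions[[1]]$base_seed)
    wg <- calibrate_stimulus_weight(intact, pattern, dt = cfg$options$dt_ms)
  }
  reports <- lapply(names(conditions), function(nm) {
    run_condition(conditions[[nm]], cfg, pattern,
                  stim_weight_nS = wg, label = nm)
  })
  names(reports) <- names(conditions)
  tab <- do.call(rbind, lapply(reports, function(rep) {
    ag <- rep$aggregate
    data.frame(condition = rep$label,
               window = seq_along(ag$per_window_mean),
               mean = ag$per_window_mean, sem = ag$per_window_sem,
               n = ag$n)
  }))
  rownames(tab) <- NULL
  attr(reports, "accuracy_table") <- tab
  reports
}

#' Condition sets of the four ablation studies
#'
#' * `ll_single`: intact vs chandelier-cell ablation by layer (protocol a).
#' * `classes_single`: intact vs each interneuron class and the combined
#'   cross-layer + long-range ablation (protocol a).
#' * `l23_multi`: intact vs layer 2/3 class ablations under five
#'   stimulations (protocol b).
#' * `multicolumn`: layer 2/3 chandelier-cell ablation in 1, 2 and 4
#'   columns under five stimulations, against the intact single column.
#'
#' @param study One of the names above.
#' @param repeats,base_seed Passed to [experiment_protocol()].
#' @return Named list of protocols for [run_study()].
#' @export
study_conditions <- function(study = c("ll_single", "classes_single",
                                       "l23_multi", "multicolumn"),
                             repeats = 15L, base_seed = 20200313L) {
  study <- match.arg(study)
  p <- function(protocol, n_columns = 1L, ablation = ablation_spec())
    experiment_protocol(protocol, n_columns, ablation, repeats, base_seed)
  switch(study,
    ll_single = list(
      control   = p("a"),
      ll_l23    = p("a", ablation = "LL:L23"),
      ll_l5     = p("a", ablation = "LL:L5"),
      ll_both   = p("a", ablation = "LL")),
    classes_single = list(
      control   = p("a"),
      ll        = p("a", ablation = "LL:L23"),
      cl        = p("a", ablation = "CL:L23"),
      lr        = p("a", ablation = "LR:L23"),
      cl_lr     = p("a", ablation = c("CL:L23", "LR:L23"))),
    l23_multi = list(
      control   = p("b"),
      ll        = p("b", ablation = "LL:L23"),
      cl        = p("b", ablation = "CL:L23"),
      lr        = p("b", ablation = "LR:L23")),
    multicolumn = list(
      control   = p("b"),
      ll_1col   = p("b", ablation = "LL:L23"),
      ll_2col   = p("c", n_columns = 2L, ablation = "LL:L23"),
      ll_4col   = p("c", n_columns = 4L, ablation = "LL:L23")))
}

#' @export
print.pfc_report <- function(x, ...) {
  ag <- x$aggregate
  cat(sprintf("pfc_report%s: %d repeats\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"), ag$n))
  for (i in seq_along(ag$per_window_mean))
    cat(sprintf("  window %d: %.2f +/- %.2f %%\n", i,
                ag$per_window_mean[i], ag$per_window_sem[i]))
  invisible(x)
}
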