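#' @useDynLib pfcmaint, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-column population counts by largest-remainder rounding
#'
#' Allocates `n_total` neurons to the (type, layer) populations of the
#' proportion table so the total is hit exactly: floors first, then the
#' remaining cells go to the populations with the largest fractional
#' remainders (ties broken by table order).
#'
#' @param cfg A [pfc_config()].
#' @param n_total Neurons per column (default from config, 2000).
#' @return The proportion table with an added integer `n` column.
#' @export
cell_populations <- function(cfg, n_total = cfg$options$n_per_column) {
  pr <- cfg$proportions
  raw <- pr$proportion * n_total
  n <- floor(raw)
  short <- round(n_total - sum(n))
  if (short > 0) {
    take <- order(raw - n, decreasing = TRUE)[seq_len(short)]
    n[take] <- n[take] + 1
  }
  pr$n <- as.integer(n)
  pr
}

interneuron_types <- c("ChC", "BPC", "DBC", "LBC", "MC")

# Expand wildcard layers and the "IN" post-type token into concrete
# (pre_type, pre_layer, post_type, post_layer) rows; fill STP defaults.
expand_rules <- function(cfg) {
  con <- cfg$connectivity
  pops <- cfg$proportions
  layers <- unique(pops$layer)
  rows <- list()
  for (i in seq_len(nrow(con))) {
    r <- con[i, ]
    pre_layers <- if (r$pre_layer == "*") layers else r$pre_layer
    post_layers <- if (r$post_layer == "*") layers else r$post_layer
    post_types <- switch(r$post_type,
      "*" = unique(pops$type), "IN" = interneuron_types, r$post_type)
    for (pl in pre_layers) for (ql in post_layers) for (qt in post_types) {
      if (!any(pops$type == r$pre_type & pops$layer == pl)) next
      if (!any(pops$type == qt & pops$layer == ql)) next
      rr <- r
      rr$pre_layer <- pl; rr$post_layer <- ql; rr$post_type <- qt
      rows[[length(rows) + 1L]] <- rr
    }
  }
  out <- do.call(rbind, rows)
  out$U <- ifelse(is.na(out$U), cfg$options$stp_U, out$U)
  out$tau_facil_ms <- ifelse(is.na(out$tau_facil_ms),
                             cfg$options$stp_tau_facil_ms, out$tau_facil_ms)
  out$tau_rec_ms <- ifelse(is.na(out$tau_rec_ms),
                           cfg$options$stp_tau_rec_ms, out$tau_rec_ms)
  out$delay_ms <- ifelse(is.na(out$delay_ms),
                         cfg$options$delay_default_ms, out$delay_ms)
  rownames(out) <- NULL
  out
}

# Derived cross-column rules: PC and long-range interneuron (LBC, MC)
# projections mirror the within-column rules at reduced probabilities.
# Excitatory and long-range-inhibitory projections carry separate scale
# factors; the inhibitory one defaults to the shared scale.
cross_rules <- function(cfg, scale = cfg$options$cross_column_scale,
                        scale_inh = cfg$options$cross_column_scale_inh) {
  if (is.null(scale_inh) || is.na(scale_inh)) scale_inh <- scale
  rules <- expand_rules(cfg)
  rules <- rules[rules$pre_type %in% c("PC", "LBC", "MC"), ]
  rules$p <- rules$p * ifelse(rules$pre_type == "PC", scale, scale_inh)
  # inter-column synapses carry the canonical STP triple; per-connection
  # overrides in the table describe the within-column synapse populations
  rules$U <- cfg$options$stp_U
  rules$tau_facil_ms <- cfg$options$stp_tau_facil_ms
  rules$tau_rec_ms <- cfg$options$stp_tau_rec_ms
  rules
}

draw_edges <- function(rule, pre_ids, post_ids) {
  n1 <- length(pre_ids); n2 <- length(post_ids)
  npairs <- n1 * n2
  if (npairs == 0 || rule$p <= 0) return(NULL)
  m <- stats::rbinom(1, npairs, rule$p)
  if (m == 0) return(NULL)
  idx <- sample.int(npairs, m)
  pre <- pre_ids[(idx - 1L) %% n1 + 1L]
  post <- post_ids[(idx - 1L) %/% n1 + 1L]
  keep <- pre != post
  if (!any(keep)) return(NULL)
  data.frame(pre = pre[keep], post = post[keep],
             g_ampa_nS = rule$g_ampa_nS, g_nmda_nS = rule$g_nmda_nS,
             g_gabaa_nS = rule$g_gabaa_nS, delay_ms = rule$delay_ms,
             U = rule$U, tau_facil_ms = rule$tau_facil_ms,
             tau_rec_ms = rule$tau_rec_ms)
}

make_neuron_table <- function(cfg, column, id_offset,
                              n_total = cfg$options$n_per_column) {
  vth_sd <- cfg$options$vth_sd_mV
  if (is.null(vth_sd) || is.na(vth_sd)) vth_sd <- 0
  pops <- cell_populations(cfg, n_total)
  # order: L2/3 first with PC leading so the stimulus image maps onto the
  # first 900 ids of each column
  type_order <- c("PC", "ChC", "BPC", "DBC", "LBC", "MC")
  pops <- pops[order(match(pops$layer, c("L23", "L5")),
                     match(pops$type, type_order)), ]
  neurons <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    p <- pops[i, ]
    if (p$n == 0) return(NULL)
    pr <- neuron_param_row(cfg, p$type, p$layer)
    data.frame(id = integer(p$n), column = column, type = p$type,
               layer = p$layer, C_m_pF = pr$C_m_pF, g_L_nS = pr$g_L_nS,
               E_L_mV = pr$E_L_mV, V_th_mV = pr$V_th_mV,
               Delta_T_mV = pr$Delta_T_mV, tau_w_ms = pr$tau_w_ms,
               a_nS = pr$a_nS, b_pA = pr$b_pA, V_r_mV = pr$V_r_mV,
               I_bg_pA = pr$I_bg_pA,
               w_min_pA = if (is.null(pr$w_min_pA)) -Inf else pr$w_min_pA)
  }))
  neurons$id <- id_offset + seq_len(nrow(neurons))
  # cell-to-cell variability: thresholds are drawn around the table means
  # (the parameter table reports means of measured distributions)
  if (vth_sd > 0)
    neurons$V_th_mV <- neurons$V_th_mV +
      pmax(pmin(stats::rnorm(nrow(neurons), 0, vth_sd), 3 * vth_sd),
           -3 * vth_sd)
  neurons$V_peak_mV <- neurons$V_th_mV +
    cfg$options$v_peak_mult * neurons$Delta_T_mV
  neurons
}

column_edges <- function(cfg, neurons) {
  rules <- expand_rules(cfg)
  chunks <- lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    pre <- neurons$id[neurons$type == r$pre_type & neurons$layer == r$pre_layer]
    post <- neurons$id[neurons$type == r$post_type & neurons$layer == r$post_layer]
    draw_edges(r, pre, post)
  })
  do.call(rbind, chunks)
}

#' Build a single 2000-neuron laminar column
#'
#' Allocates the (type, layer) populations by largest-remainder rounding of
#' the configured proportions and wires every ordered cell pair
#' independently with its rule's probability (single Bernoulli draw per
#' pair, no autapses). Excitatory connections carry AMPA and NMDA
#' conductances sharing one short-term-plasticity state; interneuron
#' connections carry GABA_A.
#'
#' @param cfg A [pfc_config()].
#' @param seed Integer seed; construction is deterministic given the seed.
#' @param column Column index stored on the neurons (default 1).
#' @param n_total Neurons in the column (default 2000).
#' @return A `pfc_network`: list with `neurons` and `synapses` data frames,
#'   `seed`, and `n_columns`.
#' @export
build_column <- function(cfg, seed, column = 1L,
                         n_total = cfg$options$n_per_column) {
  with_seed(seed, {
    neurons <- make_neuron_table(cfg, column, 0L, n_total)
    synapses <- column_edges(cfg, neurons)
    structure(list(neurons = neurons, synapses = synapses,
                   seed = seed, n_columns = 1L, cfg_options = cfg$options,
                   receptors = cfg$receptors),
              class = "pfc_network")
  })
}

#' Build a multicolumn network
#'
#' Stacks `n_columns` statistically exchangeable columns and adds
#' cross-column synapses drawn only from pyramidal cells and long-range
#' interneurons (large basket and Martinotti cells), mirroring the
#' within-column target preferences at a reduced connection probability
#' (`cross_column_scale`, default 0.5).
#'
#' @inheritParams build_column
#' @param n_columns Number of columns (1-4 in the study protocols).
#' @param intercolumn_rules Optional explicit cross-column rule table in the
#'   format of [pfc_config()]'s connectivity table; defaults to the derived
#'   mirror rules. Presynaptic types other than PC/LBC/MC are rejected.
#' @return A `pfc_network` spanning all columns.
#' @export
build_multicolumn <- function(cfg, n_columns, seed,
                              intercolumn_rules = NULL) {
  stopifnot(n_columns >= 1)
  if (is.null(intercolumn_rules)) {
    intercolumn_rules <- cross_rules(cfg)
    # normalize long-range inhibition by the neighbor count so the total
    # cross-column inhibitory in-degree is independent of how many
    # columns are stacked
    if (n_columns > 2) {
      inh <- intercolumn_rules$pre_type %in% c("LBC", "MC")
      intercolumn_rules$p[inh] <- intercolumn_rules$p[inh] / (n_columns - 1)
    }
  }
  if (!all(intercolumn_rules$pre_type %in% c("PC", "LBC", "MC")))
    stop("cross-column projections may originate only from PC or long-range interneurons (LBC, MC)")
  with_seed(seed, {
    n_per <- cfg$options$n_per_column
    neurons <- do.call(rbind, lapply(seq_len(n_columns), function(ci) {
      make_neuron_table(cfg, ci, (ci - 1L) * n_per)
    }))
    chunks <- lapply(seq_len(n_columns), function(ci) {
      column_edges(cfg, neurons[neurons$column == ci, ])
    })
    if (n_columns > 1) {
      for (ci in seq_len(n_columns)) for (cj in seq_len(n_columns)) {
        if (ci == cj) next
        pre_n <- neurons[neurons$column == ci, ]
        post_n <- neurons[neurons$column == cj, ]
        cross <- lapply(seq_len(nrow(intercolumn_rules)), function(i) {
          r <- intercolumn_rules[i, ]
          pre <- pre_n$id[pre_n$type == r$pre_type & pre_n$layer == r$pre_layer]
          post <- post_n$id[post_n$type == r$post_type &
                              post_n$layer == r$post_layer]
          draw_edges(r, pre, post)
        })
        chunks[[length(chunks) + 1L]] <- do.call(rbind, cross)
      }
    }
    synapses <- do.call(rbind, chunks)
    rownames(synapses) <- NULL
    structure(list(neurons = neurons, synapses = synapses,
                   seed = seed, n_columns = as.integer(n_columns),
                   cfg_options = cfg$options, receptors = cfg$receptors),
              class = "pfc_network")
  })
}

#' Describe an ablation target set
#'
#' Targets are given as strings `"class:layer:column"`, where class is an
#' interneuron class (`LL`, `CL`, `LR`, `IN`) or a cell type name, and layer
#' (`L23`, `L5`) and column may be `"*"` (the default when omitted), e.g.
#' `"LL:L23"` for all layer 2/3 chandelier cells in every column.
#'
#' @param ... Target strings.
#' @return Data frame with columns `class`, `layer`, `column`.
#' @export
ablation_spec <- function(...) {
  targets <- c(...)
  if (length(targets) == 0)
    return(data.frame(class = character(), layer = character(),
                      column = character()))
  parts <- lapply(strsplit(targets, ":", fixed = TRUE), function(p) {
    c(p, rep("*", 3 - length(p)))[1:3]
  })
  m <- do.call(rbind, parts)
  data.frame(class = m[, 1], layer = m[, 2], column = m[, 3])
}

resolve_ablation <- function(net, spec) {
  nn <- net$neurons
  hit <- rep(FALSE, nrow(nn))
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    sel <- nn$type %in% cell_class_types(s$class)
    if (s$layer != "*") sel <- sel & nn$layer == s$layer
    if (s$column != "*") sel <- sel & nn$column == as.integer(s$column)
    hit <- hit | sel
  }
  nn$id[hit]
}

#' Structurally remove an interneuron class from a network
#'
#' Deletes the targeted neurons together with every synapse touching them;
#' all remaining neurons, synapses and parameters are identical to the
#' input network (ids are preserved). Ablating an empty target set returns
#' the network unchanged; a non-empty spec that resolves to no neurons
#' raises a warning and returns the identity.
#'
#' @param net A `pfc_network`.
#' @param spec An [ablation_spec()] data frame (or target strings).
#' @return The ablated `pfc_network`.
#' @export
apply_ablation <- function(net, spec) {
  if (is.character(spec)) spec <- ablation_spec(spec)
  if (nrow(spec) == 0) return(net)
  ids <- resolve_ablation(net, spec)
  if (length(ids) == 0) {
    warning("ablation spec resolved to no neurons; returning network unchanged")
    return(net)
  }
  net$neurons <- net$neurons[!(net$neurons$id %in% ids), ]
  net$synapses <- net$synapses[!(net$synapses$pre %in% ids) &
                                 !(net$synapses$post %in% ids), ]
  rownames(net$neurons) <- NULL
  rownames(net$synapses) <- NULL
  net
}

#' Ids of selected neurons
#'
#' @param net A `pfc_network`.
#' @param types Cell types to keep (default all).
#' @param layers Layers to keep (default all).
#' @param columns Columns to keep (default all).
#' @return Integer vector of neuron ids.
#' @export
neuron_ids <- function(net, types = NULL, layers = NULL, columns = NULL) {
  nn <- net$neurons
  sel <- rep(TRUE, nrow(nn))
  if (!is.null(types)) sel <- sel & nn$type %in% types
  if (!is.null(layers)) sel <- sel & nn$layer %in% layers
  if (!is.null(columns)) sel <- sel & nn$column %in% columns
  nn$id[sel]
}

#' @export
print.pfc_network <- function(x, ...) {
  cat(sprintf("pfc_network: %d neurons in %d column(s), %d synapses (seed %d)\n",
              nrow(x$neurons), x$n_columns, nrow(x$synapses), x$seed))
  print(table(x$neurons$type, x$neurons$layer))
  invisible(x)
}
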