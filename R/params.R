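#' Load the default model configuration
#'
#' Reads the parameter tables shipped with the package: per-cell-type
#' adaptive exponential integrate-and-fire (aEIF) constants and background
#' currents, per-layer cell-type proportions, receptor kinetics
#' (AMPA/NMDA/GABA_A), and the cell-type-to-cell-type connection table
#' (probability, peak conductances, delay, optional short-term-plasticity
#' overrides). All tables are plain TSV under `inst/extdata` so they can be
#' edited without touching code.
#'
#' @param path Directory holding the four TSV tables plus `options.tsv`.
#'   Defaults to the tables shipped with the package.
#' @return A list of class `pfc_config` with elements `neurons`,
#'   `proportions`, `receptors`, `connectivity` (data frames) and `options`
#'   (named list of scalars).
#' @export
pfc_config <- function(path = system.file("extdata", package = "pfcmaint")) {
  read_tsv <- function(f) {
    utils::read.delim(file.path(path, f), stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  opts_df <- read_tsv("options.tsv")
  opts <- as.list(stats::setNames(as.numeric(opts_df$value), opts_df$key))
  cfg <- structure(list(
    neurons      = read_tsv("neuron_params.tsv"),
    proportions  = read_tsv("cell_proportions.tsv"),
    receptors    = read_tsv("receptors.tsv"),
    connectivity = read_tsv("connectivity.tsv"),
    options      = opts
  ), class = "pfc_config")
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks the structural invariants of the parameter tables: positive
#' capacitances, conductances and time constants; proportions summing to 1;
#' connection probabilities in \[0,1\]; receptor offset time constants larger
#' than onset time constants; inhibitory presynaptic types carrying only
#' GABA_A conductance and excitatory types only AMPA/NMDA.
#'
#' @param cfg A `pfc_config` list.
#' @return `cfg`, invisibly; stops on violation.
#' @export
validate_config <- function(cfg) {
  np <- cfg$neurons
  stopifnot(
    all(np$C_m_pF > 0), all(np$g_L_nS > 0), all(np$tau_w_ms > 0),
    all(np$Delta_T_mV > 0)
  )
  vpk <- np$V_th_mV + cfg$options$v_peak_mult * np$Delta_T_mV
  stopifnot(all(np$V_r_mV < vpk), all(np$V_th_mV < vpk))
  if (abs(sum(cfg$proportions$proportion) - 1) > 1e-6)
    stop("cell-type proportions must sum to 1")
  if (nrow(merge(cfg$proportions, data.frame(type = "BPC", layer = "L5"))) > 0)
    stop("L5 carries no BPC population")
  con <- cfg$connectivity
  if (any(con$p < 0 | con$p > 1)) stop("connection probabilities must be in [0,1]")
  inhib <- con$pre_type %in% c("ChC", "BPC", "DBC", "LBC", "MC")
  if (any(inhib & (con$g_ampa_nS > 0 | con$g_nmda_nS > 0)))
    stop("inhibitory presynaptic types cannot carry AMPA/NMDA conductance")
  if (any(!inhib & con$g_gabaa_nS > 0))
    stop("excitatory presynaptic types cannot carry GABA_A conductance")
  rec <- cfg$receptors
  if (any(rec$tau_off_ms <= rec$tau_on_ms))
    stop("receptor tau_off must exceed tau_on")
  invisible(cfg)
}

#' Interneuron class membership by axonal range
#'
#' `LL` (local-layer) interneurons are chandelier cells; `CL` (cross-layer)
#' are bipolar and double-bouquet cells; `LR` (long-range) are large basket
#' and Martinotti cells. `IN` covers all five; `E` is the pyramidal cells.
#'
#' @param class One of `"LL"`, `"CL"`, `"LR"`, `"IN"`, `"E"`, or a cell type
#'   name (`"PC"`, `"ChC"`, `"BPC"`, `"DBC"`, `"LBC"`, `"MC"`).
#' @return Character vector of cell type names.
#' @export
cell_class_types <- function(class) {
  switch(class,
    LL  = "ChC",
    CL  = c("BPC", "DBC"),
    LR  = c("LBC", "MC"),
    IN  = c("ChC", "BPC", "DBC", "LBC", "MC"),
    E   = "PC",
    PC  = , ChC = , BPC = , DBC = , LBC = , MC = class,
    stop("unknown cell class: ", class)
  )
}

#' Numerical spike-detection ceiling for a parameter row
#'
#' The aEIF exponential term diverges in finite time once the membrane
#' potential escapes past threshold, so a spike is declared when V crosses
#' `V_th + v_peak_mult * Delta_T` (default multiplier 5), after which the
#' reset rule is applied.
#'
#' @param params A row of the neuron parameter table (list or one-row
#'   data frame with `V_th_mV` and `Delta_T_mV`).
#' @param mult Multiplier on the slope factor (default 5).
#' @return V_peak in mV.
#' @export
v_peak <- function(params, mult = 5) {
  params$V_th_mV + mult * params$Delta_T_mV
}

neuron_param_row <- function(cfg, type, layer) {
  np <- cfg$neurons
  row <- np[np$type == type & np$layer == layer, ]
  if (nrow(row) != 1)
    stop("no neuron parameters for ", type, " in ", layer)
  as.list(row)
}
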