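#' The default triangular stimulus pattern
#'
#' A filled, apex-up, horizontally centered isoceles triangle on the 30x30
#' grid, mirror-symmetric about the vertical midline. Used as the standard
#' input image of the stimulation protocols.
#'
#' @return A 30x30 integer matrix of 0/1.
#' @export
make_triangle_pattern <- function() {
  m <- matrix(0L, 30, 30)
  rows <- 5:26                           # 22 rows tall, centered vertically
  for (i in seq_along(rows)) {
    half <- round(10 * (i - 1) / 21) + 1 # half-width grows 1..11
    cols <- (16 - half):(15 + half)      # symmetric about cols 15|16
    m[rows[i], cols] <- 1L
  }
  m
}

#' A random binary stimulus pattern
#'
#' Independent Bernoulli(density) entries, deterministic given the seed.
#'
#' @param density Probability that a cell is active, in \[0,1\].
#' @param seed Integer seed.
#' @return A 30x30 integer matrix of 0/1.
#' @export
make_random_pattern <- function(density, seed) {
  stopifnot(density >= 0, density <= 1)
  with_seed(seed, matrix(as.integer(stats::runif(900) < density), 30, 30))
}

#' Map matrix cells onto layer 2/3 pyramidal cells
#'
#' Row-major bijection from the 900 cells of the 30x30 stimulus grid onto
#' the first 900 layer 2/3 pyramidal cells of the target column.
#'
#' @param net A `pfc_network`.
#' @param column Target column index.
#' @return Integer vector of 900 neuron ids; entry k is the PC for matrix
#'   cell k in row-major order.
#' @export
pc_index_map <- function(net, column = 1L) {
  ids <- neuron_ids(net, types = "PC", layers = "L23", columns = column)
  if (length(ids) < 900)
    stop("column ", column, " has fewer than 900 L2/3 pyramidal cells")
  sort(ids)[1:900]
}

#' Stimulation window onsets for the study protocols
#'
#' Protocol "a" delivers one 20 ms stimulus starting at 51 ms; protocols
#' "b" and "c" deliver five, at 51, 301, 551, 801 and 1051 ms.
#'
#' @param protocol `"a"`, `"b"` or `"c"`.
#' @return Numeric vector of window onset times (ms).
#' @export
stim_onsets <- function(protocol = c("a", "b", "c")) {
  protocol <- match.arg(protocol)
  if (protocol == "a") 51 else c(51, 301, 551, 801, 1051)
}

#' Encode a binary pattern as timed spike trains
#'
#' Every active matrix cell yields, for each stimulation window, a
#' deterministic regular spike train at the stimulus rate on its mapped
#' pyramidal cell: at 1000 Hz a 20 ms window carries 20 spikes at 1 ms
#' spacing starting at the window onset. Inactive cells yield nothing.
#' A Poisson variant (same expected count) is available for robustness
#' checks.
#'
#' @param pattern 30x30 binary matrix.
#' @param map Neuron ids from [pc_index_map()] (row-major over cells).
#' @param onsets Window onset times (ms), e.g. [stim_onsets()].
#' @param window_ms Window length (default 20 ms).
#' @param rate_hz Stimulus rate (default 1000 Hz).
#' @param poisson Draw Poisson spike times instead of a regular train.
#' @param seed Seed for the Poisson variant.
#' @return Data frame with `neuron` (id) and `time_ms`, sorted by time.
#' @export
encode_to_spikes <- function(pattern, map, onsets, window_ms = 20,
                             rate_hz = 1000, poisson = FALSE, seed = 1L) {
  stopifnot(all(pattern %in% c(0L, 1L)), length(map) == length(pattern))
  isi <- 1000 / rate_hz
  if (window_ms < isi)
    stop("stimulation window shorter than one inter-spike interval")
  active <- map[as.vector(t(pattern)) == 1L]   # row-major cell order
  if (length(active) == 0)
    return(data.frame(neuron = integer(), time_ms = numeric()))
  if (poisson) {
    return(with_seed(seed, {
      ev <- lapply(onsets, function(on) {
        n <- stats::rpois(length(active), rate_hz * window_ms / 1000)
        data.frame(
          neuron = rep(active, n),
          time_ms = on + stats::runif(sum(n)) * window_ms)
      })
      out <- do.call(rbind, ev)
      out[order(out$time_ms, out$neuron), ]
    }))
  }
  offsets <- seq(0, by = isi, length.out = floor(window_ms / isi))
  ev <- expand.grid(neuron = active, off = offsets, on = onsets)
  out <- data.frame(neuron = ev$neuron, time_ms = ev$on + ev$off)
  out <- out[order(out$time_ms, out$neuron), ]
  rownames(out) <- NULL
  out
}

#' Write / read a binary pattern as PBM (P1)
#'
#' Plain-text portable bitmap, one matrix row per line.
#'
#' @param pattern 30x30 binary matrix.
#' @param path File path.
#' @return `read_pbm` returns the integer matrix.
#' @export
write_pbm <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P1", con)
  writeLines(sprintf("%d %d", ncol(pattern), nrow(pattern)), con)
  apply(pattern, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pbm
#' @export
read_pbm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  stopifnot(lines[1] == "P1")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
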