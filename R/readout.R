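#' Decode a readout window into a binary output image
#'
#' A matrix cell is 1 iff its mapped layer 2/3 pyramidal cell emitted at
#' least one spike strictly inside the window, else 0.
#'
#' @param raster A `pfc_raster` (or its `events` data frame).
#' @param map Neuron ids from [pc_index_map()], row-major over cells.
#' @param window Numeric `c(start, end)` in ms; must lie within the
#'   recorded duration.
#' @return A 30x30 integer matrix of 0/1.
#' @export
decode_window <- function(raster, map, window) {
  ev <- if (inherits(raster, "pfc_raster")) raster$events else raster
  if (inherits(raster, "pfc_raster") && window[2] > raster$duration + 1e-9)
    stop("readout window extends beyond the recorded duration")
  inwin <- ev$time_ms > window[1] & ev$time_ms < window[2]
  spiked <- unique(ev$id[inwin])
  matrix(as.integer(map %in% spiked), nrow = 30, ncol = 30, byrow = TRUE)
}

#' Information-maintenance accuracy
#'
#' Percentage of the 900 layer 2/3 pyramidal cells whose binary readout
#' matches the binary input,
#' \deqn{p_{accuracy} = N_{input=output} / N_{L2/3\,PC} \times 100,}
#' where agreement on inactive cells (both 0) counts.
#'
#' @param input,output Binary matrices of identical shape.
#' @return Accuracy in percent, in \[0, 100\].
#' @export
accuracy <- function(input, output) {
  if (!all(dim(input) == dim(output)))
    stop("input and output patterns differ in shape")
  mean(input == output) * 100
}

#' Aggregate per-trial accuracies
#'
#' Mean and standard error of the mean (sample sd / sqrt(n)) across
#' independent repeats, per readout window and overall.
#'
#' @param trials Numeric matrix, rows = trials, columns = readout windows
#'   (a vector is treated as one window).
#' @return List with `per_window_mean`, `per_window_sem`, `mean`, `sem`,
#'   `n`, and the input matrix as `per_trial`.
#' @export
aggregate_trials <- function(trials) {
  if (is.vector(trials)) trials <- matrix(trials, ncol = 1)
  n <- nrow(trials)
  if (n < 2) stop("SEM requires at least 2 trials")
  pw_mean <- colMeans(trials)
  pw_sem <- apply(trials, 2, stats::sd) / sqrt(n)
  trial_means <- rowMeans(trials)
  list(per_window_mean = pw_mean, per_window_sem = pw_sem,
       mean = mean(trial_means), sem = stats::sd(trial_means) / sqrt(n),
       n = n, per_trial = trials)
}

#' Readout windows for a protocol
#'
#' Each stimulation window is followed by a 160 ms readout window anchored
#' at the stimulus offset: 70-230 ms for the single stimulus, and
#' additionally 320-480, 570-730, 820-980, 1070-1230 ms for the
#' five-stimulus protocols.
#'
#' @param protocol `"a"`, `"b"` or `"c"`.
#' @param window_ms Stimulus window length (default 20 ms).
#' @param readout_ms Readout length (default 160 ms).
#' @return List of `c(start, end)` windows (ms).
#' @export
readout_windows <- function(protocol = c("a", "b", "c"), window_ms = 20,
                            readout_ms = 160) {
  protocol <- match.arg(protocol)
  lapply(stim_onsets(protocol), function(on) {
    off <- on + window_ms - 1   # last stimulus spike at onset + 19 ms
    c(off, off + readout_ms)
  })
}
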