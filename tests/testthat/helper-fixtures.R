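# shared fixtures: small configs and hand-built epoch sets

quick_cfg <- function(seed = 1, ...) {
  generator_config(sampling_rate = 1000, seed = seed, ...)
}

# epoch_set from a trials x samples matrix on a -200..200 ms axis at 1 kHz
make_epoch_set <- function(data, meta = NULL) {
  n <- ncol(data)
  stopifnot(n == 401)
  if (is.null(meta))
    meta <- data.frame(trigger = seq_len(nrow(data)),
                       channel = "FDI_R")
  structure(list(data = data, time_ms = seq(-200, 200), meta = meta),
            class = "epoch_set")
}

# averaged-trace time axis helper
ms_axis <- function(fs = 1000) seq(-200 * fs / 1000, 200 * fs / 1000) /
  fs * 1000

# a minimal mep_table-like data frame
make_mep_tab <- function(participant, location, post, pre,
                         task = "rest", orientation = 45, intensity = 110) {
  tab <- data.frame(participant = participant, channel = "FDI_R",
                    task = task, location = location,
                    orientation = orientation, intensity = intensity,
                    amplitude_post = post, amplitude_pre = pre,
                    latency_ms = NA_real_, n_trials = 10L)
  class(tab) <- c("mep_table", "data.frame")
  tab
}
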