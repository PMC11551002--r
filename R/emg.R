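#' Continuous multi-channel EMG record with TMS triggers
#'
#' @param samples Numeric matrix, samples in rows, one column per channel
#'   (muscle); values in mV. A plain vector is treated as one channel.
#' @param sampling_rate Sampling rate in Hz (1000-20000).
#' @param trigger_s TMS trigger times in seconds, strictly increasing and at
#'   least 0.2 s from both record edges.
#' @return An object of class `continuous_record`.
#' @export
continuous_record <- function(samples, sampling_rate, trigger_s) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  if (sampling_rate < 1000 || sampling_rate > 20000)
    stopf("sampling_rate must lie in [1000, 20000] Hz")
  if (length(trigger_s) && any(diff(trigger_s) <= 0))
    stopf("triggers must be strictly increasing")
  dur <- (nrow(samples) - 1) / sampling_rate
  if (length(trigger_s) &&
      (min(trigger_s) < 0.2 || max(trigger_s) > dur - 0.2))
    stopf("triggers must be >= 0.2 s from both record edges")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 trigger_s = as.numeric(trigger_s)),
            class = "continuous_record")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (zero-phase, effective order 4) to every channel. The two-pass scheme
#' squares the magnitude response and cancels the phase response, preserving
#' MEP onset latencies.
#'
#' @param record A [continuous_record()].
#' @param low,high Band edges in Hz (defaults 25 and 250).
#' @param order Butterworth order per pass.
#' @return The filtered `continuous_record`.
#' @export
bandpass <- function(record, low = 25, high = 250, order = 2) {
  stopifnot(inherits(record, "continuous_record"))
  fs <- record$sampling_rate
  if (!(low > 0 && low < high)) stopf("need 0 < low < high")
  if (high >= fs / 2)
    stopf("high edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
          high, fs / 2)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  record$samples <- apply(record$samples, 2,
                          function(x) signal::filtfilt(bf, x))
  record
}

#' Segment a continuous record into TMS-locked epochs
#'
#' Cuts one epoch per trigger, from `pre_ms` before to `post_ms` after the
#' pulse, endpoints inclusive. Time 0 is the sample nearest the trigger
#' (ties resolved toward the earlier sample). Triggers whose window does not
#' fit inside the record are rejected with a warning, mirroring the removal
#' of trials with missed hardware triggers.
#'
#' @param record A [continuous_record()].
#' @param pre_ms,post_ms Window half-widths in ms (defaults 200 and 200).
#' @return An object of class `epoch_set`: a list with `data` (matrix, one
#'   row per trial x channel), `time_ms` (shared time axis, ms, 0 = TMS) and
#'   `meta` (data frame with `trigger`, `channel` and, once filled by the
#'   caller or by [generate_experiment()], the condition metadata
#'   `participant`, `task`, `location`, `orientation`, `intensity`).
#' @export
segment_epochs <- function(record, pre_ms = 200, post_ms = 200) {
  stopifnot(inherits(record, "continuous_record"))
  fs <- record$sampling_rate
  n_pre <- round(fs * pre_ms / 1000)
  n_post <- round(fs * post_ms / 1000)
  n <- nrow(record$samples)
  # nearest sample to the trigger, half-sample ties toward the earlier one
  centre <- ceiling(record$trigger_s * fs - 0.5) + 1
  ok <- centre - n_pre >= 1 & centre + n_post <= n
  if (any(!ok))
    warnf("%d trigger(s) rejected: epoch window outside the record",
          sum(!ok))
  centre <- centre[ok]
  chans <- colnames(record$samples)
  n_ep <- length(centre) * length(chans)
  data <- matrix(NA_real_, nrow = n_ep, ncol = n_pre + n_post + 1)
  meta <- data.frame(trigger = rep(which(ok), times = length(chans)),
                     channel = rep(chans, each = length(centre)),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (ch in seq_along(chans)) {
    for (k in seq_along(centre)) {
      row <- row + 1L
      data[row, ] <- record$samples[(centre[k] - n_pre):(centre[k] + n_post),
                                    ch]
    }
  }
  structure(list(data = data,
                 time_ms = seq(-n_pre, n_post) / fs * 1000,
                 meta = meta),
            class = "epoch_set")
}

# concatenate epoch sets sharing one time axis
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  t0 <- sets[[1]]$time_ms
  for (s in sets) {
    if (length(s$time_ms) != length(t0) || any(abs(s$time_ms - t0) > 1e-9))
      stopf("epoch sets have differing time axes")
  }
  metas <- lapply(sets, `[[`, "meta")
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
    m[cols]
  })
  structure(list(data = do.call(rbind, lapply(sets, `[[`, "data")),
                 time_ms = t0,
                 meta = do.call(rbind, metas)),
            class = "epoch_set")
}

#' Event-related average of TMS-locked epochs
#'
#' Pointwise mean across trials within each group defined by metadata keys,
#' suppressing background EMG that is not phase-locked to the pulse.
#'
#' @param epoch_set An `epoch_set` from [segment_epochs()].
#' @param group_by Character vector of metadata column names defining the
#'   averaging groups (e.g. `c("participant", "channel", "task")`).
#' @return An `epoch_set` with one averaged trace per group; `meta` carries
#'   the grouping keys plus `n_trials`.
#' @export
event_related_average <- function(epoch_set,
                                  group_by = intersect(
                                    c("participant", "channel", "task",
                                      "location", "orientation", "intensity"),
                                    names(epoch_set$meta))) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  miss <- setdiff(group_by, names(epoch_set$meta))
  if (length(miss)) stopf("unknown metadata key(s): %s",
                          paste(miss, collapse = ", "))
  key <- interaction(epoch_set$meta[group_by], drop = TRUE, lex.order = TRUE)
  if (any(tabulate(key) == 0)) stopf("empty group")
  groups <- levels(key)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(epoch_set$data))
  meta <- epoch_set$meta[match(groups, key), group_by, drop = FALSE]
  meta$n_trials <- as.integer(table(key)[groups])
  for (g in seq_along(groups)) {
    rows <- which(key == groups[g])
    out[g, ] <- colMeans(epoch_set$data[rows, , drop = FALSE])
  }
  rownames(meta) <- NULL
  structure(list(data = out, time_ms = epoch_set$time_ms, meta = meta),
            class = "epoch_set")
}
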