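#' Peak-to-peak amplitude of a trace within a time window
#'
#' `max - min` of the trace over the window, endpoints inclusive. Adding a
#' constant offset to the trace leaves the result unchanged.
#'
#' @param trace Numeric vector (mV).
#' @param time_ms Time axis of `trace` in ms.
#' @param window Length-2 numeric, window in ms (inclusive).
#' @return Peak-to-peak amplitude in mV.
#' @export
peak_to_peak <- function(trace, time_ms, window = c(10, 50)) {
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  if (!length(idx)) stopf("window [%g, %g] ms contains no samples",
                          window[1], window[2])
  v <- trace[idx]
  max(v) - min(v)
}

#' Baseline threshold-crossing contrast around the TMS pulse
#'
#' Forms a baseline tolerance band (mean +/- `z` SD of the samples in
#' `baseline_window`) and counts samples outside it in the post-TMS MEP
#' window and in a pre-TMS control window of equal length. A genuine MEP
#' yields more extreme samples after than before the pulse; with stationary
#' noise the two counts are exchangeable.
#'
#' @param trace Averaged trace (mV).
#' @param time_ms Time axis (ms, 0 = TMS).
#' @param baseline_window Baseline interval in ms (default `c(-200, -50)`).
#' @param post_window,pre_window MEP and control windows (defaults
#'   `c(10, 50)` and `c(-50, -10)`).
#' @param z Half-width of the band in baseline SDs (default 1.96, a 95%
#'   tolerance band). With a degenerate zero-SD baseline the band collapses
#'   to the mean and the counts remain defined.
#' @return List with `n_post`, `n_pre`, `ci` (band bounds) and the window
#'   sample count `n_window`.
#' @export
crossing_count_contrast <- function(trace, time_ms,
                                    baseline_window = c(-200, -50),
                                    post_window = c(10, 50),
                                    pre_window = c(-50, -10),
                                    z = 1.96) {
  b <- trace[time_ms >= baseline_window[1] & time_ms <= baseline_window[2]]
  if (!length(b)) stopf("baseline window contains no samples")
  m <- mean(b); s <- sd(b)
  if (!is.finite(s)) s <- 0
  ci <- c(m - z * s, m + z * s)
  count <- function(w) {
    v <- trace[time_ms >= w[1] & time_ms <= w[2]]
    sum(v < ci[1] | v > ci[2])
  }
  n_post_w <- sum(time_ms >= post_window[1] & time_ms <= post_window[2])
  n_pre_w <- sum(time_ms >= pre_window[1] & time_ms <= pre_window[2])
  list(n_post = count(post_window), n_pre = count(pre_window),
       ci = ci, n_window = c(post = n_post_w, pre = n_pre_w))
}

#' Automatic MEP onset latency
#'
#' Earliest time in `search_window` at which the averaged trace deviates from
#' the baseline mean by more than `k_sd` baseline SDs continuously for
#' `hold_ms`. The reported onset is refined to sub-sample precision by
#' linear interpolation of the threshold crossing between the last
#' sub-threshold and first supra-threshold sample. Returns `NA` when no
#' sustained deviation exists (absence of a detectable MEP is a value, not
#' an error).
#'
#' @inheritParams crossing_count_contrast
#' @param k_sd Detection threshold in baseline SDs (default 3).
#' @param hold_ms Required supra-threshold duration in ms (default 2).
#' @param search_window Interval searched for the onset, ms (default
#'   `c(10, 50)`, open at both ends).
#' @param mode `"baseline_sd"` (default): threshold is `k_sd` baseline SDs
#'   — sensitive, but its crossing time depends on the MEP's amplitude.
#'   `"fraction_of_peak"`: threshold is `peak_fraction` of the trace's own
#'   peak deviation within the search window (still requiring the
#'   `baseline_sd` detection threshold to be exceeded at the peak) — a
#'   self-scaling onset whose bias does not depend on MEP amplitude,
#'   preferred when comparing latencies across conditions with different
#'   amplitude distributions.
#' @param peak_fraction Fraction of the peak deviation used by
#'   `"fraction_of_peak"` (default 0.2).
#' @return Onset latency in ms, or `NA_real_`.
#' @export
auto_latency <- function(trace, time_ms, k_sd = 3, hold_ms = 2,
                         baseline_window = c(-200, -50),
                         search_window = c(10, 50),
                         mode = c("baseline_sd", "fraction_of_peak"),
                         peak_fraction = 0.2) {
  mode <- match.arg(mode)
  b <- trace[time_ms >= baseline_window[1] & time_ms <= baseline_window[2]]
  if (!length(b)) stopf("baseline window contains no samples")
  m <- mean(b); s <- sd(b)
  if (!is.finite(s) || s == 0) s <- .Machine$double.eps
  dt <- median(diff(time_ms))
  hold_n <- max(1L, round(hold_ms / dt))
  dev <- abs(trace - m)
  in_win <- time_ms > search_window[1] & time_ms < search_window[2]
  thr <- k_sd * s
  if (mode == "fraction_of_peak") {
    pk <- max(dev[in_win])
    if (pk <= thr) return(NA_real_)  # no detectable MEP
    thr <- peak_fraction * pk
  }
  above <- dev > thr
  cand <- which(above & in_win)
  for (i in cand) {
    run <- i:min(i + hold_n - 1L, length(above))
    if (length(run) == hold_n && all(above[run])) {
      if (i > 1 && dev[i - 1] <= thr && dev[i] > dev[i - 1]) {
        frac <- (thr - dev[i - 1]) / (dev[i] - dev[i - 1])
        return(time_ms[i - 1] + frac * (time_ms[i] - time_ms[i - 1]))
      }
      return(time_ms[i])
    }
  }
  NA_real_
}

#' Per-condition MEP measures from averaged epochs
#'
#' Averages epochs within each condition cell ([event_related_average()]) and
#' measures the peak-to-peak amplitude 10-50 ms after TMS
#' (`amplitude_post`), the matching pre-TMS control amplitude -50 to -10 ms
#' (`amplitude_pre`) and the automatic onset latency.
#'
#' @param epoch_set An `epoch_set`.
#' @param group_by Metadata keys defining the condition cells.
#' @param post_window,pre_window Measurement windows in ms.
#' @param latency Logical; also estimate [auto_latency()] per cell.
#' @param latency_mode Onset threshold mode passed to [auto_latency()].
#' @return A data frame of class `mep_table`: grouping keys plus
#'   `amplitude_post`, `amplitude_pre` (mV), `latency_ms`, `n_trials`.
#' @export
mep_table <- function(epoch_set,
                      group_by = intersect(
                        c("participant", "channel", "task", "location",
                          "orientation", "intensity"),
                        names(epoch_set$meta)),
                      post_window = c(10, 50), pre_window = c(-50, -10),
                      latency = TRUE, latency_mode = "baseline_sd") {
  avg <- event_related_average(epoch_set, group_by)
  tab <- avg$meta
  tab$amplitude_post <- apply(avg$data, 1, peak_to_peak,
                              time_ms = avg$time_ms, window = post_window)
  tab$amplitude_pre <- apply(avg$data, 1, peak_to_peak,
                             time_ms = avg$time_ms, window = pre_window)
  tab$latency_ms <- if (latency) {
    apply(avg$data, 1, auto_latency, time_ms = avg$time_ms,
          mode = latency_mode)
  } else NA_real_
  class(tab) <- c("mep_table", "data.frame")
  tab
}

#' Single-trial MEP measures
#'
#' Peak-to-peak amplitude per individual epoch in the post-TMS and pre-TMS
#' windows, without averaging. `amplitude_corrected` is the post minus pre
#' difference floored at zero, a background-referenced per-trial MEP measure
#' used by the threshold-estimation rules during movement states in which
#' raw peak-to-peak is dominated by background EMG.
#'
#' @inheritParams mep_table
#' @return Data frame: the epoch metadata plus `amplitude_post`,
#'   `amplitude_pre` and `amplitude_corrected` (mV).
#' @export
mep_trial_measures <- function(epoch_set, post_window = c(10, 50),
                               pre_window = c(-50, -10)) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  out <- epoch_set$meta
  out$amplitude_post <- apply(epoch_set$data, 1, peak_to_peak,
                              time_ms = epoch_set$time_ms,
                              window = post_window)
  out$amplitude_pre <- apply(epoch_set$data, 1, peak_to_peak,
                             time_ms = epoch_set$time_ms,
                             window = pre_window)
  out$amplitude_corrected <- pmax(out$amplitude_post - out$amplitude_pre, 0)
  out
}

#' Rescale MEP amplitudes to the per-scope maximum
#'
#' Divides `amplitude_post` (and `amplitude_pre`, by the same factor) by the
#' maximum `amplitude_post` within each normalization scope, so the largest
#' MEP in every scope becomes exactly 1. Scope `"participant_muscle"`
#' rescales per participant and muscle; `"participant_muscle_condition"`
#' additionally per task condition — the more stringent variant used when
#' comparing orientation preference across movement conditions.
#'
#' @param tab A [mep_table()].
#' @param scope `"participant_muscle"` or `"participant_muscle_condition"`.
#' @return The table with `amplitude_norm` and `amplitude_pre_norm` columns
#'   and a `normalization_scope` attribute. Idempotent.
#' @export
normalize_meps <- function(tab, scope = c("participant_muscle",
                                          "participant_muscle_condition")) {
  scope <- match.arg(scope)
  keys <- intersect(c("participant", "channel"), names(tab))
  if (scope == "participant_muscle_condition")
    keys <- c(keys, intersect("task", names(tab)))
  key <- if (length(keys)) {
    interaction(tab[keys], drop = TRUE)
  } else factor(rep(1, nrow(tab)))
  mx <- tapply(tab$amplitude_post, key, max)
  if (any(mx <= 0)) stopf("all-zero amplitude group within scope")
  f <- as.numeric(mx[key])
  tab$amplitude_norm <- tab$amplitude_post / f
  tab$amplitude_pre_norm <- tab$amplitude_pre / f
  attr(tab, "normalization_scope") <- scope
  tab
}
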