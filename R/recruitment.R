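#' Resting motor threshold by the 5-of-10 rule
#'
#' The lowest tested intensity at which at least `k` of the last `n`
#' single-trial MEP amplitudes exceed `criterion_uv`. Intensities with fewer
#' than `n` trials are skipped with a warning. The clinical adaptive hunting
#' procedure is replaced by offline evaluation over the supplied intensity
#' ladder; because recruitment is monotone, the threshold separates a sub-
#' from a supra-threshold regime, so by default (`persistent = TRUE`) the
#' estimate is the lowest intensity at and above which the criterion holds
#' for every tested intensity — isolated sub-threshold noise crossings do
#' not capture the estimate.
#'
#' @param trials Data frame with columns `intensity` and `amplitude_mV`
#'   (single-trial MEP amplitudes; callers choose the measure — during
#'   movement states a background-corrected amplitude such as
#'   `amplitude_corrected` from [mep_trial_measures()] should be supplied,
#'   since raw post-window peak-to-peak reflects background EMG there).
#' @param criterion_uv MEP criterion in microvolts (default 50).
#' @param k,n Required count among the last `n` trials (defaults 5 of 10).
#' @param persistent Require the criterion at all higher tested intensities
#'   too (default `TRUE`); `FALSE` takes the lowest isolated crossing.
#' @return List of class `threshold_estimate`: `kind`, `value` (intensity
#'   or `NA`), `evidence` (per-intensity counts).
#' @export
rmt_rossini <- function(trials, criterion_uv = 50, k = 5, n = 10,
                        persistent = TRUE) {
  ev <- threshold_evidence(trials, criterion_uv, n)
  ok <- !is.na(ev$n_above) & ev$n_above >= k
  structure(list(kind = "RMT_Rossini94",
                 value = lowest_regime(ev$intensity, ok,
                                       skip = is.na(ev$n_above),
                                       persistent = persistent),
                 criterion_uv = criterion_uv, evidence = ev),
            class = "threshold_estimate")
}

# lowest intensity satisfying the criterion; with persistent = TRUE, the
# lowest from which it holds at every higher (non-skipped) intensity
lowest_regime <- function(intensity, ok, skip = rep(FALSE, length(ok)),
                          persistent = TRUE) {
  keep <- !skip
  intensity <- intensity[keep]; ok <- ok[keep]
  if (!any(ok)) return(NA_real_)
  if (!persistent) return(min(intensity[ok]))
  run <- rev(cumall(rev(ok)))
  if (!any(run)) return(NA_real_)
  intensity[which(run)[1]]
}

threshold_evidence <- function(trials, criterion_uv, n) {
  stopifnot(all(c("intensity", "amplitude_mV") %in% names(trials)))
  ints <- sort(unique(trials$intensity))
  crit <- criterion_uv / 1000
  n_above <- vapply(ints, function(i) {
    a <- trials$amplitude_mV[trials$intensity == i]
    if (length(a) < n) {
      warnf("intensity %g skipped: %d < %d trials", i, length(a), n)
      return(NA_integer_)
    }
    sum(tail(a, n) > crit)
  }, integer(1))
  data.frame(intensity = ints, n_above = n_above, n = n)
}

#' Active motor threshold during movement (count-or-average rule)
#'
#' The lowest tested intensity at which either at least `k` of the last `n`
#' single-trial MEP amplitudes exceed `criterion_uv`, or the event-related
#' average MEP amplitude exceeds `criterion_uv`.
#'
#' @inheritParams rmt_rossini
#' @param averaged Data frame with `intensity` and `amplitude_mV` of the
#'   averaged MEP per intensity (background-corrected during movement, as
#'   for `trials`).
#' @return A `threshold_estimate` with `kind = "AMT_pegboard"`.
#' @export
amt_pegboard <- function(averaged, trials, criterion_uv = 50, k = 5,
                         n = 10, persistent = TRUE) {
  ev <- threshold_evidence(trials, criterion_uv, n)
  ev$avg_mV <- averaged$amplitude_mV[match(ev$intensity,
                                           averaged$intensity)]
  crit <- criterion_uv / 1000
  ok <- (!is.na(ev$n_above) & ev$n_above >= k) |
    (!is.na(ev$avg_mV) & ev$avg_mV > crit)
  structure(list(kind = "AMT_pegboard",
                 value = lowest_regime(ev$intensity, ok,
                                       skip = is.na(ev$n_above) &
                                         is.na(ev$avg_mV),
                                       persistent = persistent),
                 criterion_uv = criterion_uv, evidence = ev),
            class = "threshold_estimate")
}

#' Recruitment (input-output) curve for one site and task state
#'
#' Aggregates per-participant MEP measures across stimulation intensity into
#' group means with 95% confidence intervals, converts intensities to
#' percent of each participant's resting motor threshold, and determines the
#' lowest intensity with significant MEPs. Significance at an intensity is a
#' one-sample t across participants on the post-minus-pre amplitude
#' contrast; the curve's `first_significant` is the lowest tested intensity
#' from which the contrast is significantly positive at that intensity *and
#' all higher tested intensities* (thresholds are reported "at and above"
#' an intensity), uncorrected across intensities.
#'
#' @param tab A [mep_table()] restricted or restrictable to one site/state;
#'   must carry `participant`, `intensity`, `amplitude_post`,
#'   `amplitude_pre` (and optionally `latency_ms`).
#' @param site,state Optional filters on `location` and `task` columns.
#' @param rmt Data frame with `participant` and `rmt` (resting motor
#'   threshold, percent MSO) used to express intensity in percent RMT;
#'   required when `intensity_unit = "mso"`.
#' @param intensity_unit `"mso"` when the table's `intensity` column is
#'   percent MSO (converted to percent RMT via `rmt`), `"pct_rmt"` when it
#'   already is percent RMT.
#' @param alpha Two-tailed significance level (default 0.05); the test is
#'   applied in the MEP direction, `t > qt(1 - alpha/2, df)`.
#' @return List of class `recruitment_curve`: `points` (per intensity: mean
#'   amplitude, 95% CI, mean percent RMT, mean latency, n, t), and
#'   `first_significant` / `first_significant_pct_rmt` (`NA` when none).
#' @export
build_curve <- function(tab, site = NULL, state = NULL, rmt = NULL,
                        intensity_unit = c("mso", "pct_rmt"),
                        alpha = 0.05) {
  intensity_unit <- match.arg(intensity_unit)
  if (!is.null(site)) tab <- tab[tab$location == site, , drop = FALSE]
  if (!is.null(state)) tab <- tab[tab$task == state, , drop = FALSE]
  if (!nrow(tab)) stopf("no rows for the requested site/state")
  ints <- sort(unique(tab$intensity))
  if (length(ints) < 2) stopf("need >= 2 intensities")
  if (intensity_unit == "pct_rmt") {
    tab$pct_rmt <- tab$intensity
  } else {
    if (is.null(rmt)) stopf("per-participant rmt table is required")
    if (!all(unique(tab$participant) %in% rmt$participant))
      stopf("missing RMT for some participants")
    pr <- rmt$rmt[match(tab$participant, rmt$participant)]
    tab$pct_rmt <- 100 * tab$intensity / pr
  }
  pts <- lapply(ints, function(i) {
    r <- tab[tab$intensity == i, , drop = FALSE]
    d <- r$amplitude_post - r$amplitude_pre
    nn <- length(d)
    se <- sd(d) / sqrt(nn)
    tt <- if (nn >= 2 && se > 0) mean(d) / se else NA_real_
    ci <- if (nn >= 2) qt(1 - alpha / 2, nn - 1) * se else NA_real_
    data.frame(intensity = i, mean_amplitude = mean(r$amplitude_post),
               mean_contrast = mean(d), ci_half = ci,
               mean_pct_rmt = mean(r$pct_rmt),
               mean_latency = mean(r$latency_ms, na.rm = TRUE),
               n = nn, n_latency = sum(!is.na(r$latency_ms)), t = tt)
  })
  pts <- do.call(rbind, pts)
  sig <- !is.na(pts$t) &
    pts$t > qt(1 - alpha / 2, pmax(pts$n - 1, 1))
  # lowest intensity from which all higher tested intensities are significant
  first <- NA_integer_
  run <- rev(cumall(rev(sig)))
  if (any(run)) first <- which(run)[1]
  structure(list(points = pts,
                 first_significant = if (is.na(first)) NA_real_ else
                   pts$intensity[first],
                 first_significant_pct_rmt = if (is.na(first)) NA_real_ else
                   pts$mean_pct_rmt[first],
                 alpha = alpha),
            class = "recruitment_curve")
}

cumall <- function(x) cumprod(as.logical(x)) > 0

#' Latency comparison at matched MEP amplitudes between two sites
#'
#' Selects the intensity pairs (one intensity per site) whose group-mean
#' amplitudes are most similar, among intensities where at least `min_n`
#' common participants have measurable latencies, then runs paired t tests
#' on amplitude and latency across the common participants. Overlapping
#' latencies at matched amplitudes are the signature of a single cortical
#' source.
#'
#' @param a,b Data frames for the two sites with columns `participant`,
#'   `intensity`, `amplitude` and `latency_ms`.
#' @param n_pairs Number of intensity pairs to return (default 2).
#' @param min_n Minimum common participants with latencies (default 10).
#' @return Data frame, one row per matched pair: the two intensities, mean
#'   amplitudes, paired t/p for amplitude and latency, and n.
#' @export
matched_amplitude_latency <- function(a, b, n_pairs = 2, min_n = 10) {
  usable <- function(d) {
    ok <- vapply(sort(unique(d$intensity)), function(i) {
      sum(!is.na(d$latency_ms[d$intensity == i])) >= min_n
    }, logical(1))
    sort(unique(d$intensity))[ok]
  }
  ia <- usable(a); ib <- usable(b)
  if (!length(ia) || !length(ib))
    stopf("no intensities with >= %d participants with latencies", min_n)
  grid <- expand.grid(ia = ia, ib = ib)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ra <- a[a$intensity == grid$ia[g], ]
    rb <- b[b$intensity == grid$ib[g], ]
    common <- intersect(ra$participant[!is.na(ra$latency_ms)],
                        rb$participant[!is.na(rb$latency_ms)])
    if (length(common) < min_n) return(NULL)
    ra <- ra[match(common, ra$participant), ]
    rb <- rb[match(common, rb$participant), ]
    # degenerate constant differences (e.g. identical curves) get a
    # defined limit instead of an error: t = 0/p = 1 when the constant is
    # zero, an infinite t with p = 0 otherwise
    zero_safe_t <- function(d) {
      if (sd(d) == 0) {
        if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1))
        return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1))
      }
      paired_t(d)
    }
    t_amp <- zero_safe_t(ra$amplitude - rb$amplitude)
    t_lat <- zero_safe_t(ra$latency_ms - rb$latency_ms)
    data.frame(intensity_a = grid$ia[g], intensity_b = grid$ib[g],
               mean_amp_a = mean(ra$amplitude),
               mean_amp_b = mean(rb$amplitude),
               amp_diff = abs(mean(ra$amplitude) - mean(rb$amplitude)),
               t_amplitude = t_amp$t, p_amplitude = t_amp$p,
               mean_lat_a = mean(ra$latency_ms),
               mean_lat_b = mean(rb$latency_ms),
               t_latency = t_lat$t, p_latency = t_lat$p,
               n = length(common))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stopf("no common participants at candidate intensities")
  rows <- rows[order(rows$amp_diff), , drop = FALSE]
  head(rows, n_pairs)
}
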