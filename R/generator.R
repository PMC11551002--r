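#' Configuration of the synthetic TMS-EMG experiment generator
#'
#' Bundles every tunable of the generative model of state-dependent
#' corticospinal excitability. The model is deliberately minimal: a scalar
#' stimulation "drive" (intensity scaled by Gaussian distance decay from the
#' scalp hotspot and by a von-Mises-shaped coil-orientation tuning factor)
#' passes through a sigmoidal recruitment nonlinearity whose threshold is
#' lower during dynamic, goal-directed movement than at rest or during
#' isotonic contraction. MEP onset latency shortens sigmoidally with the same
#' drive, between `latency_max_ms` at threshold drive and `latency_min_ms` at
#' saturation.
#'
#' @param sampling_rate Sampling rate in Hz (>= 1000).
#' @param hotspot_xy Hotspot scalp coordinates in mm, Cz-referenced
#'   (x lateral, negative = left; y anterior, negative = posterior). Default
#'   `c(-52, 5)`, the mean optimal first-dorsal-interosseus site 5.2 cm
#'   lateral and 0.5 cm anterior to the vertex.
#' @param sigma_space Spatial decay constant (mm) of effective stimulation.
#' @param theta_pref Preferred induced-current direction in degrees
#'   (0 = East toward the right preauricular point, 90 = North toward the
#'   nasion). Default 45 ("North-East"), the canonical M1-hand orientation.
#' @param kappa_orient Orientation-tuning concentration (unitless, >= 0);
#'   0 disables tuning.
#' @param rmt_drive Resting recruitment threshold on the drive scale. The
#'   drive scale is anchored to a percent-of-maximum-stimulator-output-like
#'   intensity axis, so 55 corresponds to a resting motor threshold of
#'   55 percent MSO at the hotspot with the preferred orientation.
#' @param active_threshold_ratio Ratio of the dynamic-movement threshold to
#'   the resting threshold (0 < ratio <= 1). Default 0.61, the observed mean
#'   active/resting threshold ratio during natural manual dexterity.
#' @param slope Sigmoid slope on the drive scale.
#' @param amp_max_mV Maximal mean MEP amplitude (mV).
#' @param latency_min_ms,latency_max_ms Latency bounds in ms (defaults 21.5
#'   and 25.5, the printed extremes of intensity-dependent MEP latencies).
#' @param latency_jitter_ms Gaussian SD of per-trial latency jitter (ms).
#' @param background_rms_mV Named numeric vector of task background EMG RMS
#'   in mV for `rest`, `isotonic` and `dynamic`.
#' @param burst_mod Amplitude-modulation depth of the dynamic-task background
#'   (0.5-3 Hz envelope), emulating movement bursts.
#' @param trial_noise_sigma Log-normal SD of multiplicative per-trial MEP
#'   amplitude variability.
#' @param hotspot_sd_mm Between-participant SD (mm, per axis) of the hotspot
#'   position used by [generate_experiment()].
#' @param rmt_sd Between-participant SD of `rmt_drive`.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [drive()], [mep_amplitude_and_latency()],
#'   [generate_continuous()], [generate_experiment()]
#' @export
generator_config <- function(sampling_rate = 5000,
                             hotspot_xy = c(-52, 5),
                             sigma_space = 40,
                             theta_pref = 45,
                             kappa_orient = 2,
                             rmt_drive = 55,
                             active_threshold_ratio = 0.61,
                             slope = 1.5,
                             amp_max_mV = 2,
                             latency_min_ms = 21.5,
                             latency_max_ms = 25.5,
                             latency_jitter_ms = 1,
                             background_rms_mV = c(rest = 0.005,
                                                   isotonic = 0.05,
                                                   dynamic = 0.1),
                             burst_mod = 0.5,
                             trial_noise_sigma = 0.5,
                             hotspot_sd_mm = 7,
                             rmt_sd = 5,
                             seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, hotspot_xy = hotspot_xy,
              sigma_space = sigma_space, theta_pref = theta_pref,
              kappa_orient = kappa_orient, rmt_drive = rmt_drive,
              active_threshold_ratio = active_threshold_ratio, slope = slope,
              amp_max_mV = amp_max_mV, latency_min_ms = latency_min_ms,
              latency_max_ms = latency_max_ms,
              latency_jitter_ms = latency_jitter_ms,
              background_rms_mV = background_rms_mV, burst_mod = burst_mod,
              trial_noise_sigma = trial_noise_sigma,
              hotspot_sd_mm = hotspot_sd_mm, rmt_sd = rmt_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$sampling_rate < 1000) stopf("sampling_rate must be >= 1000 Hz")
  if (length(cfg$hotspot_xy) != 2 || !all(is.finite(cfg$hotspot_xy)))
    stopf("hotspot_xy must be two finite coordinates (mm)")
  if (cfg$sigma_space <= 0) stopf("sigma_space must be > 0")
  if (cfg$kappa_orient < 0) stopf("kappa_orient must be >= 0")
  if (cfg$active_threshold_ratio <= 0 || cfg$active_threshold_ratio > 1)
    stopf("active_threshold_ratio must lie in (0, 1]")
  if (cfg$latency_min_ms >= cfg$latency_max_ms)
    stopf("latency_min_ms must be < latency_max_ms")
  tasks <- c("rest", "isotonic", "dynamic")
  if (!all(tasks %in% names(cfg$background_rms_mV)))
    stopf("background_rms_mV must name rest, isotonic and dynamic")
  if (any(cfg$background_rms_mV < 0))
    stopf("background RMS values must be >= 0")
  if (cfg$slope <= 0) stopf("slope must be > 0")
  invisible(cfg)
}

#' Stimulation drive at a coil position, orientation and intensity
#'
#' The drive is `intensity * exp(-d^2 / (2 sigma_space^2)) * tuning(theta)`
#' where `d` is the scalp distance from the coil to the hotspot and
#' `tuning(theta) = exp(kappa * (cos(theta - theta_pref) - 1))` is a
#' von-Mises-shaped factor in (0, 1], equal to 1 at the preferred direction.
#'
#' @param intensity Stimulation intensity on the percent-MSO-like scale
#'   (unitless, vectorised).
#' @param coil_xy Coil centre, Cz-referenced mm `c(x, y)`.
#' @param theta Induced-current direction, degrees.
#' @param config A [generator_config()].
#' @return Numeric drive value(s) on the intensity scale.
#' @export
drive <- function(intensity, coil_xy, theta, config) {
  d2 <- sum((coil_xy - config$hotspot_xy)^2)
  spatial <- exp(-d2 / (2 * config$sigma_space^2))
  tuning <- exp(config$kappa_orient *
                  (cos(deg2rad(theta - config$theta_pref)) - 1))
  intensity * spatial * tuning
}

# recruitment threshold on the drive scale for a task state
state_threshold <- function(task_state, config) {
  switch(task_state,
         rest = ,
         isotonic = config$rmt_drive,
         dynamic = config$rmt_drive * config$active_threshold_ratio,
         stopf("unknown task_state '%s'", task_state))
}

#' Noiseless mean MEP amplitude for a given drive and task state
#'
#' `amp_max_mV * sigmoid((drive - threshold) / slope)`, with the threshold at
#' `rmt_drive` for rest and isotonic contraction and at
#' `rmt_drive * active_threshold_ratio` during dynamic movement.
#'
#' @inheritParams drive
#' @param drive_value Drive value(s) from [drive()].
#' @param task_state One of `"rest"`, `"isotonic"`, `"dynamic"`.
#' @return Mean MEP amplitude(s) in mV.
#' @export
mean_mep_amplitude <- function(drive_value, task_state, config) {
  thr <- state_threshold(task_state, config)
  config$amp_max_mV * sigmoid((drive_value - thr) / config$slope)
}

#' Draw per-trial MEP amplitude and latency
#'
#' Trial amplitude is the noiseless mean ([mean_mep_amplitude()]) scaled by a
#' log-normal factor `exp(N(0, trial_noise_sigma))`; latency interpolates
#' sigmoidally from `latency_max_ms` near threshold down to `latency_min_ms`
#' at saturating drive, plus Gaussian jitter. Uses the current RNG stream.
#'
#' @inheritParams mean_mep_amplitude
#' @return A list with numeric vectors `amplitude_mV` and `latency_ms`
#'   (recycled to the length of `drive_value`).
#' @export
mep_amplitude_and_latency <- function(drive_value, task_state, config) {
  thr <- state_threshold(task_state, config)
  s <- sigmoid((drive_value - thr) / config$slope)
  n <- length(drive_value)
  amp <- config$amp_max_mV * s *
    rlnorm(n, meanlog = 0, sdlog = config$trial_noise_sigma)
  lat <- config$latency_max_ms -
    (config$latency_max_ms - config$latency_min_ms) * s +
    rnorm(n, 0, config$latency_jitter_ms)
  list(amplitude_mV = amp, latency_ms = lat)
}

#' Biphasic MEP waveform template
#'
#' A damped sinusoid (`sin(2 pi f t) exp(-t / tau)`, ~10 ms wide) sampled at
#' `sampling_rate` and scaled to unit peak-to-peak amplitude. Only its
#' peak-to-peak amplitude and onset are contractually meaningful; the shape
#' is a convenient stand-in for a real MEP waveform.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param freq_hz Oscillation frequency (Hz).
#' @param tau_ms Exponential decay constant (ms).
#' @param duration_ms Template support (ms).
#' @return Numeric vector starting at the MEP onset, unit peak-to-peak.
#' @export
mep_template <- function(sampling_rate, freq_hz = 120, tau_ms = 3,
                         duration_ms = 20) {
  t <- seq(0, duration_ms / 1000, by = 1 / sampling_rate)
  w <- sin(2 * pi * freq_hz * t) * exp(-t / (tau_ms / 1000))
  w / (max(w) - min(w))
}

# band-limited Gaussian background at a target RMS; dynamic task adds a slow
# (0.5-3 Hz) amplitude-modulation envelope mimicking movement bursts
background_noise <- function(n, task_state, config) {
  target <- unname(config$background_rms_mV[[task_state]])
  if (target <= 0) return(numeric(n))
  fs <- config$sampling_rate
  x <- rnorm(n)
  bf <- signal::butter(2, c(25, 250) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  if (task_state == "dynamic" && config$burst_mod > 0) {
    ef <- signal::butter(2, c(0.5, 3) / (fs / 2), type = "pass")
    env <- signal::filtfilt(ef, rnorm(n))
    env <- env / max(rms(env), .Machine$double.eps)
    x <- x * pmax(1 + config$burst_mod * env, 0.05)
  }
  x * target / max(rms(x), .Machine$double.eps)
}

#' Generate a continuous EMG record with TMS triggers and ground truth
#'
#' Builds task-state background EMG, places TMS triggers at a fixed
#' inter-trigger interval, and adds the MEP template at
#' `trigger + latency` with per-trial amplitude and latency drawn by
#' [mep_amplitude_and_latency()] from the drive implied by `intensity`,
#' `coil_xy` and `theta`. The record covers all triggers with a 300 ms
#' margin on each side.
#'
#' @inheritParams mean_mep_amplitude
#' @param task_state One of `"rest"`, `"isotonic"`, `"dynamic"`.
#' @param n_triggers Number of TMS pulses (>= 1).
#' @param inter_trigger_s Inter-trigger interval in seconds.
#' @param intensity Stimulation intensity (percent-MSO-like scale).
#' @param coil_xy Coil position (mm, Cz-referenced); default the hotspot.
#' @param theta Coil orientation (degrees); default the preferred direction.
#' @param channel Channel (muscle) label.
#' @param seed Optional integer seed. `NULL` (the default) draws from the
#'   current RNG stream so that callers such as [generate_experiment()] can
#'   manage reproducibility themselves; passing a seed makes the record
#'   bit-reproducible in isolation.
#' @return A list with `record` (a [continuous_record()]) and `ground_truth`
#'   (data frame: trigger id and time, true amplitude, latency and drive).
#' @export
generate_continuous <- function(task_state, n_triggers, inter_trigger_s = 0.5,
                                config = generator_config(),
                                intensity = 1.1 * config$rmt_drive,
                                coil_xy = config$hotspot_xy,
                                theta = config$theta_pref,
                                channel = "FDI_R", seed = NULL) {
  if (n_triggers < 1) stopf("n_triggers must be >= 1")
  state_threshold(task_state, config)  # validates task_state
  with_seed(seed, {
    fs <- config$sampling_rate
    margin_s <- 0.3
    trig <- margin_s + (seq_len(n_triggers) - 1) * inter_trigger_s
    n <- ceiling((max(trig) + margin_s) * fs) + 1
    x <- background_noise(n, task_state, config)
    drv <- drive(intensity, coil_xy, theta, config)
    tr <- mep_amplitude_and_latency(rep(drv, n_triggers), task_state, config)
    tmpl <- mep_template(fs)
    for (k in seq_len(n_triggers)) {
      i0 <- round((trig[k] + tr$latency_ms[k] / 1000) * fs) + 1
      idx <- i0:min(i0 + length(tmpl) - 1, n)
      x[idx] <- x[idx] + tr$amplitude_mV[k] * tmpl[seq_along(idx)]
    }
    gt <- data.frame(trigger = seq_len(n_triggers), trigger_s = trig,
                     amplitude_mV = tr$amplitude_mV,
                     latency_ms = tr$latency_ms, drive = drv)
    rec <- continuous_record(matrix(x, ncol = 1,
                                    dimnames = list(NULL, channel)),
                             sampling_rate = fs, trigger_s = trig)
    list(record = rec, ground_truth = gt)
  })
}

#' Generate a full factorial TMS mapping dataset with known ground truth
#'
#' Crosses participants, task states, scalp locations, coil orientations and
#' intensities; per participant the hotspot and resting threshold are
#' jittered around the configured values (`hotspot_sd_mm` per axis,
#' `rmt_sd`). One continuous record per cell is generated with
#' [generate_continuous()] and segmented into epochs, so the returned
#' dataset exercises the same path as recorded data. Each participant draws
#' from an RNG stream seeded at `config$seed + 10007 * participant_index`,
#' so per-participant data are reproducible in isolation.
#'
#' @param design A list with elements `participants` (count or vector of
#'   ids), `tasks`, `locations` (data frame with `id`, `x`, `y` in mm),
#'   `orientations` (degrees), `intensities` and `n_trials` per cell.
#' @param config A [generator_config()].
#' @param intensity_unit `"mso"` (default): intensities are absolute values
#'   on the percent-MSO-like drive scale; `"pct_rmt"`: intensities are
#'   percent of each simulated participant's resting threshold, as when
#'   stimulating every participant at e.g. 110 percent RMT. The epoch
#'   metadata records the requested value in the requested unit.
#' @param locations_relative When `TRUE`, `design$locations` coordinates
#'   are offsets (mm) from each simulated participant's own hotspot, as
#'   when sites are placed relative to the individually localized optimal
#'   M1-hand position; when `FALSE` (default) they are absolute
#'   Cz-referenced coordinates shared by all participants, as with a fixed
#'   grid.
#' @param inter_trigger_s Inter-trigger interval (s) inside each cell.
#' @return A list with `epochs` (an `epoch_set`, see [segment_epochs()]),
#'   `ground_truth` (per-trigger true amplitude/latency/drive with cell
#'   metadata) and `participants` (per-participant hotspot and threshold).
#' @export
generate_experiment <- function(design, config = generator_config(),
                                intensity_unit = c("mso", "pct_rmt"),
                                locations_relative = FALSE,
                                inter_trigger_s = 0.5) {
  intensity_unit <- match.arg(intensity_unit)
  stopifnot(is.list(design))
  req <- c("participants", "tasks", "locations", "intensities", "n_trials")
  miss <- setdiff(req, names(design))
  if (length(miss)) stopf("design lacks: %s", paste(miss, collapse = ", "))
  pid <- design$participants
  if (length(pid) == 1 && is.numeric(pid)) pid <- seq_len(pid)
  orients <- design$orientations %||% config$theta_pref
  locs <- design$locations
  if (!all(c("id", "x", "y") %in% names(locs)))
    stopf("design$locations needs columns id, x, y")
  if (!length(pid) || !length(design$tasks) || !nrow(locs) ||
      !length(design$intensities) || design$n_trials < 1)
    stopf("empty design")

  sets <- list(); gts <- list(); parts <- list()
  for (p_i in seq_along(pid)) {
    cfg_p <- config
    set.seed(config$seed + 10007L * p_i)
    cfg_p$hotspot_xy <- config$hotspot_xy + rnorm(2, 0, config$hotspot_sd_mm)
    cfg_p$rmt_drive <- max(config$rmt_drive + rnorm(1, 0, config$rmt_sd), 1)
    parts[[p_i]] <- data.frame(participant = pid[p_i],
                               hotspot_x = cfg_p$hotspot_xy[1],
                               hotspot_y = cfg_p$hotspot_xy[2],
                               rmt_drive = cfg_p$rmt_drive)
    cells <- expand.grid(task = design$tasks, loc_i = seq_len(nrow(locs)),
                         orientation = orients,
                         intensity = design$intensities,
                         stringsAsFactors = FALSE)
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      loc <- locs[cell$loc_i, ]
      int_abs <- if (intensity_unit == "pct_rmt") {
        cell$intensity * cfg_p$rmt_drive / 100
      } else cell$intensity
      coil <- if (locations_relative) {
        cfg_p$hotspot_xy + c(loc$x, loc$y)
      } else c(loc$x, loc$y)
      sim <- generate_continuous(cell$task, design$n_trials, inter_trigger_s,
                                 cfg_p, intensity = int_abs,
                                 coil_xy = coil,
                                 theta = cell$orientation)
      es <- segment_epochs(sim$record)
      es$meta$participant <- pid[p_i]
      es$meta$task <- cell$task
      es$meta$location <- loc$id
      es$meta$orientation <- cell$orientation
      es$meta$intensity <- cell$intensity
      sets[[length(sets) + 1L]] <- es
      gt <- sim$ground_truth
      gt$participant <- pid[p_i]; gt$task <- cell$task
      gt$location <- loc$id; gt$orientation <- cell$orientation
      gt$intensity <- cell$intensity
      gts[[length(gts) + 1L]] <- gt
    }
  }
  epochs <- bind_epoch_sets(sets)
  list(epochs = epochs,
       ground_truth = do.call(rbind, gts),
       participants = do.call(rbind, parts))
}
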