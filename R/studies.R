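# Self-contained simulation studies on generator data. Each study builds a
# factorial dataset with known ground truth, runs the same analysis path as
# recorded data, and returns the recovered quantities. They are used by the
# validation suite and by the analysis scripts; problem sizes default to the
# study conditions (12 participants, 10 trials per cell) with EMG simulated
# at 1 kHz, the lower bound of the supported sampling range, to keep
# replicated runs affordable.

#' Scalp-map recovery study: hotspot node and state-dependent map area
#'
#' Simulates a 27-location mapping session (rest and dynamic movement, 110
#' percent of each participant's resting threshold, preferred coil
#' orientation, grid centred on each participant's own hotspot as with the
#' individually positioned cloth map), quantifies MEPs, and builds the post-
#' vs pre-TMS t map per
#' task state. Recovers (a) the grid node with the largest group-mean
#' resting MEP — which should be the node nearest the true hotspot — and
#' (b) the thresholded map areas, whose rest vs movement ordering reflects
#' the lower corticospinal threshold during natural movement.
#'
#' @param seed Integer seed.
#' @param n_participants,n_trials Study size (defaults 12 and 10).
#' @param sampling_rate Hz (default 1000).
#' @param t_crit Map significance threshold (default 2.20).
#' @return List: `hotspot_id`, `center_id`, `hotspot_recovered`,
#'   `area_rest`, `area_dynamic`, `tmap_rest`, `tmap_dynamic`.
#' @export
study_map_recovery <- function(seed, n_participants = 12, n_trials = 10,
                               sampling_rate = 1000, t_crit = 2.20) {
  cfg <- generator_config(sampling_rate = sampling_rate, seed = seed)
  layout <- make_layout("grid27", params = list(center = c(0, 0)))
  design <- list(participants = n_participants,
                 tasks = c("rest", "dynamic"), locations = layout,
                 orientations = cfg$theta_pref, intensities = 110,
                 n_trials = n_trials)
  exp <- generate_experiment(design, cfg, intensity_unit = "pct_rmt",
                             locations_relative = TRUE)
  tab <- mep_table(exp$epochs, latency = FALSE)
  tab <- normalize_meps(tab, "participant_muscle")
  rest <- tab[tab$task == "rest", ]
  by_loc <- tapply(rest$amplitude_norm, rest$location, mean)
  hotspot_id <- names(by_loc)[which.max(by_loc)]
  tm_rest <- scalp_tmap(rest, layout, t_crit = t_crit)
  tm_dyn <- scalp_tmap(tab[tab$task == "dynamic", ], layout,
                       t_crit = t_crit)
  list(hotspot_id = hotspot_id, center_id = attr(layout, "center_id"),
       hotspot_recovered = hotspot_id == attr(layout, "center_id"),
       area_rest = tm_rest$area, area_dynamic = tm_dyn$area,
       tmap_rest = tm_rest, tmap_dynamic = tm_dyn)
}

#' Orientation-preference recovery study
#'
#' Simulates stimulation at the hotspot under the dynamic movement task
#' across 8 coil orientations, computes per-participant baseline-corrected
#' orientation preferences from per-condition-normalized amplitudes, and
#' summarises the group: the circular mean of the preferred angles should
#' recover the configured preferred current direction, and the group-mean
#' corrected resultant length should be significantly positive.
#'
#' @inheritParams study_map_recovery
#' @return List: `preferences` (per participant), `group_angle` (circular
#'   mean, degrees), `mean_corrected_length`, `t_corrected` (one-sample t
#'   of corrected length vs 0), `p_corrected`.
#' @export
study_orientation_recovery <- function(seed, n_participants = 12,
                                       n_trials = 10,
                                       sampling_rate = 1000) {
  cfg <- generator_config(sampling_rate = sampling_rate, seed = seed)
  angles <- seq(0, 315, by = 45)
  design <- list(participants = n_participants, tasks = "dynamic",
                 locations = data.frame(id = "hotspot", x = 0, y = 0),
                 orientations = angles, intensities = 110,
                 n_trials = n_trials)
  exp <- generate_experiment(design, cfg, intensity_unit = "pct_rmt",
                             locations_relative = TRUE)
  tab <- mep_table(exp$epochs, latency = FALSE)
  tab <- normalize_meps(tab, "participant_muscle_condition")
  prefs <- lapply(split(tab, tab$participant), function(p) {
    p <- p[order(p$orientation), ]
    baseline_corrected_preference(p$orientation, p$amplitude_norm,
                                  p$amplitude_pre_norm)
  })
  ang <- vapply(prefs, `[[`, 1, "preferred_angle")
  corr <- vapply(prefs, `[[`, 1, "corrected_length")
  grp <- wrap360(rad2deg(atan2(mean(sin(deg2rad(ang))),
                               mean(cos(deg2rad(ang))))))
  tt <- paired_t(corr)
  list(preferences = prefs, group_angle = grp,
       mean_corrected_length = mean(corr), t_corrected = tt$t,
       p_corrected = tt$p)
}

#' Motor-threshold recovery study (resting vs movement thresholds)
#'
#' Simulates a fixed intensity ladder at the hotspot at rest and during
#' dynamic movement, estimates each participant's resting threshold with
#' the 5-of-10 rule and the movement threshold with the count-or-average
#' rule, and returns the active/resting threshold ratio, whose configured
#' value is `active_threshold_ratio` (0.61). Threshold rules are fed
#' background-corrected amplitudes (post minus pre peak-to-peak), since
#' during movement raw post-window peak-to-peak reflects background EMG.
#'
#' @inheritParams study_map_recovery
#' @param intensities Intensity ladder, percent-MSO scale.
#' @return List: `per_participant` (rmt, amt, ratio), `mean_ratio`,
#'   `mean_rmt`, `mean_amt`.
#' @export
study_threshold_recovery <- function(seed, n_participants = 12,
                                     n_trials = 10,
                                     intensities = seq(20, 75, by = 5),
                                     sampling_rate = 1000) {
  cfg <- generator_config(sampling_rate = sampling_rate, seed = seed)
  design <- list(participants = n_participants,
                 tasks = c("rest", "dynamic"),
                 locations = data.frame(id = "hotspot", x = 0, y = 0),
                 orientations = cfg$theta_pref, intensities = intensities,
                 n_trials = n_trials)
  exp <- generate_experiment(design, cfg, locations_relative = TRUE)
  trials <- mep_trial_measures(exp$epochs)
  avg <- mep_table(exp$epochs, latency = FALSE)
  avg$amplitude_corrected <- pmax(avg$amplitude_post - avg$amplitude_pre, 0)
  per <- lapply(split(seq_len(nrow(trials)), trials$participant),
                function(idx) {
    tr <- trials[idx, ]
    rest <- data.frame(intensity = tr$intensity[tr$task == "rest"],
                       amplitude_mV = tr$amplitude_corrected[tr$task ==
                                                               "rest"])
    dyn <- data.frame(intensity = tr$intensity[tr$task == "dynamic"],
                      amplitude_mV = tr$amplitude_corrected[tr$task ==
                                                              "dynamic"])
    av <- avg[avg$participant == tr$participant[1] & avg$task == "dynamic", ]
    rmt <- rmt_rossini(rest)$value
    amt <- amt_pegboard(data.frame(intensity = av$intensity,
                                   amplitude_mV = av$amplitude_corrected),
                        dyn)$value
    data.frame(participant = tr$participant[1], rmt = rmt, amt = amt,
               ratio = amt / rmt)
  })
  per <- do.call(rbind, per)
  list(per_participant = per,
       mean_ratio = mean(per$ratio, na.rm = TRUE),
       mean_rmt = mean(per$rmt, na.rm = TRUE),
       mean_amt = mean(per$amt, na.rm = TRUE))
}

#' Recruitment-curve study at the hotspot and at a distant site
#'
#' Builds recruitment curves over a percent-RMT intensity ladder for a
#' stimulation site, task state and seed, and reports the lowest intensity
#' with significant MEPs ("at and above" rule). At the hotspot the onset
#' during movement falls near the configured active/resting threshold ratio
#' (61 percent RMT); at a site 55 mm away at rest no intensity up to 160
#' percent RMT is expected to reach significance.
#'
#' @inheritParams study_map_recovery
#' @param site_offset_mm Offset of the stimulated site from the hotspot
#'   (default `c(0, 0)`).
#' @param task Task state.
#' @param intensities Ladder in percent RMT.
#' @return The [build_curve()] result.
#' @export
study_recruitment <- function(seed, site_offset_mm = c(0, 0),
                              task = "dynamic",
                              intensities = seq(40, 160, by = 20),
                              n_participants = 12, n_trials = 10,
                              sampling_rate = 1000) {
  cfg <- generator_config(sampling_rate = sampling_rate, seed = seed)
  design <- list(participants = n_participants, tasks = task,
                 locations = data.frame(id = "site",
                                        x = site_offset_mm[1],
                                        y = site_offset_mm[2]),
                 orientations = cfg$theta_pref, intensities = intensities,
                 n_trials = n_trials)
  exp <- generate_experiment(design, cfg, intensity_unit = "pct_rmt",
                             locations_relative = TRUE)
  tab <- mep_table(exp$epochs)
  build_curve(tab, intensity_unit = "pct_rmt")
}

#' Matched-amplitude latency study across two sites
#'
#' Simulates recruitment curves during movement over the hotspot and over a
#' site 55 mm away (the supramarginal-gyrus analogue), with intensity
#' ladders chosen so the amplitude ranges overlap, then compares MEP
#' latencies at the intensity pairs with the most similar group-mean
#' amplitudes. Onsets use the self-scaling fraction-of-peak mode of
#' [auto_latency()], whose bias is amplitude-independent and therefore
#' cancels in the cross-site comparison. Under the generator's
#' single-source model the latency difference is null; `latency_shift_ms`
#' adds a latency offset at the distant site to emulate a second, slower
#' source.
#'
#' @inheritParams study_map_recovery
#' @param latency_shift_ms Latency offset (ms) added at the distant site.
#' @param intensities_a,intensities_b Percent-RMT ladders for hotspot and
#'   distant site.
#' @param min_n Minimum participants with latencies per intensity.
#' @return The [matched_amplitude_latency()] table.
#' @export
study_matched_latency <- function(seed, latency_shift_ms = 0,
                                  intensities_a = seq(55, 115, by = 5),
                                  intensities_b = seq(105, 165, by = 5),
                                  n_participants = 12, n_trials = 10,
                                  min_n = 10, sampling_rate = 1000) {
  cfg <- generator_config(sampling_rate = sampling_rate, seed = seed)
  site_tab <- function(offset, ints, cfg_site, id) {
    design <- list(participants = n_participants, tasks = "dynamic",
                   locations = data.frame(id = id, x = offset[1],
                                          y = offset[2]),
                   orientations = cfg$theta_pref, intensities = ints,
                   n_trials = n_trials)
    exp <- generate_experiment(design, cfg_site,
                               intensity_unit = "pct_rmt",
                               locations_relative = TRUE)
    mep_table(exp$epochs, latency_mode = "fraction_of_peak")
  }
  cfg_b <- cfg
  cfg_b$seed <- cfg$seed + 500000L
  cfg_b$latency_min_ms <- cfg$latency_min_ms + latency_shift_ms
  cfg_b$latency_max_ms <- cfg$latency_max_ms + latency_shift_ms
  ta <- site_tab(c(0, 0), intensities_a, cfg, "hotspot")
  tb <- site_tab(c(-39, -39), intensities_b, cfg_b, "distant")
  both <- rbind(ta, tb)
  both <- normalize_meps(both, "participant_muscle")
  mk <- function(t, loc) data.frame(participant = t$participant[t$location
                                                                == loc],
                                    intensity = t$intensity[t$location ==
                                                              loc],
                                    amplitude = t$amplitude_norm[t$location
                                                                 == loc],
                                    latency_ms = t$latency_ms[t$location ==
                                                                loc])
  matched_amplitude_latency(mk(both, "hotspot"), mk(both, "distant"),
                            min_n = min_n)
}

#' Electric-field threshold knee recovery on synthetic data
#'
#' Builds a synthetic field-vs-MEP table in which MEP amplitude follows
#' `max(0, field - knee)` plus Gaussian noise, runs the threshold sweep and
#' returns the recovered best threshold, which should land near the knee.
#'
#' @param seed Integer seed.
#' @param knee_vpm Knee of the piecewise-linear relation (V/m, default 30).
#' @param n_points Number of location/orientation pairs (default 108, as
#'   27 locations by 4 orientations).
#' @param noise_sd Noise SD on the MEP scale (default 0.02).
#' @return The [efield_threshold_sweep()] result plus `knee_vpm`.
#' @export
study_efield_knee <- function(seed, knee_vpm = 30, n_points = 108,
                              noise_sd = 0.02) {
  with_seed(seed, {
    field <- stats::runif(n_points, 0, 79)
    mep <- pmax(0, field - knee_vpm) / 49 + rnorm(n_points, 0, noise_sd)
    sw <- suppressWarnings(
      efield_threshold_sweep(data.frame(field_vpm = field, mep = mep)))
    sw$knee_vpm <- knee_vpm
    sw
  })
}
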