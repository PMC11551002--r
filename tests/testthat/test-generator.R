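test_that("drive has its closed-form values at the hotspot and at 2 sigma", {
  cfg <- quick_cfg()
  expect_equal(drive(50, cfg$hotspot_xy, cfg$theta_pref, cfg), 50)
  away <- cfg$hotspot_xy + c(2 * cfg$sigma_space, 0)
  expect_equal(drive(50, away, cfg$theta_pref, cfg), 50 * exp(-2))
})

test_that("drive decays monotonically with distance from the hotspot", {
  cfg <- quick_cfg()
  d <- seq(0, 120, length.out = 100)
  vals <- vapply(d, function(r)
    drive(60, cfg$hotspot_xy + c(r, 0), cfg$theta_pref, cfg), 1)
  expect_true(all(diff(vals) <= 0))
})

test_that("orientation tuning peaks at the preferred direction", {
  cfg <- quick_cfg()
  at_pref <- drive(60, cfg$hotspot_xy, cfg$theta_pref, cfg)
  others <- vapply(seq(0, 315, 45), function(th)
    drive(60, cfg$hotspot_xy, th, cfg), 1)
  expect_equal(max(others), at_pref)
  expect_true(all(others > 0 & others <= at_pref))
})

test_that("amplitude follows the state-dependent sigmoid limits", {
  cfg <- quick_cfg()
  expect_lt(mean_mep_amplitude(0, "rest", cfg), 0.01 * cfg$amp_max_mV)
  expect_equal(mean_mep_amplitude(1e4, "rest", cfg), cfg$amp_max_mV)
  set.seed(1)
  hi <- mep_amplitude_and_latency(rep(1e4, 500), "dynamic", cfg)
  expect_equal(mean(hi$latency_ms), cfg$latency_min_ms,
               tolerance = 0.01)
  expect_error(mep_amplitude_and_latency(10, "jumping", cfg),
               "task_state")
})

test_that("movement lowers the 50 uV crossing intensity by roughly the
           configured threshold ratio", {
  cfg <- quick_cfg()
  crossing <- function(task) {
    uniroot(function(i) {
      mean_mep_amplitude(drive(i, cfg$hotspot_xy, cfg$theta_pref, cfg),
                         task, cfg) - 0.05
    }, c(1, 200))$root
  }
  ratio <- crossing("dynamic") / crossing("rest")
  expect_equal(ratio, cfg$active_threshold_ratio, tolerance = 0.12)
})

test_that("continuous records are reproducible and cover the triggers", {
  cfg <- quick_cfg()
  a <- generate_continuous("rest", 3, 0.5, cfg, seed = 42)
  b <- generate_continuous("rest", 3, 0.5, cfg, seed = 42)
  expect_identical(a, b)
  dur <- (nrow(a$record$samples) - 1) / cfg$sampling_rate
  expect_gte(dur, max(a$record$trigger_s) + 0.3)
  expect_equal(nrow(a$ground_truth), 3)
  expect_true(all(a$ground_truth$amplitude_mV >= 0))
})

test_that("zero background and zero drive give a flat record", {
  cfg <- quick_cfg(background_rms_mV = c(rest = 0, isotonic = 0.05,
                                         dynamic = 0.1))
  sim <- generate_continuous("rest", 2, 0.5, cfg, intensity = 0, seed = 1)
  # zero drive leaves only the deep sigmoid tail (~1e-16 of amp_max)
  expect_lt(max(abs(sim$record$samples)), 1e-12)
})

test_that("background RMS matches the configured task level over 60 s", {
  cfg <- quick_cfg()
  sim <- generate_continuous("rest", 119, 0.5, cfg, intensity = 0,
                             seed = 3)
  measured <- sqrt(mean(sim$record$samples^2))
  expect_equal(measured, cfg$background_rms_mV[["rest"]],
               tolerance = 0.05)
})

test_that("factorial datasets have one epoch per design cell and trial", {
  cfg <- quick_cfg()
  locs <- data.frame(id = c("a", "b"), x = c(0, 10), y = c(0, -10))
  design <- list(participants = 2, tasks = c("rest", "dynamic"),
                 locations = locs, orientations = c(45, 135),
                 intensities = c(40, 60), n_trials = 3)
  exp <- generate_experiment(design, cfg)
  expect_equal(nrow(exp$epochs$data), 2 * 2 * 2 * 2 * 2 * 3)
  expect_equal(nrow(exp$ground_truth), nrow(exp$epochs$data))
  # identical seed, identical dataset
  exp2 <- generate_experiment(design, cfg)
  expect_identical(exp$epochs$data, exp2$epochs$data)
  expect_error(generate_experiment(list(participants = 0, tasks = "rest",
                                        locations = locs,
                                        intensities = 50, n_trials = 1),
                                   cfg), "empty")
})

test_that("zero intensity produces near-zero true amplitudes", {
  cfg <- quick_cfg()
  design <- list(participants = 2, tasks = "rest",
                 locations = data.frame(id = "a", x = 0, y = 0),
                 intensities = 0, n_trials = 5)
  exp <- generate_experiment(design, cfg)
  expect_lt(max(exp$ground_truth$amplitude_mV), 1e-6)
})

test_that("noiseless mean amplitude is monotone in intensity", {
  cfg <- quick_cfg()
  for (task in c("rest", "isotonic", "dynamic")) {
    amps <- mean_mep_amplitude(
      drive(seq(10, 100, 5), cfg$hotspot_xy, cfg$theta_pref, cfg),
      task, cfg)
    expect_true(all(diff(amps) >= 0))
  }
})

test_that("far locations are silent at rest at 110% resting threshold", {
  cfg <- quick_cfg()
  r <- 55 + 2 * cfg$sigma_space
  for (ang in seq(0, 300, 60)) {
    xy <- cfg$hotspot_xy + r * c(cos(ang * pi / 180), sin(ang * pi / 180))
    amp <- mean_mep_amplitude(
      drive(1.1 * cfg$rmt_drive, xy, cfg$theta_pref, cfg), "rest", cfg)
    expect_lt(amp, 0.05)
  }
})
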