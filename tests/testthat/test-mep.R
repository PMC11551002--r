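test_that("peak-to-peak measures the window extrema and ignores offsets", {
  tm <- seq(-200, 200)
  tr <- numeric(401)
  expect_equal(peak_to_peak(tr, tm), 0)
  tr[tm == 20] <- 1.0
  tr[tm == 25] <- -0.5
  expect_equal(peak_to_peak(tr, tm), 1.5)
  expect_equal(peak_to_peak(tr + 3.7, tm), 1.5)
  expect_error(peak_to_peak(tr, tm, c(300, 310)), "no samples")
})

test_that("an injected template of known p2p is recovered on a zero
           background", {
  fs <- 1000
  cfg <- quick_cfg(background_rms_mV = c(rest = 0, isotonic = 0.05,
                                         dynamic = 0.1),
                   trial_noise_sigma = 1e-9, latency_jitter_ms = 0)
  sim <- generate_continuous("rest", 1, 0.5, cfg, intensity = 1e4,
                             seed = 1)
  es <- segment_epochs(sim$record)
  p2p <- peak_to_peak(es$data[1, ], es$time_ms)
  expect_equal(p2p, cfg$amp_max_mV, tolerance = 0.02)
})

test_that("crossing counts contrast a real MEP against its pre-TMS
           control window", {
  tm <- seq(-200, 200)
  flat <- numeric(401)
  res <- crossing_count_contrast(flat, tm)
  expect_equal(res$n_post, 0)
  expect_equal(res$n_pre, 0)
  expect_equal(res$n_window[["post"]], res$n_window[["pre"]])
  set.seed(5)
  tr <- rnorm(401, sd = 0.01)
  tr[tm >= 20 & tm <= 30] <- tr[tm >= 20 & tm <= 30] + 1
  res2 <- crossing_count_contrast(tr, tm)
  expect_gt(res2$n_post, res2$n_pre)
})

test_that("crossing counts are symmetric under the stationary-noise null", {
  set.seed(21)
  diffs <- replicate(1000, {
    r <- crossing_count_contrast(rnorm(401), seq(-200, 200))
    r$n_post - r$n_pre
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 1e-9)
})

test_that("a degenerate zero-SD baseline still yields defined counts", {
  tm <- seq(-200, 200)
  tr <- numeric(401)
  tr[tm >= 10 & tm <= 50] <- 1
  res <- crossing_count_contrast(tr, tm)
  expect_equal(res$ci, c(0, 0))
  expect_gt(res$n_post, 0)
  expect_equal(res$n_pre, 0)
})

test_that("normalization rescales to the scope maximum and is idempotent", {
  tab <- make_mep_tab(participant = c(1, 1), location = c("a", "b"),
                      post = c(2, 4), pre = c(0.2, 0.4))
  norm <- normalize_meps(tab)
  expect_equal(norm$amplitude_norm, c(0.5, 1.0))
  expect_equal(norm$amplitude_pre_norm, c(0.05, 0.1))
  expect_equal(normalize_meps(norm)$amplitude_norm, norm$amplitude_norm)
  single <- normalize_meps(make_mep_tab(1, "a", 0.8, 0.1))
  expect_equal(single$amplitude_norm, 1.0)
  expect_error(normalize_meps(make_mep_tab(1, "a", 0, 0)), "all-zero")
})

test_that("per-condition scope can promote a condition-local maximum to
           1 that stays below 1 under the participant-wide scope", {
  tab <- rbind(make_mep_tab(1, c("a", "b"), post = c(1, 2),
                            pre = c(0, 0), task = "rest"),
               make_mep_tab(1, c("a", "b"), post = c(3, 4),
                            pre = c(0, 0), task = "dynamic"))
  class(tab) <- c("mep_table", "data.frame")
  overall <- normalize_meps(tab, "participant_muscle")
  percond <- normalize_meps(tab, "participant_muscle_condition")
  rest_b <- tab$task == "rest" & tab$location == "b"
  expect_equal(percond$amplitude_norm[rest_b], 1.0)
  expect_lt(overall$amplitude_norm[rest_b], 1.0)
})

test_that("automatic latency finds a high-SNR onset near its true time and
           is absent on flat traces", {
  tm <- seq(-200, 200)
  expect_true(is.na(auto_latency(numeric(401), tm)))
  set.seed(9)
  mk <- function(amp) {
    tr <- rnorm(401, sd = 0.005)
    onset <- which(tm == 21)
    wave <- amp * sin(2 * pi * 0.12 * (0:80)) * exp(-(0:80) / 30)
    tr[onset:(onset + 80)] <- tr[onset:(onset + 80)] + wave
    tr
  }
  lat <- auto_latency(mk(1), tm)
  expect_true(abs(lat - 21) <= 0.5)
})

test_that("doubling the template amplitude never delays the detected
           onset", {
  tm <- seq(-200, 200)
  set.seed(13)
  noise <- rnorm(401, sd = 0.02)
  mk <- function(amp) {
    tr <- noise
    onset <- which(tm == 21)
    wave <- amp * sin(2 * pi * 0.12 * (0:80)) * exp(-(0:80) / 30)
    tr[onset:(onset + 80)] <- tr[onset:(onset + 80)] + wave
    tr
  }
  l1 <- auto_latency(mk(0.5), tm)
  l2 <- auto_latency(mk(1.0), tm)
  expect_lte(l2, l1)
})

test_that("fraction-of-peak onsets require a detectable MEP first", {
  tm <- seq(-200, 200)
  set.seed(2)
  expect_true(is.na(auto_latency(rnorm(401), tm,
                                 mode = "fraction_of_peak")))
})

test_that("averaged pure-noise amplitude falls with the number of trials", {
  set.seed(31)
  p2p_for <- function(n) {
    mean(replicate(40, {
      avg <- colMeans(matrix(rnorm(n * 401, sd = 0.1), nrow = n))
      peak_to_peak(avg, seq(-200, 200))
    }))
  }
  a10 <- p2p_for(10); a40 <- p2p_for(40)
  expect_equal(a10 / a40, 2, tolerance = 0.35)  # sqrt(40/10) = 2
})
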