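ladder_trials <- function(counts, n = 10, crit_mv = 0.05) {
  # counts: named vector intensity -> number of supra-criterion trials
  do.call(rbind, lapply(names(counts), function(i) {
    k <- counts[[i]]
    data.frame(intensity = as.numeric(i),
               amplitude_mV = c(rep(crit_mv * 2, k),
                                rep(crit_mv / 2, n - k)))
  }))
}

test_that("the resting threshold rule picks the lowest intensity with 5 of
           10 supra-criterion trials", {
  est <- rmt_rossini(ladder_trials(c(`40` = 2, `45` = 5, `50` = 9)))
  expect_equal(est$value, 45)
  zero <- rmt_rossini(data.frame(intensity = rep(c(40, 50), each = 10),
                                 amplitude_mV = 0))
  expect_true(is.na(zero$value))
  expect_warning(
    short <- rmt_rossini(rbind(ladder_trials(c(`50` = 9)),
                               data.frame(intensity = 45,
                                          amplitude_mV = rep(1, 5)))),
    "skipped")
  expect_equal(short$value, 50)
})

test_that("the persistent rule ignores isolated sub-threshold crossings", {
  spurious <- ladder_trials(c(`20` = 6, `25` = 1, `30` = 7, `35` = 9))
  expect_equal(rmt_rossini(spurious)$value, 30)
  expect_equal(rmt_rossini(spurious, persistent = FALSE)$value, 20)
})

test_that("raising the amplitude criterion never lowers the threshold", {
  set.seed(23)
  for (i in 1:20) {
    tr <- data.frame(intensity = rep(seq(40, 60, 5), each = 10),
                     amplitude_mV = rlnorm(50, log(0.04), 1))
    vals <- vapply(c(25, 50, 100, 200), function(cu) {
      v <- rmt_rossini(tr, criterion_uv = cu)$value
      if (is.na(v)) 999 else v  # absent counts as above any ladder value
    }, 1)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("the movement threshold rule accepts either the count or the
           average clause", {
  few <- ladder_trials(c(`30` = 2, `35` = 3))
  avg <- data.frame(intensity = c(30, 35), amplitude_mV = c(0.02, 0.08))
  expect_equal(amt_pegboard(avg, few)$value, 35)
  count6 <- ladder_trials(c(`30` = 6, `35` = 7))
  avg_low <- data.frame(intensity = c(30, 35),
                        amplitude_mV = c(0.04, 0.04))
  expect_equal(amt_pegboard(avg_low, count6)$value, 30)
})

test_that("recruitment curves report group means and a persistent
           significance onset", {
  set.seed(41)
  ints <- seq(100, 150, 10)
  tab <- expand.grid(participant = 1:12, intensity = ints)
  tab$location <- "site"; tab$task <- "dynamic"
  slope <- pmax(tab$intensity - 115, 0) / 40
  tab$amplitude_post <- 0.1 + slope + rnorm(nrow(tab), sd = 0.03)
  tab$amplitude_pre <- 0.1 + rnorm(nrow(tab), sd = 0.03)
  tab$latency_ms <- 24 - slope
  cv <- build_curve(tab, intensity_unit = "pct_rmt")
  expect_equal(cv$points$intensity, ints)
  expect_equal(cv$points$n, rep(12, 6))
  expect_false(is.na(cv$first_significant))
  expect_gte(cv$first_significant, 120)
  # strictly increasing amplitudes give strictly increasing means
  mono <- tab
  mono$amplitude_post <- tab$intensity / 100 + tab$participant / 100
  cvm <- build_curve(mono, intensity_unit = "pct_rmt")
  expect_true(all(diff(cvm$points$mean_amplitude) > 0))
  # all-zero amplitudes: no significant intensity
  null <- tab
  null$amplitude_post <- 0; null$amplitude_pre <- 0
  cvn <- build_curve(null, intensity_unit = "pct_rmt")
  expect_true(is.na(cvn$first_significant))
  expect_error(build_curve(tab), "rmt")
})

test_that("percent RMT conversion uses the per-participant threshold", {
  tab <- expand.grid(participant = 1:2, intensity = c(50, 60))
  tab$amplitude_post <- c(0.1, 0.2, 0.6, 0.7)
  tab$amplitude_pre <- 0.01
  tab$latency_ms <- NA
  rmt <- data.frame(participant = 1:2, rmt = c(50, 40))
  cv <- build_curve(tab, rmt = rmt)
  expect_equal(cv$points$mean_pct_rmt,
               c(mean(c(100, 125)), mean(c(120, 150))))
})

test_that("identical curves match at equal intensities with a null latency
           difference", {
  set.seed(2)
  a <- expand.grid(participant = 1:12, intensity = seq(60, 100, 10))
  a$amplitude <- a$intensity / 100 + a$participant / 50
  a$latency_ms <- 24 - a$intensity / 100
  ml <- matched_amplitude_latency(a, a)
  expect_equal(ml$intensity_a, ml$intensity_b)
  expect_equal(ml$t_latency, c(0, 0))
  expect_equal(ml$p_latency, c(1, 1))
  expect_equal(ml$amp_diff, c(0, 0))
  b <- a; b$latency_ms <- NA
  expect_error(matched_amplitude_latency(a, b), "latencies")
})
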