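test_that("MNI and scalp distances are Euclidean and symmetric", {
  expect_equal(mni_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(mni_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(scalp_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(scalp_distance(c(0, 0), c(33, -35)), sqrt(33^2 + 35^2))
  set.seed(19)
  for (i in 1:100) {
    a <- rnorm(2, sd = 40); b <- rnorm(2, sd = 40)
    expect_equal(scalp_distance(a, b), scalp_distance(b, a))
  }
})

test_that("the M1 to SMG distance matches the published MNI coordinates to
           the nearest mm", {
  d <- mni_distance(c(-38, -15, 58), c(-57, -44, 44))
  expect_equal(round(d), 37)
})

test_that("proximity screening flags targets within the motor-confound
           cutoffs and sorts by distance", {
  targets <- data.frame(
    label = c("at_m1", "smg", "far", "scalp_near"),
    mni_x = c(-38, -57, -38, NA), mni_y = c(-15, -44, 65, NA),
    mni_z = c(58, 44, 58, NA),
    scalp_x = c(NA, NA, NA, -20), scalp_y = c(NA, NA, NA, 5))
  rep <- proximity_screen(targets)
  expect_equal(rep$distance_mm[1], 0)
  expect_true(rep$flagged[rep$label == "at_m1"])
  expect_true(rep$flagged[rep$label == "smg"])       # 37 <= 42
  expect_false(rep$flagged[rep$label == "far"])      # 80 mm away
  expect_true(rep$flagged[rep$label == "scalp_near"])  # 32 <= 55
  expect_true(all(diff(rep$distance_mm) >= 0))
  # flags are monotone in the cutoff
  loose <- proximity_screen(targets, brain_cutoff_mm = 100,
                            scalp_cutoff_mm = 100)
  expect_true(all(loose$flagged[match(rep$label, loose$label)] |
                    !rep$flagged))
  expect_error(proximity_screen(data.frame(label = "none")), "neither")
})

test_that("a linear field-MEP relation yields correlation 1 at threshold
           0", {
  ft <- data.frame(field_vpm = seq(5, 60, 5), mep = seq(5, 60, 5) / 60)
  sw <- efield_threshold_sweep(ft)
  expect_equal(sw$best_threshold, 0)
  expect_equal(sw$best_correlation, 1)
  # thresholds leaving < 3 pairs are absent from the profile
  expect_false(any(sw$profile$threshold > 50))
  expect_true(all(sw$profile$n >= 3))
})

test_that("the sweep profile is invariant to affine rescaling of MEPs", {
  set.seed(27)
  ft <- data.frame(field_vpm = runif(40, 0, 79), mep = rnorm(40))
  a <- suppressWarnings(efield_threshold_sweep(ft))
  ft2 <- ft; ft2$mep <- 5 * ft$mep + 2
  b <- suppressWarnings(efield_threshold_sweep(ft2))
  expect_equal(a$profile$r, b$profile$r, tolerance = 1e-12)
  expect_equal(a$best_threshold, b$best_threshold)
})

test_that("the synthetic knee is recovered by the sweep", {
  # the median over a few seeds is used because max-r selection has a
  # known heavy tail from tiny high-threshold subsets
  best <- vapply(1:5, function(s) study_efield_knee(s)$best_threshold, 1)
  expect_lte(abs(median(best) - 30), 3)
})

test_that("the IDW volume matches a brute-force per-voxel oracle", {
  set.seed(33)
  locs <- matrix(runif(15, 0, 50), ncol = 3)
  mep <- runif(5)
  grid <- list(x = seq(2.5, 47.5, 5), y = seq(2.5, 47.5, 5),
               z = seq(2.5, 47.5, 5))
  vol <- idw_volume(locs, mep, grid, threshold = FALSE, rescale = FALSE)
  # independent loop oracle
  for (trial in 1:50) {
    i <- sample(10, 1); j <- sample(10, 1); k <- sample(10, 1)
    v <- c(grid$x[i], grid$y[j], grid$z[k])
    d <- sqrt(rowSums((locs - matrix(v, 5, 3, byrow = TRUE))^2))
    w <- (1 / d) / sum(1 / d)
    expect_equal(vol$values[i, j, k], sum(w * mep), tolerance = 1e-10)
  }
  # convex-combination bounds
  expect_gte(min(vol$values), min(mep) - 1e-12)
  expect_lte(max(vol$values), max(mep) + 1e-12)
})

test_that("IDW handles coincident voxels, thresholding and rescaling", {
  grid <- list(x = 0:3, y = 0:3, z = 0)
  one <- idw_volume(matrix(c(1, 1, 0), 1), 1, grid)
  expect_equal(max(one$values), 1)
  expect_true(all(one$values == 1))  # single site: constant, all survive
  two <- idw_volume(rbind(c(0, 0, 0), c(2, 0, 0)), c(0.2, 0.8),
                    grid = list(x = 1, y = 0, z = 0), threshold = FALSE,
                    rescale = FALSE)
  expect_equal(as.numeric(two$values), 0.5)  # equidistant voxel
  coin <- idw_volume(rbind(c(0, 0, 0), c(2, 0, 0)), c(0.2, 0.8),
                     grid = list(x = c(0, 2), y = 0, z = 0),
                     threshold = FALSE, rescale = FALSE)
  expect_equal(as.numeric(coin$values), c(0.2, 0.8))
  resc <- idw_volume(matrix(runif(12, 0, 10), 4), c(0.1, 0.4, 0.7, 1),
                     list(x = seq(0, 10, 2), y = seq(0, 10, 2),
                          z = seq(0, 10, 2)))
  expect_equal(max(resc$values), 1)
  expect_gte(min(resc$values), 0)
  expect_error(idw_volume(matrix(0, 1, 3), 1, list(x = numeric(0),
                                                   y = 0, z = 0)),
               "empty grid")
})

test_that("volumes round-trip through NIfTI", {
  vol <- idw_volume(matrix(runif(9, 0, 10), 3), runif(3),
                    list(x = seq(0, 10, 2), y = seq(0, 10, 2),
                         z = seq(0, 10, 2)))
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path)
  back <- RNifti::readNifti(path)
  expect_equal(as.array(back), vol$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(path)
})
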