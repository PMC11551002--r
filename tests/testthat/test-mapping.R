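test_that("layout constructors reproduce their defining geometry", {
  l5 <- make_layout("line5", list(from = c(0, 0), to = c(40, -40)))
  expect_equal(l5$x, c(0, 10, 20, 30, 40))
  expect_equal(l5$y, c(0, -10, -20, -30, -40))

  c17 <- make_layout("circles17", list(center = c(0, 0)))
  expect_equal(nrow(c17), 17)
  r <- sqrt(c17$x^2 + c17$y^2)
  expect_equal(sum(abs(r - 35) < 1e-9), 8)
  expect_equal(sum(abs(r - 70) < 1e-9), 8)
  expect_equal(r[1], 0)

  sg <- make_layout("search_grid", list(center = c(0, 0), nx = 5, ny = 5))
  expect_equal(nrow(sg), 25)
  expect_equal(diff(range(sg$x)), 40)
  expect_equal(diff(range(sg$y)), 40)

  g27 <- make_layout("grid27")
  expect_equal(nrow(g27), 27)
  expect_false(anyDuplicated(g27$id) > 0)
  ctr <- g27[g27$id == attr(g27, "center_id"), ]
  expect_equal(c(ctr$x, ctr$y), c(-52, 5))

  expect_error(make_layout("line5"), "from")
})

test_that("the per-location paired t matches hand computation and the
           stats library", {
  tab <- make_mep_tab(participant = 1:3, location = "a",
                      post = c(2, 3, 4), pre = c(1, 1, 1))
  lt <- location_t(tab, "a")
  expect_equal(lt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(lt$df, 2)
  ref <- t.test(c(1, 2, 3))
  expect_equal(lt$t, unname(ref$statistic))
  # post identical to pre: a well-defined t of 0
  same <- make_mep_tab(participant = 1:3, location = "a",
                       post = c(1, 2, 3), pre = c(1, 2, 3))
  expect_equal(location_t(same, "a")$t, 0)
  # constant nonzero contrast is degenerate
  const <- make_mep_tab(participant = 1:3, location = "a",
                        post = c(2, 3, 4), pre = c(1, 2, 3))
  expect_error(location_t(const, "a"), "zero-variance")
})

test_that("interpolation reproduces node values, constants and affine
           fields inside the hull", {
  lay <- make_layout("grid27", params = list(center = c(0, 0)))
  const <- interpolate_layout(lay, rep(3.3, 27))
  expect_true(all(abs(const$z - 3.3) < 1e-12, na.rm = TRUE))
  vals <- 2 * lay$x - 0.5 * lay$y + 1
  ras <- interpolate_layout(lay, vals)
  plane <- outer(2 * ras$x, -0.5 * ras$y, "+") + 1
  expect_lt(max(abs(ras$z - plane), na.rm = TRUE), 1e-9)
  # node reproduction at pixels coinciding with nodes (integer-mm nodes)
  set.seed(4)
  vals2 <- runif(27)
  ras2 <- interpolate_layout(lay, vals2)
  for (k in c(1, 13, 25, 27)) {
    i <- which(abs(ras2$x - lay$x[k]) < 1e-9)
    j <- which(abs(ras2$y - lay$y[k]) < 1e-9)
    expect_equal(ras2$z[i, j], vals2[k], tolerance = 1e-9)
  }
  line <- make_layout("line5", list(from = c(0, 0), to = c(40, 0)))
  expect_error(interpolate_layout(line, 1:5), "collinear")
})

test_that("the contour area matches the analytic area of a
           super-threshold disc within 2%", {
  x <- seq(-30, 30); y <- seq(-30, 30)
  z <- outer(x, y, function(a, b) 30 - sqrt(a^2 + b^2))
  ras <- structure(list(x = x, y = y, z = z), resolution_mm = 1,
                   class = "scalp_raster")
  ca <- contour_area(ras, t_crit = 10)  # disc of radius 20
  expect_equal(ca$area, pi * 400, tolerance = 0.02)
  expect_length(ca$contour, 1)
})

test_that("contour area agrees with fine pixel counting and is monotone in
           the threshold", {
  set.seed(6)
  f <- function(a, b) {
    2 * sin(a / 9) + 1.5 * cos(b / 11) + 0.8 * sin((a + b) / 13)
  }
  x <- seq(0, 60); y <- seq(0, 60)
  ras <- structure(list(x = x, y = y, z = outer(x, y, f)),
                   resolution_mm = 1, class = "scalp_raster")
  xf <- seq(0, 60, by = 0.25); yf <- xf
  zf <- outer(xf, yf, f)
  for (thr in c(-1, 0, 1)) {
    pix <- sum(zf > thr) * 0.25^2
    expect_equal(contour_area(ras, thr)$area, pix, tolerance = 0.02)
  }
  areas <- vapply(seq(-2, 3, 0.5),
                  function(t) contour_area(ras, t)$area, 1)
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("empty and full super-threshold regions hit the bounds", {
  lay <- make_layout("grid27", params = list(center = c(0, 0)))
  ras <- interpolate_layout(lay, rep(1, 27))
  none <- contour_area(ras, t_crit = 5)
  expect_equal(none$area, 0)
  all_in <- contour_area(ras, t_crit = 0)
  expect_equal(all_in$area, all_in$domain_area)
  expect_lte(all_in$area, all_in$domain_area)
})

test_that("the scalp t map flags exactly the locations above threshold", {
  set.seed(12)
  lay <- make_layout("search_grid", list(center = c(0, 0)))
  tabs <- lapply(seq_len(nrow(lay)), function(i) {
    bump <- 2 * exp(-((lay$x[i])^2 + (lay$y[i])^2) / 300)
    make_mep_tab(participant = 1:12, location = lay$id[i],
                 post = bump + rnorm(12, sd = 0.3) + 0.5,
                 pre = rep(0.5, 12))
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("mep_table", "data.frame")
  tm <- scalp_tmap(tab, lay, t_crit = 2.20)
  expect_setequal(tm$significant, tm$stats$location[tm$stats$t > 2.20])
  expect_true(all(tm$stats$df == 11))
  expect_gte(tm$area, 0)
  expect_lte(tm$area, contour_area(tm$raster, -Inf)$domain_area + 1e-9)
})
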