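#' Stimulation-site layouts in Cz-referenced scalp coordinates
#'
#' Constructs the scalp layouts used for MEP mapping, as data frames of
#' `id`, `x` (mm lateral, negative = left) and `y` (mm anterior, negative =
#' posterior) relative to the vertex Cz at (0, 0).
#'
#' * `line5`: two endpoints plus 3 equidistant interior points (the
#'   M1-to-SMG line); `params$from`, `params$to`.
#' * `circles17`: `params$center` plus 8 points on a 35 mm circle and 8 on a
#'   70 mm circle, 45 degree spacing, first point toward North (anterior).
#' * `grid27`: a 27-point arrangement centred on M1 (`params$center`): a
#'   5x5 grid at 17.5 mm spacing plus two posterolateral extension sites at
#'   (-40, -30) and (-30, -45) mm from the centre, toward the supramarginal
#'   gyrus. This is an idealized approximation of the published cloth-map
#'   geometry, which is only available as per-participant tables.
#' * `search_grid`: `params$nx` by `params$ny` grid at
#'   `params$spacing` mm (default 10) centred on `params$center`, as used
#'   when hunting for the optimal M1-hand site.
#'
#' @param kind One of `"line5"`, `"circles17"`, `"grid27"`, `"search_grid"`.
#' @param params Named list of parameters for the kind (see above). All
#'   kinds accept `center`; default `c(-52, 5)`, the mean M1-hand site.
#' @return Data frame of class `scalp_layout` with columns `id`, `x`, `y`
#'   and attributes `kind` and `center_id`.
#' @export
make_layout <- function(kind = c("line5", "circles17", "grid27",
                                 "search_grid"),
                        params = list()) {
  kind <- match.arg(kind)
  center <- params$center %||% c(-52, 5)
  ring <- function(r, n = 8, first_deg = 90) {
    a <- deg2rad(first_deg + seq(0, by = 45, length.out = n))
    cbind(x = center[1] + r * cos(a), y = center[2] + r * sin(a))
  }
  if (kind == "line5") {
    from <- params$from; to <- params$to
    if (is.null(from) || is.null(to)) stopf("line5 needs params$from and $to")
    f <- seq(0, 1, length.out = 5)
    xy <- cbind(x = from[1] + f * (to[1] - from[1]),
                y = from[2] + f * (to[2] - from[2]))
    out <- data.frame(id = paste0("pos", 1:5), xy)
    center_id <- "pos1"
  } else if (kind == "circles17") {
    xy <- rbind(c(center[1], center[2]), ring(35), ring(70))
    out <- data.frame(id = sprintf("loc%02d", 1:17),
                      x = xy[, 1], y = xy[, 2])
    center_id <- "loc01"
  } else if (kind == "grid27") {
    g <- expand.grid(dx = seq(-35, 35, by = 17.5),
                     dy = seq(35, -35, by = -17.5))
    ext <- rbind(c(-40, -30), c(-30, -45))
    xy <- rbind(as.matrix(g), ext)
    out <- data.frame(id = sprintf("loc%02d", 1:27),
                      x = center[1] + xy[, 1], y = center[2] + xy[, 2])
    center_id <- out$id[g$dx == 0 & g$dy == 0][1]
  } else {
    nx <- params$nx %||% 5; ny <- params$ny %||% 5
    sp <- params$spacing %||% 10
    g <- expand.grid(dx = (seq_len(nx) - (nx + 1) / 2) * sp,
                     dy = (seq_len(ny) - (ny + 1) / 2) * sp)
    out <- data.frame(id = sprintf("loc%02d", seq_len(nx * ny)),
                      x = center[1] + g$dx, y = center[2] + g$dy)
    ctr <- which.min(g$dx^2 + g$dy^2)
    center_id <- out$id[ctr]
  }
  if (anyDuplicated(out$id)) stopf("layout ids must be unique")
  attr(out, "kind") <- kind
  attr(out, "center_id") <- center_id
  class(out) <- c("scalp_layout", "data.frame")
  out
}

#' Per-location paired t statistic of post- vs pre-TMS MEP amplitude
#'
#' Averages the post-minus-pre amplitude contrast within participant at the
#' given location (across orientations/intensities if present) and computes
#' the paired t statistic across participants, `df = n - 1`. Normalized
#' amplitudes are used when present in the table.
#'
#' @param tab A [mep_table()] (normalized or raw).
#' @param location Location id.
#' @return List with `t`, `df`, `n` and the mean contrast.
#' @export
location_t <- function(tab, location) {
  rows <- tab[tab$location == location, , drop = FALSE]
  if (!nrow(rows)) stopf("no data at location '%s'", location)
  post <- rows$amplitude_norm %||% NULL
  if (is.null(post) || is.null(rows$amplitude_pre_norm)) {
    d <- rows$amplitude_post - rows$amplitude_pre
  } else {
    d <- rows$amplitude_norm - rows$amplitude_pre_norm
  }
  dm <- tapply(d, rows$participant, mean)
  n <- length(dm)
  if (n < 2) stopf("need >= 2 participants at location '%s'", location)
  s <- sd(dm)
  if (s == 0) {
    # identically zero contrasts (post == pre) are a well-defined t of 0;
    # a degenerate nonzero constant contrast is not
    if (all(dm == 0)) return(list(t = 0, df = n - 1, n = n, mean = 0))
    stopf("zero-variance contrast at location '%s'", location)
  }
  list(t = mean(dm) / (s / sqrt(n)), df = n - 1, n = n, mean = mean(dm))
}

#' Piecewise-linear interpolation of location values onto a 1 mm raster
#'
#' Linearly interpolates values on a Delaunay triangulation of the layout,
#' evaluated on a regular grid clipped to the convex hull (no
#' extrapolation; cells outside the hull are `NA`). Node values are
#' reproduced exactly and any affine field is reproduced everywhere in the
#' hull — the interpolant cannot overshoot, so it creates no spurious
#' significant islands.
#'
#' @param layout A [make_layout()] data frame (or any `id`, `x`, `y` table).
#' @param values Numeric vector, one value per layout row.
#' @param resolution_mm Grid step in mm (default 1).
#' @return List of class `scalp_raster`: `x`, `y` (grid axes, mm) and `z`
#'   (matrix `length(x)` by `length(y)`, `NA` outside the hull), with the
#'   grid `resolution_mm` as an attribute.
#' @export
interpolate_layout <- function(layout, values, resolution_mm = 1) {
  if (nrow(layout) != length(values))
    stopf("values must match layout rows")
  if (nrow(layout) < 3) stopf("need >= 3 locations to interpolate")
  # collinearity check: rank of centred coordinates
  xy <- cbind(layout$x, layout$y)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2)
    stopf("layout is collinear; report per-location values instead")
  xo <- seq(min(layout$x), max(layout$x), by = resolution_mm)
  yo <- seq(min(layout$y), max(layout$y), by = resolution_mm)
  g <- interp::interp(x = layout$x, y = layout$y, z = values,
                      xo = xo, yo = yo, method = "linear",
                      output = "grid")
  structure(list(x = g$x, y = g$y, z = g$z),
            resolution_mm = resolution_mm, class = "scalp_raster")
}

# area fraction of {linear > t} on a triangle with vertex values a, b, c
# (vectorised); any non-finite vertex value contributes 0
triangle_above_fraction <- function(a, b, c, t) {
  lo <- pmin(a, b, c); hi <- pmax(a, b, c)
  mid <- a + b + c - lo - hi
  f <- numeric(length(a))
  finite <- is.finite(lo) & is.finite(hi)
  full <- finite & (t < lo)
  f[full] <- 1
  upper <- finite & (t >= mid) & (t < hi)
  den <- (hi - mid) * (hi - lo)
  ok <- upper & den > 0
  f[ok] <- ((hi - t)^2 / den)[ok]
  lower <- finite & (t >= lo) & (t < mid)
  den2 <- (mid - lo) * (hi - lo)
  ok2 <- lower & den2 > 0
  f[ok2] <- 1 - ((t - lo)^2 / den2)[ok2]
  f[lower & den2 <= 0] <- 1  # degenerate flat triangle sitting above t
  f
}

#' Super-threshold area of a raster with sub-cell contouring
#'
#' Measures the area of the region where the interpolated raster exceeds
#' `t_crit`. Each grid cell is split into four triangles against the cell
#' centre (the corner mean) and the super-level-set area of the linear
#' interpolant is accumulated per triangle, which resolves the
#' marching-squares saddle ambiguity deterministically and is accurate to
#' sub-cell precision. Cells touching the raster boundary (`NA` corners,
#' outside the convex hull) contribute nothing. The threshold contour
#' polyline is also returned for plotting.
#'
#' @param raster A [interpolate_layout()] raster.
#' @param t_crit Threshold (default 2.20, the two-tailed 5% critical t at
#'   11 degrees of freedom).
#' @return List with `area` (mm^2), `contour` (list of polylines from
#'   [grDevices::contourLines()]), `t_crit` and `domain_area` (measure of
#'   the finite raster region, an upper bound for `area`).
#' @export
contour_area <- function(raster, t_crit = 2.20) {
  z <- raster$z
  z[!is.finite(z)] <- -Inf
  nx <- length(raster$x); ny <- length(raster$y)
  if (nx < 2 || ny < 2) return(list(area = 0, contour = list(),
                                    t_crit = t_crit, domain_area = 0))
  res <- attr(raster, "resolution_mm") %||%
    (raster$x[2] - raster$x[1])
  c00 <- as.vector(z[-nx, -ny]); c10 <- as.vector(z[-1, -ny])
  c11 <- as.vector(z[-1, -1]);  c01 <- as.vector(z[-nx, -1])
  cc <- (c00 + c10 + c11 + c01) / 4
  tri_area <- res^2 / 4
  measure <- function(thr) {
    tri_area * sum(triangle_above_fraction(c00, c10, cc, thr),
                   triangle_above_fraction(c10, c11, cc, thr),
                   triangle_above_fraction(c11, c01, cc, thr),
                   triangle_above_fraction(c01, c00, cc, thr))
  }
  finite_floor <- if (any(is.finite(z))) min(z[is.finite(z)]) - 1 else 0
  polyline <- tryCatch(
    grDevices::contourLines(raster$x, raster$y, raster$z, levels = t_crit),
    error = function(e) list())
  list(area = measure(t_crit), contour = polyline, t_crit = t_crit,
       domain_area = measure(finite_floor))
}

#' Scalp t-statistic map with thresholded contour area
#'
#' Computes the per-location post- vs pre-TMS paired t statistic
#' ([location_t()]), interpolates the t values across the layout
#' ([interpolate_layout()]) and measures the area of the region above
#' `t_crit` ([contour_area()]). No correction for multiple comparisons is
#' applied across locations; locations on a map are spatially
#' autocorrelated and the map is read as a descriptive surface with
#' hypothesis tests focused on specific sites.
#'
#' @inheritParams location_t
#' @param layout A [make_layout()] layout matching `tab$location` ids.
#' @param t_crit Significance threshold on t (default 2.20); the
#'   significant set is one-sided, `t > t_crit`, since MEPs increase
#'   post-TMS amplitude.
#' @param resolution_mm Raster resolution (mm).
#' @return List of class `scalp_tmap`: `stats` (per-location `t`, `df`,
#'   `n`), `raster`, `area` (mm^2), `contour`, `significant` (location
#'   ids with `t > t_crit`) and `t_crit`.
#' @export
scalp_tmap <- function(tab, layout, t_crit = 2.20, resolution_mm = 1) {
  st <- do.call(rbind, lapply(layout$id, function(id) {
    lt <- location_t(tab, id)
    data.frame(location = id, t = lt$t, df = lt$df, n = lt$n)
  }))
  raster <- interpolate_layout(layout, st$t, resolution_mm)
  ca <- contour_area(raster, t_crit)
  structure(list(stats = st, raster = raster, area = ca$area,
                 contour = ca$contour,
                 significant = st$location[st$t > t_crit],
                 t_crit = t_crit),
            class = "scalp_tmap")
}
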