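#' Euclidean distance between MNI coordinates
#'
#' @param a,b Numeric length-3 vectors, mm in MNI space.
#' @return Distance in mm.
#' @export
mni_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt(sum((a - b)^2))
}

#' Euclidean distance between Cz-referenced scalp coordinates
#'
#' Straight-line distance in the 2-D tape-measure scalp plane.
#'
#' @param a,b Numeric length-2 vectors, mm.
#' @return Distance in mm.
#' @export
scalp_distance <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  sqrt(sum((a - b)^2))
}

#' Screen stimulation targets for motor-confound proximity to M1
#'
#' Flags each target as at risk of a hand-motor activation confound when it
#' lies within the empirical cutoff of the M1-hand reference: 42 mm in the
#' brain (MNI) or 55 mm on the scalp — the largest distances at which MEPs
#' were evoked during natural hand movement. Targets may carry MNI
#' (`mni_x`, `mni_y`, `mni_z`) and/or scalp (`scalp_x`, `scalp_y`)
#' coordinates; a target with neither is an error.
#'
#' @param targets Data frame with a `label` column and coordinate columns
#'   as above (missing values allowed per row, not per both spaces).
#' @param m1_mni M1-hand MNI reference (default `c(-38, -15, 58)`).
#' @param m1_scalp M1-hand scalp reference (default `c(-52, 5)`).
#' @param brain_cutoff_mm,scalp_cutoff_mm Cutoffs (defaults 42 and 55 mm).
#' @return Data frame sorted by distance: `label`, `space`, `distance_mm`,
#'   `cutoff_mm`, `flagged`.
#' @export
proximity_screen <- function(targets, m1_mni = c(-38, -15, 58),
                             m1_scalp = c(-52, 5),
                             brain_cutoff_mm = 42, scalp_cutoff_mm = 55) {
  stopifnot("label" %in% names(targets))
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, , drop = FALSE]
    out <- NULL
    if (all(c("mni_x", "mni_y", "mni_z") %in% names(tg)) &&
        all(is.finite(c(tg$mni_x, tg$mni_y, tg$mni_z)))) {
      d <- mni_distance(c(tg$mni_x, tg$mni_y, tg$mni_z), m1_mni)
      out <- rbind(out, data.frame(label = tg$label, space = "brain",
                                   distance_mm = d,
                                   cutoff_mm = brain_cutoff_mm,
                                   flagged = d <= brain_cutoff_mm))
    }
    if (all(c("scalp_x", "scalp_y") %in% names(tg)) &&
        all(is.finite(c(tg$scalp_x, tg$scalp_y)))) {
      d <- scalp_distance(c(tg$scalp_x, tg$scalp_y), m1_scalp)
      out <- rbind(out, data.frame(label = tg$label, space = "scalp",
                                   distance_mm = d,
                                   cutoff_mm = scalp_cutoff_mm,
                                   flagged = d <= scalp_cutoff_mm))
    }
    if (is.null(out))
      stopf("target '%s' has neither MNI nor scalp coordinates", tg$label)
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$distance_mm), , drop = FALSE]
}

#' Threshold sweep of the electric-field vs MEP correlation
#'
#' For each candidate field threshold, correlates modeled field magnitude
#' with mean MEP amplitude over the location/orientation pairs whose field
#' is at or above the threshold (excluding progressively more low-current
#' points). Correlations are computed only while at least 3 pairs remain
#' and both variables vary; other thresholds are dropped with a warning.
#' The best threshold is the smallest one attaining the maximum
#' correlation. The profile is invariant to affine rescaling of the MEP
#' values.
#'
#' @param field_table Data frame with columns `field_vpm` (V/m, >= 0) and
#'   `mep` (paired mean MEP amplitude, any affine scale).
#' @param thresholds Candidate thresholds in V/m (default `0:79`).
#' @return List with `best_threshold`, `best_correlation` and `profile`
#'   (data frame `threshold`, `r`, `n`).
#' @export
efield_threshold_sweep <- function(field_table, thresholds = 0:79) {
  stopifnot(all(c("field_vpm", "mep") %in% names(field_table)))
  if (nrow(field_table) < 4) stopf("need >= 4 paired points")
  if (any(field_table$field_vpm < 0)) stopf("field magnitudes must be >= 0")
  prof <- lapply(thresholds, function(th) {
    sub <- field_table[field_table$field_vpm >= th, , drop = FALSE]
    if (nrow(sub) < 3) return(NULL)
    if (sd(sub$field_vpm) == 0 || sd(sub$mep) == 0) {
      warnf("threshold %g skipped: constant field or MEP subset", th)
      return(NULL)
    }
    data.frame(threshold = th, r = cor(sub$field_vpm, sub$mep),
               n = nrow(sub))
  })
  prof <- do.call(rbind, prof)
  if (is.null(prof) || !nrow(prof))
    stopf("no threshold admits a defined correlation")
  best <- prof$threshold[which.max(prof$r)]  # ties: smallest (order kept)
  list(best_threshold = best, best_correlation = max(prof$r),
       profile = prof)
}

#' Inverse-distance-weighted MEP volume
#'
#' Renders scalp-site MEP values into a 3-D voxel volume: each voxel takes
#' the weighted sum of site MEPs with weights proportional to the inverse
#' of the voxel-site distance, normalized to sum to 1 per voxel (a convex
#' combination, so pre-threshold values lie within the range of the site
#' values). A voxel coincident with a site takes that site's value. The
#' volume is then thresholded at its mean (sub-threshold voxels set to 0)
#' and the survivors rescaled to `[0, 1]`.
#'
#' @param locations Numeric matrix (n x 3), site coordinates in mm.
#' @param mep Numeric vector of site MEP values (length n).
#' @param grid List with numeric axes `x`, `y`, `z` (mm).
#' @param threshold Apply the mean threshold (default `TRUE`).
#' @param rescale Rescale surviving voxels to `[0, 1]` (default `TRUE`).
#' @return List of class `mep_volume`: `values` (3-D array), `grid`,
#'   `threshold_value` (the pre-threshold mean, or `NA`).
#' @export
idw_volume <- function(locations, mep, grid, threshold = TRUE,
                       rescale = TRUE) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 3, nrow(locations) == length(mep),
            nrow(locations) >= 1)
  if (!all(c("x", "y", "z") %in% names(grid)) ||
      !all(vapply(grid[c("x", "y", "z")], length, 1L) >= 1))
    stopf("empty grid")
  vox <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  n_vox <- nrow(vox)
  num <- numeric(n_vox); den <- numeric(n_vox)
  exact <- rep(NA_real_, n_vox)
  for (i in seq_len(nrow(locations))) {
    d <- sqrt((vox[, 1] - locations[i, 1])^2 +
              (vox[, 2] - locations[i, 2])^2 +
              (vox[, 3] - locations[i, 3])^2)
    hit <- d == 0
    exact[hit] <- mep[i]
    w <- 1 / d
    w[hit] <- 0
    num <- num + w * mep[i]
    den <- den + w
  }
  v <- num / den
  v[!is.na(exact)] <- exact[!is.na(exact)]
  thr <- NA_real_
  if (threshold) {
    thr <- mean(v)
    v[v < thr] <- 0
  }
  if (rescale) {
    surv <- v > 0
    if (any(surv)) {
      lo <- min(v[surv]); hi <- max(v[surv])
      v[surv] <- if (hi > lo) (v[surv] - lo) / (hi - lo) else 1
    }
  }
  structure(list(values = array(v, dim = c(length(grid$x), length(grid$y),
                                           length(grid$z))),
                 grid = grid, threshold_value = thr),
            class = "mep_volume")
}
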