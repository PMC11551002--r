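#' Amplitude-weighted mean resultant vector over coil orientations
#'
#' Treats each coil orientation as a unit vector weighted by its (normalized)
#' MEP amplitude, sums the vectors and divides by their number:
#' `R = || sum_i a_i (cos t_i, sin t_i) || / N`. With equal amplitudes at
#' evenly spaced orientations the length is 0; with a single nonzero
#' amplitude of 1 among eight orientations it is 1/8. The direction of the
#' summed vector is the preferred orientation (degrees in `[0, 360)`,
#' 0 = East toward the right preauricular point, 90 = North toward the
#' nasion); it is `NA` when the length is 0.
#'
#' @param angles Orientation angles in degrees (>= 2, distinct modulo 360).
#' @param amplitudes Non-negative amplitudes, one per angle.
#' @return List with `length` and `angle` (degrees or `NA`).
#' @export
resultant <- function(angles, amplitudes) {
  if (length(angles) < 2) stopf("need at least 2 orientations")
  if (length(angles) != length(amplitudes))
    stopf("angles and amplitudes differ in length")
  if (anyDuplicated(wrap360(angles))) stopf("angles must be distinct mod 360")
  if (any(amplitudes < 0)) stopf("amplitudes must be >= 0")
  th <- deg2rad(angles)
  x <- sum(amplitudes * cos(th)); y <- sum(amplitudes * sin(th))
  n <- length(angles)
  len <- sqrt(x^2 + y^2) / n
  # the direction is undefined for a (numerically) vanishing resultant
  tol <- 1e-12 * max(1, sum(amplitudes))
  ang <- if (len < tol) NA_real_ else wrap360(rad2deg(atan2(y, x)))
  list(length = len, angle = ang)
}

#' Baseline-corrected orientation preference
#'
#' Computes the mean resultant vector of the post-TMS amplitude profile and
#' subtracts the resultant length of the matching pre-TMS (background EMG)
#' profile, since ongoing muscle activity alone can produce spurious
#' orientation structure. The preferred angle is taken from the post-TMS
#' profile. Both profiles must share one set of angles and should share one
#' normalization factor so the corrected length is comparable across
#' conditions.
#'
#' @param angles Orientation angles in degrees.
#' @param post,pre Amplitude profiles measured after (10-50 ms) and before
#'   (-50 to -10 ms) the pulse.
#' @return List of class `orientation_preference`: `resultant_length`
#'   (post), `pre_length`, `corrected_length` (post minus pre),
#'   `preferred_angle` (degrees or `NA`) and `n_orientations`.
#' @export
baseline_corrected_preference <- function(angles, post, pre) {
  if (length(post) != length(pre))
    stopf("post and pre profiles differ in length")
  rp <- resultant(angles, post)
  rb <- resultant(angles, pre)
  structure(list(resultant_length = rp$length, pre_length = rb$length,
                 corrected_length = rp$length - rb$length,
                 preferred_angle = rp$angle,
                 n_orientations = length(angles)),
            class = "orientation_preference")
}

#' Compass label of a coil orientation
#'
#' Maps an angle to the nearest of the 8 compass points, using the scalp
#' convention of the induced-current direction: East (0) toward the right
#' preauricular point, North (90) toward the nasion, West (180), South
#' (270) toward the inion. Ties exactly halfway between two points go to the
#' counterclockwise (higher-angle) neighbour, so 112.5 is NW, not N.
#'
#' @param angle Angle(s) in degrees (any finite value).
#' @return Character vector of labels among E, NE, N, NW, W, SW, S, SE.
#' @export
compass_label <- function(angle) {
  if (any(!is.finite(angle))) stopf("angle must be finite")
  labels <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")
  idx <- floor(wrap360(angle + 22.5) / 45) %% 8
  labels[idx + 1]
}
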