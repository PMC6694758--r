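# Track-path geometry for the synthetic generator: centerline pose and the
# azimuth of a preview point a fixed time headway ahead of the vehicle.

# Pose on the centerline of a right bend: x/y in meters, heading in radians
# measured clockwise from the approach direction. Vectorized over s.
track_pose <- function(s, track) {
  la <- track$approach_length_m
  lc <- track$arc_length_m
  r <- track$radius_m
  th_end <- lc / r
  x <- y <- psi <- numeric(length(s))

  on_a <- s < la
  y[on_a] <- s[on_a]

  on_c <- s >= la & s < la + lc
  th <- (s[on_c] - la) / r
  x[on_c] <- r * (1 - cos(th))
  y[on_c] <- la + r * sin(th)
  psi[on_c] <- th

  on_e <- s >= la + lc
  d <- s[on_e] - la - lc
  x[on_e] <- r * (1 - cos(th_end)) + d * sin(th_end)
  y[on_e] <- la + r * sin(th_end) + d * cos(th_end)
  psi[on_e] <- th_end

  list(x = x, y = y, psi = psi)
}

#' Azimuth of the guiding preview point
#'
#' For a vehicle at arc-length position `s` traveling at `speed_kmh`,
#' computes the horizontal angle (degrees, rightward positive for right
#' bends) at which the point on the future path `headway_s` seconds ahead
#' is seen, relative to the current heading. This is the idealized
#' guiding-fixation direction used by the synthetic generator: zero on the
#' straight far from the bend, turning smoothly toward the bend once the
#' preview point enters the arc. Preview points beyond the track end are
#' clamped to the end of the exit straight.
#'
#' On a chord of the arc the construction reduces to the inscribed-angle
#' result: a preview distance `d` fully on a circle of radius `R`
#' subtends an azimuth of `d / (2 R)` radians.
#'
#' @param s Positions along the track (m).
#' @param track A [track_spec()].
#' @param speed_kmh Speed (km/h); sets the preview distance
#'   `speed * headway_s`.
#' @param headway_s Preview time headway (s), in `[1, 2]`.
#' @param direction Bend direction; the left-bend curve is the mirror
#'   image (leftward-negative azimuth convention throughout).
#' @return Numeric vector of azimuths (deg).
#' @export
preview_azimuth <- function(s, track, speed_kmh, headway_s = 1.5,
                            direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(inherits(track, "track_spec"), speed_kmh > 0)
  if (headway_s < 1 || headway_s > 2) {
    stop("headway_s must lie in [1, 2] seconds", call. = FALSE)
  }
  d <- speed_kmh / 3.6 * headway_s
  s_target <- pmin(s + d, track_length(track))
  here <- track_pose(s, track)
  there <- track_pose(s_target, track)
  vx <- there$x - here$x
  vy <- there$y - here$y
  # vehicle frame: forward = (sin psi, cos psi), right = (cos psi, -sin psi)
  fwd <- vx * sin(here$psi) + vy * cos(here$psi)
  rgt <- vx * cos(here$psi) - vy * sin(here$psi)
  az <- atan2(rgt, fwd) * 180 / pi
  if (direction == "left") -az else az
}

#' Guiding azimuth with smooth anticipation
#'
#' The raw preview azimuth has corners where the preview point crosses
#' section boundaries; drivers blend upcoming road information over a
#' stretch of road rather than switching instantaneously. This function
#' convolves [preview_azimuth()] with a Gaussian kernel in arc length
#' (SD `blend_m`), yielding the smooth guiding direction the synthetic
#' generator tracks. `blend_m = 0` returns the raw geometric preview.
#'
#' @inheritParams preview_azimuth
#' @param blend_m Gaussian blending SD in meters of arc length.
#' @return Numeric vector of azimuths (deg) at the positions `s`.
#' @export
guiding_azimuth <- function(s, track, speed_kmh, headway_s = 1.5,
                            direction = "right", blend_m = 10) {
  if (blend_m <= 0) {
    return(preview_azimuth(s, track, speed_kmh, headway_s, direction))
  }
  curve <- guiding_curve(track, speed_kmh, headway_s, direction, blend_m)
  out <- stats::approx(curve$s, curve$az, xout = s, rule = 2)$y
  out
}

# Blended guiding curve on a fine grid over [0, approach + arc].
guiding_curve <- function(track, speed_kmh, headway_s, direction,
                          blend_m, step = 0.1) {
  s_end <- track$approach_length_m + track$arc_length_m
  pad <- 4 * blend_m
  grid <- seq(-pad, s_end + pad, by = step)
  az <- preview_azimuth(pmin(pmax(grid, 0), track_length(track)), track,
                        speed_kmh, headway_s, direction)
  kern <- stats::dnorm(seq(-pad, pad, by = step), 0, blend_m)
  kern <- kern / sum(kern)
  sm <- stats::filter(az, kern, sides = 2)
  keep <- grid >= 0 & grid <= s_end & !is.na(sm)
  list(s = grid[keep], az = as.numeric(sm[keep]))
}

#' Idealized guiding-fixation reference curve
#'
#' Evaluates [guiding_azimuth()] at the centers of contiguous `bin_m`
#' bins covering the approach and arc. This is the generator's ground
#' truth against which the empirically estimated reference can be
#' compared.
#'
#' @inheritParams guiding_azimuth
#' @param bin_m Bin width (m).
#' @return A tibble with `s_bin_m` (bin centers) and `azimuth_deg`.
#' @export
true_gf_reference <- function(track, speed_kmh, headway_s = 1.5,
                              bin_m = 0.5, direction = "right",
                              blend_m = 10) {
  s_end <- track$approach_length_m + track$arc_length_m
  centers <- seq(bin_m / 2, s_end - bin_m / 2, by = bin_m)
  tibble::tibble(
    s_bin_m = centers,
    azimuth_deg = guiding_azimuth(centers, track, speed_kmh, headway_s,
                                  direction, blend_m)
  )
}
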