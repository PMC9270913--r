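## Planar unicycle kinematics in the start frame:
## x = rightward (m), y = forward (m), heading = clockwise angle from +y
## (deg at interfaces, rad internally). Positive angular velocity turns
## rightward, matching the target-angle sign convention.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap to (-180, 180]
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Convert polar target/endpoint coordinates to Cartesian start-frame
#'
#' @param r Distance(s) from the start position in m.
#' @param theta Angle(s) in deg, positive rightward of the initial heading.
#' @return A data.frame with columns `x` (rightward, m) and `y` (forward, m).
#' @export
#' @examples
#' polar_to_xy(2, 30)
polar_to_xy <- function(r, theta) {
  th <- deg2rad(theta)
  data.frame(x = r * sin(th), y = r * cos(th))
}

#' Integrate linear/angular velocities into a pose trajectory
#'
#' Euler integration of standard unicycle kinematics from the origin with
#' heading 0 (facing +y): at each step the position advances by `v * dt`
#' along the current heading, then the heading advances by `w * dt`.
#'
#' @param v Linear velocity series in m/s.
#' @param w Angular velocity series in deg/s (positive = rightward).
#' @param dt Time step in s.
#' @return A data.frame with one row per step (pose *after* that step):
#'   columns `x`, `y` (m) and `heading` (deg, wrapped to (-180, 180\]).
#' @export
#' @examples
#' tr <- integrate_pose(rep(1, 120), rep(0, 120), dt = 1 / 60)
#' tail(tr, 1)  # 2 m straight ahead
integrate_pose <- function(v, w, dt) {
  n <- length(v)
  if (length(w) != n) stop("v and w must have equal length", call. = FALSE)
  if (n == 0) stop("empty velocity series", call. = FALSE)
  stopifnot(dt > 0)
  h <- cumsum(deg2rad(w)) * dt          # heading after each step
  h_pre <- c(0, h[-n])                  # heading during each step
  x <- cumsum(v * dt * sin(h_pre))
  y <- cumsum(v * dt * cos(h_pre))
  data.frame(x = x, y = y, heading = wrap_deg(rad2deg(h)))
}

#' Polar endpoint of a trajectory
#'
#' Distance and bearing of the final position relative to the start position
#' and initial heading (the response coordinates of a trial).
#'
#' @param trajectory A data.frame with `x` and `y` columns as produced by
#'   [integrate_pose()], or any pose table whose last row is the endpoint.
#' @return Named numeric vector `c(r = , theta = )` in m / deg. A response
#'   at the origin has an undefined bearing; it is reported as `theta = 0`
#'   with attribute `at_origin = TRUE`.
#' @export
final_polar <- function(trajectory) {
  if (NROW(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  x <- trajectory$x[NROW(trajectory)]
  y <- trajectory$y[NROW(trajectory)]
  r <- sqrt(x^2 + y^2)
  if (r < .Machine$double.eps) {
    out <- c(r = 0, theta = 0)
    attr(out, "at_origin") <- TRUE
    return(out)
  }
  c(r = r, theta = rad2deg(atan2(x, y)))
}

#' Euclidean error between a target and a response endpoint
#'
#' Both points are given in polar start-frame coordinates (distance m,
#' angle deg); the error is the Euclidean distance between them in the
#' Cartesian plane — the distance between the stopping position and the
#' target. Vectorized over trials.
#'
#' @param target_r,target_theta Target coordinates (m, deg).
#' @param endpoint_r,endpoint_theta Response coordinates (m, deg).
#' @return Error(s) in m.
#' @export
#' @examples
#' trial_error(3, 0, 4, 0)        # 1 m short/long on the same ray
#' trial_error(2, 30, 2, -30)     # chord: 2 * 2 * sin(30 deg) = 2 m
trial_error <- function(target_r, target_theta, endpoint_r, endpoint_theta) {
  a <- polar_to_xy(target_r, target_theta)
  b <- polar_to_xy(endpoint_r, endpoint_theta)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}
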