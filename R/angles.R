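#' Wrap angles to the signed shortest-arc range
#'
#' Maps angles in degrees onto `(-180, 180]`. Differences of wrapped angles
#' computed through this function are shortest-arc (wrap-aware) differences.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `(-180, 180]`.
#' @examples
#' wrap_angle(c(190, -190, 180, 360))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(!is.na(w) & w > 180, w - 360, w)
}

#' Unwrap an angle series into a continuous real series
#'
#' Removes artificial 360 degree jumps so that cumulative rotations beyond a
#' full turn are preserved (an angular spread larger than 360 degrees stays
#' larger than 360 degrees). Frame-to-frame changes are taken on the shortest
#' arc, so the input must not rotate by 180 degrees or more in a single step.
#'
#' @param x numeric vector of angles in degrees (period 360).
#' @return numeric vector, unbounded, with `x[1]` preserved.
#' @examples
#' unwrap_angle(c(350, 355, 0, 5))   # 350 355 360 365
#' @export
unwrap_angle <- function(x) {
  if (length(x) <= 1L) return(x)
  x[1L] + cumsum(c(0, wrap_angle(diff(x))))
}

#' Absolute wrap-aware angular distance in degrees
#' @param a,b angles in degrees.
#' @return absolute shortest-arc distance, in `[0, 180]`.
#' @export
angle_dist <- function(a, b) abs(wrap_angle(a - b))

# Unwrap an axis-valued (period 180) series by unwrapping doubled angles.
# Consecutive values of the result differ by < 90 degrees whenever that is
# achievable, which is exactly the minimal frame-to-frame orientation change.
unwrap_axis <- function(alpha1) unwrap_angle(2 * alpha1) / 2

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
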