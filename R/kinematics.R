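#' Smoothing parameters
#'
#' Parameters of the two-stage smoother used throughout: repeated running
#' medians (RRM) to remove tracker glitches, followed by tricube-weighted
#' local linear regression (LOWESS-type) which yields both the smoothed value
#' and its first time derivative. The defaults (13-frame local regression,
#' i.e. about 0.5 s at 25 Hz, with a 5-frame running median repeated 3
#' times) suppress per-frame tracking noise while, together with the arrest
#' tolerance bands which absorb the kernel tails, still resolving mode
#' transitions to within about two frames; see the package vignette for the
#' resolution/noise trade-off.
#'
#' @param lowess_span optional fraction (0, 1] of the series length used as
#'   the local-regression window; when `NULL` (default) `lowess_window` is
#'   used directly.
#' @param lowess_window odd local-regression window length, frames.
#' @param rrm_window odd running-median window length, frames.
#' @param passes number of running-median repetitions.
#' @return an object of class `smoothing_params`.
#' @export
smoothing_params <- function(lowess_span = NULL, lowess_window = 13L,
                             rrm_window = 5L, passes = 3L) {
  if (!is.null(lowess_span))
    stopifnot(lowess_span > 0, lowess_span <= 1)
  lowess_window <- as.integer(lowess_window)
  rrm_window <- as.integer(rrm_window)
  stopifnot(lowess_window >= 3L, lowess_window %% 2L == 1L,
            rrm_window >= 3L, rrm_window %% 2L == 1L, passes >= 1L)
  structure(list(lowess_span = lowess_span, lowess_window = lowess_window,
                 rrm_window = rrm_window, passes = as.integer(passes)),
            class = "smoothing_params")
}

resolve_window <- function(params, n) {
  w <- if (!is.null(params$lowess_span)) {
    w <- max(3L, round(params$lowess_span * n))
    as.integer(w + (1L - w %% 2L))  # force odd
  } else params$lowess_window
  w
}

repeated_running_median <- function(x, window, passes) {
  if (length(x) <= window) return(x)
  for (p in seq_len(passes))
    x <- stats::runmed(x, window, endrule = "median")
  as.numeric(x)
}

# Tricube-weighted local polynomial regression on an equally spaced series.
# degree 1 returns fitted values and slopes (d/dt); degree 2 additionally
# returns second derivatives. Interior points use a symmetric window of
# `window` frames (fixed convolution kernels); the first/last half-window
# points use shrinking asymmetric windows fitted by weighted least squares.
local_poly <- function(y, dt, window, degree = 1L) {
  n <- length(y)
  if (n < window)
    stop(sprintf("series of length %d is shorter than the smoothing window; need at least %d points",
                 n, window))
  h <- (window - 1L) %/% 2L
  j <- -h:h
  w <- (1 - (abs(j) / (h + 1))^3)^3
  x <- j * dt
  sm <- numeric(n); dv <- numeric(n)
  d2 <- if (degree >= 2L) numeric(n) else NULL
  interior <- (h + 1L):(n - h)
  if (length(interior)) {
    T0 <- numeric(length(interior)); T1 <- T0; T2 <- T0
    for (m in seq_along(j)) {
      ym <- y[interior + j[m]]
      T0 <- T0 + w[m] * ym
      T1 <- T1 + (w[m] * x[m]) * ym
      if (degree >= 2L) T2 <- T2 + (w[m] * x[m]^2) * ym
    }
    S0 <- sum(w); S2 <- sum(w * x^2)
    if (degree == 1L) {
      sm[interior] <- T0 / S0
      dv[interior] <- T1 / S2
    } else {
      S4 <- sum(w * x^4)
      den <- S0 * S4 - S2^2
      sm[interior] <- (S4 * T0 - S2 * T2) / den
      dv[interior] <- T1 / S2
      d2[interior] <- 2 * (S0 * T2 - S2 * T0) / den
    }
  }
  edge_fit <- function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    jj <- (lo:hi) - i
    ww <- (1 - (abs(jj) / (max(abs(jj)) + 1))^3)^3
    xx <- jj * dt; yy <- y[lo:hi]
    deg <- min(degree, length(yy) - 1L)
    if (deg < 1L) return(c(yy[1L], 0, 0))
    X <- stats::poly(xx, degree = deg, raw = TRUE, simple = TRUE)
    fit <- stats::lm.wfit(cbind(1, X), yy, ww)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    c(cf[1L], cf[2L], if (deg >= 2L) 2 * cf[3L] else 0)
  }
  for (i in c(seq_len(min(h, n)), if (n > h) (n - h + 1L):n)) {
    abq <- edge_fit(i)
    sm[i] <- abq[1L]; dv[i] <- abq[2L]
    if (degree >= 2L) d2[i] <- abq[3L]
  }
  list(smoothed = sm, deriv = dv, deriv2 = d2)
}

local_linear <- function(y, dt, window) local_poly(y, dt, window, 1L)

# last-observation-carried-forward (then backward for a leading NA run);
# all-NA input becomes zeros
fill_hold <- function(x) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) return(rep(0, length(x)))
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  first <- which(idx > 0L)[1L]
  idx[seq_len(first - 1L)] <- which(!is.na(x))[1L]
  x[idx]
}

#' Smooth a series and estimate its time derivative
#'
#' Applies repeated running medians (despiking) followed by tricube-weighted
#' local linear regression, whose local slope is a reliable estimate of the
#' numerical derivative of the underlying signal. Deterministic for fixed
#' parameters; endpoints are handled with shrinking windows. The input must
#' have no internal missing values (gaps are handled upstream by smoothing
#' each valid segment separately).
#'
#' @param values numeric series, equally spaced in time.
#' @param dt time step, seconds.
#' @param params a [smoothing_params()].
#' @param degree local-regression degree (1, or 2 to also estimate the
#'   second derivative).
#' @return list with `smoothed`, `deriv` (per-second) and, for `degree = 2`,
#'   `deriv2` components.
#' @export
smooth_series <- function(values, dt, params = smoothing_params(),
                          degree = 1L) {
  if (anyNA(values)) stop("series contains missing values; smooth per segment")
  n <- length(values)
  if (n <= params$rrm_window)
    stop(sprintf("series of length %d too short; need more than %d points",
                 n, params$rrm_window))
  window <- resolve_window(params, n)
  y <- repeated_running_median(values, params$rrm_window, params$passes)
  local_poly(y, dt, window, degree)
}

#' Translation kinematics from smoothed positions
#'
#' Computes speed `v_c = sqrt(xdot^2 + ydot^2)` and the direction of the
#' instantaneous velocity vector `alpha_v = atan2(ydot, xdot)` (degrees).
#' `alpha_v` is unwrapped to a continuous series, re-smoothed by the same
#' procedure, and the slope of that fit is returned as the angular velocity
#' of the velocity vector, `omega_v`. `alpha_v` and `omega_v` are undefined
#' (`NA`) where speed is below the arrest tolerance `eps_v`. Note the
#' cascade of two smoothing stages makes `omega_v` the most heavily
#' low-passed signal of the series (see the vignette on temporal
#' resolution).
#'
#' @param x,y raw centroid coordinate series (mm), one gap-free segment.
#' @param dt time step, s.
#' @param params a [smoothing_params()].
#' @param eps_v arrest tolerance on speed, mm/s.
#' @param dir_min_speed mm/s below which the instantaneous direction is
#'   noise-dominated and the last reliable direction is held instead.
#' @return data.frame with `x_s, y_s, v_c, alpha_v` (unwrapped smoothed
#'   direction of progression, deg), `omega_v` (deg/s).
#' @export
compute_translation_kinematics <- function(x, y, dt,
                                           params = smoothing_params(),
                                           eps_v = 2, dir_min_speed = 3) {
  sx <- smooth_series(x, dt, params)
  sy <- smooth_series(y, dt, params)
  v_c <- sqrt(sx$deriv^2 + sy$deriv^2)
  av_raw <- rad2deg(atan2(sy$deriv, sx$deriv))
  # the direction of a near-zero velocity vector is pure noise: hold the
  # last reliable direction through slow stretches so it cannot leak into
  # the re-smoothing of neighboring moving frames
  av_raw[v_c < max(dir_min_speed, eps_v)] <- NA
  av_raw <- fill_hold(av_raw)
  av_un <- unwrap_angle(av_raw)
  sa <- smooth_series(av_un, dt, params)
  alpha_v <- sa$smoothed
  omega_v <- sa$deriv
  und <- v_c < eps_v
  alpha_v[und] <- NA_real_
  omega_v[und] <- NA_real_
  data.frame(x_s = sx$smoothed, y_s = sy$smoothed, v_c = v_c,
             alpha_v = alpha_v, omega_v = omega_v)
}

#' Rotation kinematics from the directed body orientation
#'
#' Unwraps the head/tail-resolved body orientation into a continuous series
#' (so cumulative rotations beyond 360 degrees are preserved), smooths it,
#' and returns the smoothed series together with its derivative, the angular
#' velocity of body rotation `omega_b`.
#'
#' @param alpha_b directed body orientation series, degrees, one gap-free
#'   segment.
#' @param dt time step, s.
#' @param params a [smoothing_params()].
#' @return data.frame with `alpha_b_s` (unwrapped, deg) and `omega_b` (deg/s).
#' @export
compute_rotation_kinematics <- function(alpha_b, dt,
                                        params = smoothing_params()) {
  un <- unwrap_angle(alpha_b)
  s <- smooth_series(un, dt, params)
  data.frame(alpha_b_s = s$smoothed, omega_b = s$deriv)
}

#' Full per-frame kinematic series for an oriented trajectory
#'
#' Runs [compute_translation_kinematics()] and
#' [compute_rotation_kinematics()] on every wall-to-wall segment of a
#' head/tail-resolved trajectory. Segments shorter than the smoothing window
#' cannot be differentiated and are marked invalid.
#'
#' @param otraj output of [resolve_head_tail()].
#' @param params a [smoothing_params()].
#' @param eps_v arrest tolerance on speed, mm/s.
#' @return a `data.frame` of class `kinematic_series` with columns
#'   `t, x_s, y_s, v_c, alpha_v, omega_v, alpha_b_s, omega_b, valid,
#'   segment_id`; attribute `dt`.
#' @export
compute_kinematics <- function(otraj, params = smoothing_params(),
                               eps_v = 2) {
  n <- nrow(otraj)
  dt <- traj_dt(otraj)
  out <- data.frame(t = otraj$t, x_s = NA_real_, y_s = NA_real_,
                    v_c = NA_real_, alpha_v = NA_real_, omega_v = NA_real_,
                    alpha_b_s = NA_real_, omega_b = NA_real_,
                    valid = FALSE, segment_id = otraj$wall_segment_id)
  for (s in unique(stats::na.omit(otraj$wall_segment_id))) {
    idx <- which(otraj$wall_segment_id == s)
    min_len <- max(resolve_window(params, length(idx)),
                   params$rrm_window + 1L)
    if (length(idx) < min_len) next
    tr <- compute_translation_kinematics(otraj$x[idx], otraj$y[idx], dt,
                                         params, eps_v)
    ro <- compute_rotation_kinematics(otraj$alpha_b[idx], dt, params)
    out[idx, c("x_s", "y_s", "v_c", "alpha_v", "omega_v")] <- tr
    out[idx, c("alpha_b_s", "omega_b")] <- ro
    out$valid[idx] <- TRUE
  }
  attr(out, "dt") <- dt
  class(out) <- c("kinematic_series", "data.frame")
  out
}
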