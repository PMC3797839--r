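#' Build a mode script for the synthetic-session generator
#'
#' A mode script is an ordered list of steps, each holding a mode letter, a
#' duration and the kinematic parameters realizing that mode: forward speed,
#' path curvature (angular velocity of the direction of progression), body
#' rotation rate, and optionally the angular interval `phi` imposed at step
#' onset (e.g. `phi0 = 180` plants a backward-walking bout). Steps with
#' `mode = "free"` have no planted label: their body orientation follows the
#' direction of progression through the gain model (see
#' [generate_session()]), which is how drugged low-gain dynamics are
#' emulated.
#'
#' @param ... steps created by [script_step()].
#' @return object of class `mode_script` (a data.frame of steps).
#' @export
mode_script <- function(...) {
  steps <- rbind(...)
  stopifnot(nrow(steps) >= 1L)
  class(steps) <- c("mode_script", "data.frame")
  steps
}

#' @rdname mode_script
#' @param mode one of `A B C D L R` or `"free"`.
#' @param duration step duration, s.
#' @param speed forward speed, mm/s.
#' @param curvature path curvature, deg/s (rate of change of the direction
#'   of progression).
#' @param rotation scripted body rotation, deg/s.
#' @param phi0 angular interval imposed at step onset, deg (`NA`, the
#'   default: continue the current path direction). Body orientation is
#'   always continuous -- a fly cannot teleport its body axis -- so `phi0`
#'   redirects the *path*: the direction of progression becomes
#'   `alpha_b + phi0` in a single frame. `phi0 = 180` is the one-frame
#'   velocity reversal signature of a backward-walking bout.
#' @param follow should the gain model steer body orientation toward the
#'   direction of progression during this step (always `TRUE` for
#'   `"free"`)?
#' @export
script_step <- function(mode, duration,
                        speed = NULL, curvature = NULL, rotation = NULL,
                        phi0 = NULL, follow = NULL) {
  defaults <- list(
    A = list(speed = 10, curvature = 0, rotation = 0),
    B = list(speed = 10, curvature = 0, rotation = 45),
    C = list(speed = 10, curvature = 40, rotation = 0),
    D = list(speed = 10, curvature = 40, rotation = 45),
    L = list(speed = 0, curvature = 0, rotation = 0),
    R = list(speed = 0, curvature = 0, rotation = 45),
    free = list(speed = 10, curvature = 0, rotation = 0))
  stopifnot(mode %in% names(defaults), duration > 0)
  d <- defaults[[mode]]
  data.frame(mode = mode, duration = duration,
             speed = if (is.null(speed)) d$speed else speed,
             curvature = if (is.null(curvature)) d$curvature else curvature,
             rotation = if (is.null(rotation)) d$rotation else rotation,
             phi0 = if (is.null(phi0)) NA_real_ else phi0,
             follow = if (mode == "free") TRUE
                      else if (is.null(follow)) FALSE else follow)
}

# Planted per-step spatial spread of the center path (straight-line or chord)
step_spread <- function(speed, curvature, duration) {
  if (speed <= 0) return(0)
  if (abs(curvature) < 1e-9) return(speed * duration)
  radius <- speed / deg2rad(abs(curvature))
  turn <- min(abs(curvature) * duration, 180)
  2 * radius * sin(deg2rad(turn) / 2)
}

validate_script <- function(script, thr) {
  for (i in seq_len(nrow(script))) {
    st <- script[i, ]
    fail <- function(msg)
      stop(sprintf("script step %d (mode %s): %s", i, st$mode, msg))
    if (st$mode == "free") next
    prog <- st$mode %in% c("A", "B", "C", "D")
    rot <- st$mode %in% c("B", "D", "R")
    curv <- st$mode %in% c("C", "D")
    if (prog) {
      if (st$speed <= thr$eps_v)
        fail("progressing mode needs speed above the arrest tolerance")
      if (step_spread(st$speed, st$curvature, st$duration) <= thr$d_ling)
        fail("planted spatial spread does not exceed d_ling")
    } else if (st$speed > thr$eps_v)
      fail("non-progressing mode must not translate")
    if (rot) {
      if (abs(st$rotation) <= thr$eps_omega ||
          abs(st$rotation) * st$duration <= thr$theta_ling)
        fail("planted body rotation does not exceed theta_ling")
    } else if (abs(st$rotation) > thr$eps_omega)
      fail("non-rotating mode must keep body rotation within tolerance")
    if (curv) {
      if (abs(st$curvature) <= thr$eps_omega ||
          abs(st$curvature) * st$duration <= thr$psi_str)
        fail("planted path curvature does not exceed psi_str")
    } else if (abs(st$curvature) > thr$eps_omega)
      fail("straight-path mode must keep curvature within tolerance")
  }
  invisible(TRUE)
}

#' Gain model and noise for synthetic sessions
#'
#' The gain is the rate (1/s) at which body orientation relaxes toward the
#' direction of progression, `d alpha_b/dt = gain * wrap(alpha_v - alpha_b)`.
#' Intact flies behave as a high-gain system (the front snaps onto a changed
#' direction of progression); alcohol and, much more strongly, cocaine lower
#' the gain, leaving the body lagging ("slow chasing") and widening the
#' angular interval.
#'
#' @param gain relaxation rate, 1/s (`>= 0`).
#' @param noise_pos positional noise sd, mm.
#' @param noise_angle body-axis angle noise sd, deg.
#' @param seed integer RNG seed.
#' @return object of class `gain_model`.
#' @export
gain_model <- function(gain = 0, noise_pos = 0, noise_angle = 0, seed = 1) {
  stopifnot(gain >= 0, noise_pos >= 0, noise_angle >= 0)
  structure(list(gain = gain, noise_pos = noise_pos,
                 noise_angle = noise_angle, seed = as.integer(seed)),
            class = "gain_model")
}

#' Generate a tracker-format session with ground truth
#'
#' Euler-integrates the scripted center motion and body orientation at the
#' arena frame rate, then restores the tracker's head/tail ambiguity by
#' emitting only the axis-valued angle `alpha1 = alpha_b mod 180` plus
#' additive Gaussian noise. Ground-truth per-frame mode letters, angular
#' intervals and codes are returned alongside, so every stage of the
#' analysis pipeline can be validated. When a step would carry the fly into
#' the wall zone the direction of progression (and the body orientation with
#' it, preserving the angular interval) is re-aimed toward the arena center;
#' such frames are recorded in `wall_events`. Deterministic given the seed.
#'
#' @param script a [mode_script()].
#' @param gain a [gain_model()].
#' @param arena an [arena_geometry()].
#' @param start starting coordinates, mm (default: arena center).
#' @param alpha_v0 initial direction of progression, deg.
#' @param thr a [threshold_set()] used to validate that scripted parameters
#'   realize their modes' defining predicates.
#' @param wall_margin mm distance-from-wall at which re-aiming triggers.
#' @return object of class `synthetic_session`: list with `trajectory` (a
#'   [raw_trajectory()]), `truth` (frame, t, mode, phi, code, step),
#'   `clean` (noise-free x, y, alpha_v, alpha_b), `wall_events`, `script`,
#'   `gain`, `arena`.
#' @export
generate_session <- function(script, gain = gain_model(),
                             arena = arena_geometry(), start = NULL,
                             alpha_v0 = 0, thr = threshold_set(),
                             wall_margin = 15) {
  validate_script(script, thr)
  dt <- 1 / arena$frame_rate
  nf <- pmax(1L, as.integer(round(script$duration / dt)))
  n <- sum(nf)
  x <- y <- av <- ab <- numeric(n)
  mode <- character(n); stepi <- integer(n)
  wall_events <- integer(0)
  cx <- if (is.null(start)) arena$x_center else start[1]
  cy <- if (is.null(start)) arena$y_center else start[2]
  cav <- alpha_v0
  cab <- alpha_v0
  f <- 0L
  for (i in seq_len(nrow(script))) {
    st <- script[i, ]
    if (!is.na(st$phi0) && st$speed > 0) cav <- cab + st$phi0
    for (k in seq_len(nf[i])) {
      f <- f + 1L
      if (st$speed > 0 &&
          distance_from_wall(cx + st$speed * cos(deg2rad(cav)) * dt,
                             cy + st$speed * sin(deg2rad(cav)) * dt,
                             arena) < wall_margin) {
        home <- rad2deg(atan2(arena$y_center - cy, arena$x_center - cx))
        delta <- wrap_angle(home - cav)
        cav <- cav + delta
        cab <- cab + delta  # preserve the angular interval
        wall_events <- c(wall_events, f)
      }
      x[f] <- cx; y[f] <- cy; av[f] <- cav; ab[f] <- cab
      mode[f] <- st$mode; stepi[f] <- i
      cx <- cx + st$speed * cos(deg2rad(cav)) * dt
      cy <- cy + st$speed * sin(deg2rad(cav)) * dt
      if (st$speed > 0) cav <- cav + st$curvature * dt
      abdot <- st$rotation +
        if (st$follow) gain$gain * wrap_angle(cav - cab) else 0
      cab <- cab + abdot * dt
    }
  }
  set.seed(gain$seed)
  xo <- x + stats::rnorm(n, 0, gain$noise_pos)
  yo <- y + stats::rnorm(n, 0, gain$noise_pos)
  a1 <- (ab + stats::rnorm(n, 0, gain$noise_angle)) %% 180
  spd <- script$speed[stepi]
  prog <- mode %in% c("A", "B", "C", "D") | (mode == "free" & spd > 0)
  phi <- ifelse(prog, wrap_angle(av - ab), NA_real_)
  truth <- data.frame(frame = seq_len(n), t = (seq_len(n) - 1L) * dt,
                      mode = ifelse(mode == "free", NA_character_, mode),
                      phi = phi,
                      code = digitize_interval(phi, lingering = !prog),
                      step = stepi)
  truth$code[mode == "free"] <- NA_integer_
  structure(list(
    trajectory = raw_trajectory(t = truth$t, x = xo, y = yo, alpha1 = a1),
    truth = truth,
    clean = data.frame(x = x, y = y, alpha_v = av, alpha_b = ab),
    wall_events = wall_events, script = script, gain = gain,
    arena = arena), class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %d frames, %d script steps, gain %g/s\n",
              nrow(x$truth), nrow(x$script), x$gain$gain))
  invisible(x)
}

#' Transition frames of a synthetic session
#'
#' The frames at which the planted per-frame labels change regime: the last
#' frame of each script step plus any wall re-aim events (a re-aim is an
#' unscripted step change of the path direction). Frame-accurate recovery of
#' planted labels is only expected outside a small buffer around these
#' frames, since any smoother spreads a discontinuity over its window.
#'
#' @param session a [generate_session()] result.
#' @return sorted integer frame indices.
#' @export
session_transitions <- function(session) {
  steps <- session$truth$step
  sort(unique(c(which(diff(steps) != 0L), session$wall_events)))
}

#' Draw samples from a planted Gaussian mixture
#'
#' Fixture generator for threshold-recovery experiments: i.i.d. draws from a
#' specified mixture together with the planted intersection point between
#' the two rightmost components, computed with the package's analytic
#' solver.
#'
#' @param weights,means,sds mixture parameters (recycled to equal length).
#' @param n number of draws (`>= 1`).
#' @param seed integer RNG seed.
#' @return list with `values`, `intersection` and the sorted `components`.
#' @export
generate_mixture_samples <- function(weights, means, sds, n, seed = 1) {
  k <- length(means)
  stopifnot(k >= 2, length(weights) == k, length(sds) == k, n >= 1,
            all(sds > 0), all(weights > 0))
  weights <- weights / sum(weights)
  o <- order(means)
  fit <- structure(list(k = k, weights = weights[o], means = means[o],
                        sds = sds[o]), class = "gaussian_mixture_fit")
  set.seed(seed)
  comp <- sample.int(k, n, replace = TRUE, prob = weights[o])
  list(values = stats::rnorm(n, fit$means[comp], fit$sds[comp]),
       intersection = mixture_intersection(fit, c(k - 1L, k),
                                           fallback = TRUE),
       components = fit)
}

#' A reference script exercising all six coordination modes
#'
#' A meandering session visiting every mode (lingering, straight and curved
#' progression, each with and without body rotation, and rotation in place)
#' while staying in the central region of the default arena. Curvature
#' changes are bracketed by arrests, matching the temporal resolution of the
#' two-stage smoothing of the path-direction signal, so planted labels are
#' recoverable to within a couple of frames of each transition.
#'
#' @return a [mode_script()] of about 17 s.
#' @export
six_mode_script <- function() {
  mode_script(
    script_step("L", 1.5), script_step("A", 1.5),
    script_step("B", 1.5, rotation = 40), script_step("A", 1.5),
    script_step("L", 1), script_step("C", 2, curvature = 60),
    script_step("L", 1), script_step("R", 1.5),
    script_step("D", 2, curvature = 60, rotation = 40),
    script_step("L", 1), script_step("A", 1.5),
    script_step("B", 1.2, rotation = -40), script_step("L", 1))
}

#' A fixed turning path for gain-contrast experiments
#'
#' A script of alternating-curvature `"free"` steps on which body
#' orientation is driven purely by the gain model; running it under
#' different gains and comparing the mean absolute angular interval
#' reproduces the intact (high gain) vs drugged (low gain) contrast.
#'
#' @param n_legs number of alternating curved legs.
#' @param leg_duration s per leg.
#' @param speed mm/s.
#' @param curvature deg/s, sign alternating between legs.
#' @return a [mode_script()].
#' @export
turning_path_script <- function(n_legs = 6, leg_duration = 1.5, speed = 15,
                                curvature = 45) {
  steps <- lapply(seq_len(n_legs), function(i)
    script_step("free", leg_duration, speed = speed,
                curvature = curvature * (-1)^(i - 1)))
  do.call(mode_script, steps)
}
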