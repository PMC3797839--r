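#' Run the full analysis pipeline on a raw trajectory
#'
#' Masks wall-contact and jump frames, resolves the head/tail ambiguity,
#' computes the smoothed kinematic series, classifies every frame into one
#' of the six coordination modes, computes and digitizes the angular
#' interval, encodes the symbolic sequence, and extracts movement segments
#' with their start/midsection/end phases.
#'
#' @param raw a [raw_trajectory()].
#' @param arena an [arena_geometry()].
#' @param thr a [threshold_set()].
#' @param params a [smoothing_params()].
#' @param mask apply [mask_wall_and_jumps()] first.
#' @param jump_speed mm/s jump exclusion threshold.
#' @return object of class `fly_session`: list with `trajectory` (oriented),
#'   `kinematics`, `letters`, `phi`, `codes`, `sequence`, `segments`
#'   (movement segments), `phases` (per-frame factor, `NA` outside movement
#'   segments), `thresholds`.
#' @export
analyze_session <- function(raw, arena = arena_geometry(),
                            thr = threshold_set(),
                            params = smoothing_params(), mask = TRUE,
                            jump_speed = 200) {
  if (mask)
    raw <- mask_wall_and_jumps(raw, arena, thr$wall_boundary, jump_speed)
  ot <- resolve_head_tail(raw, min_speed = thr$eps_v)
  kin <- compute_kinematics(ot, params, eps_v = thr$eps_v)
  letters <- classify_frames(kin, thr)
  ai <- compute_angular_interval(kin, letters)
  sq <- encode_symbolic(letters, ai$code)
  segs <- movement_segments(kin, thr)
  phases <- factor(rep(NA_character_, nrow(kin)),
                   levels = c("start", "midsection", "end"))
  for (i in seq_len(nrow(segs))) {
    fr <- segs$start[i]:segs$end[i]
    phases[fr] <- partition_phases(kin$v_c[fr])
  }
  structure(list(trajectory = ot, kinematics = kin, letters = letters,
                 phi = ai$phi, codes = ai$code, sequence = sq,
                 segments = segs, phases = phases, thresholds = thr),
            class = "fly_session")
}

#' @export
print.fly_session <- function(x, ...) {
  n <- nrow(x$kinematics)
  tab <- table(factor(x$letters, levels = MODE_LETTERS))
  cat(sprintf("Fly session: %d frames (%.1f s), %d movement segment(s)\n",
              n, n * attr(x$kinematics, "dt"), nrow(x$segments)))
  cat("mode usage (frames): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Summarize a session: proportions, stages, episodes, transitions
#'
#' Collects the descriptive outputs of a session: phase-wise mode-usage
#' proportions, per-movement-segment rotational shares and drug-stage
#' labels, rotational-episode statistics with their 0.95 quantile of
#' cumulative angles, and the 6x6 mode-transition matrix. Transitions are
#' counted on midsection frames only (the relatively stationary part of a
#' movement segment) and never across gaps longer than `max_gap` frames.
#'
#' @param ses a [analyze_session()] result.
#' @param min_len minimum cluster length, frames.
#' @param max_gap largest frame gap across which a transition is counted.
#' @return list with `mode_proportions`, `segments`, `episodes`,
#'   `episode_q95` (deg), `transitions`.
#' @export
session_report <- function(ses, min_len = 3L, max_gap = 12L) {
  mup <- mode_usage_proportions(ses$letters, ses$phases)
  stages <- stage_movement_segments(ses$kinematics, ses$letters,
                                    ses$thresholds)
  eps <- rotation_episode_stats(ses$kinematics, ses$thresholds)
  mid <- ifelse(!is.na(ses$phases) & ses$phases == "midsection",
                ses$letters, NA_character_)
  cl <- find_clusters(list(letters = mid, codes = ses$codes), min_len)
  list(mode_proportions = mup, segments = stages, episodes = eps,
       episode_q95 = if (nrow(eps))
         unname(stats::quantile(eps$cumulative_angle, 0.95)) else NA_real_,
       transitions = build_transition_matrix(cl, max_gap = max_gap))
}

#' Plot a session path colored by mode
#'
#' Basic diagnostic plot: the smoothed center path, colored by the six
#' coordination modes, with the arena outline.
#'
#' @param x a [analyze_session()] result.
#' @param arena an [arena_geometry()] for the outline (optional).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fly_session <- function(x, arena = NULL, ...) {
  kin <- x$kinematics
  cols <- c(A = "black", B = "red", C = "dodgerblue", D = "purple",
            L = "grey60", R = "orange")
  graphics::plot(kin$x_s, kin$y_s, type = "n", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  if (!is.null(arena)) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(arena$x_center + arena$r_arena * cos(th),
                    arena$y_center + arena$r_arena * sin(th),
                    col = "grey70")
  }
  graphics::points(kin$x_s, kin$y_s, pch = 16, cex = 0.4,
                   col = cols[x$letters])
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(x)
}
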