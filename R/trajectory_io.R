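#' Arena geometry
#'
#' Describes the circular open-field arena in which a fly is tracked. All
#' downstream distances-from-wall and wall masking are computed against this
#' geometry.
#'
#' @param x_center,y_center arena center, mm.
#' @param r_arena arena radius, mm (default 75, a 15 cm arena).
#' @param frame_rate acquisition rate, Hz (default 25, i.e. 40 ms frames).
#' @return an object of class `arena_geometry`.
#' @export
arena_geometry <- function(x_center = 0, y_center = 0, r_arena = 75,
                           frame_rate = 25) {
  stopifnot(is.numeric(r_arena), r_arena > 0,
            is.numeric(frame_rate), frame_rate > 0)
  structure(list(x_center = x_center, y_center = y_center,
                 r_arena = r_arena, frame_rate = frame_rate),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("Circular arena: center (%g, %g) mm, radius %g mm, %g Hz\n",
              x$x_center, x$y_center, x$r_arena, x$frame_rate))
  invisible(x)
}

#' Raw tracked trajectory
#'
#' Per-frame centroid coordinates and the axis-valued body angle as produced
#' by axis-tracking software. The body-axis angle is only defined up to a 180
#' degree ambiguity (the tracker cannot tell head from tail); see
#' [resolve_head_tail()].
#'
#' @param t time in seconds, strictly increasing with constant step.
#' @param x,y centroid coordinates, mm.
#' @param alpha1 body-axis angle, degrees; stored modulo 180 in `[0, 180)`.
#' @param valid logical per-frame validity flag.
#' @return a `data.frame` of class `raw_trajectory` with columns
#'   `t, x, y, alpha1, valid` and attribute `dt` (the frame step, s).
#' @export
raw_trajectory <- function(t, x, y, alpha1, valid = NULL) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(alpha1) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & is.finite(x) & is.finite(y) & is.finite(alpha1)
  if (n > 1L) {
    dts <- diff(t)
    if (any(dts <= 0)) stop("time must be strictly increasing")
    if (diff(range(dts)) > 1e-6 * mean(dts))
      stop("time must have a constant step")
    dt <- mean(dts)
  } else dt <- NA_real_
  out <- data.frame(t = t, x = x, y = y, alpha1 = alpha1 %% 180,
                    valid = valid)
  attr(out, "dt") <- dt
  class(out) <- c("raw_trajectory", "data.frame")
  out
}

traj_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt) || is.na(dt)) dt <- stats::median(diff(traj$t))
  dt
}

#' Read a tracker output table
#'
#' Reads a delimited (CSV/TSV) per-frame tracking table with at least
#' frame-or-time, x, y and body-axis-angle columns, converts coordinates to mm
#' and normalizes the axis angle to `[0, 180)`. Rows with missing coordinates
#' or angle are kept but flagged invalid; rows with unparseable numeric fields
#' are an error (their line numbers are reported).
#'
#' @param path file path of the delimited table (delimiter auto-detected
#'   among comma, tab, semicolon and whitespace; header required).
#' @param arena an [arena_geometry()]; supplies the frame rate used to convert
#'   frame indices to seconds.
#' @param scale mm per coordinate unit (e.g. 1/1.5 for 1.5 px/mm tracking).
#' @param columns named character vector mapping the canonical names
#'   `frame, x, y, angle` (and optionally `valid`) to column names in the
#'   file.
#' @param time_unit `"auto"` (frame column treated as frame indices when all
#'   values are integers, otherwise as seconds), `"frames"` or `"seconds"`.
#' @return a [raw_trajectory()].
#' @export
read_trajectory <- function(path, arena = arena_geometry(), scale = 1,
                            columns = c(frame = "frame", x = "x", y = "y",
                                        angle = "angle"),
                            time_unit = c("auto", "frames", "seconds")) {
  time_unit <- match.arg(time_unit)
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header)) "," else if (grepl("\t", header)) "\t"
         else if (grepl(";", header)) ";" else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("frame", "x", "y", "angle")
  miss <- setdiff(need, names(columns))
  if (length(miss))
    stop("column mapping must name: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(columns), names(tab))
  if (length(absent))
    stop("file lacks mapped column(s): ", paste(absent, collapse = ", "))

  num <- function(col) {
    raw <- tab[[columns[[col]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & raw != "NA" & is.na(val))
    if (length(bad))
      stop(sprintf("unparseable '%s' values at line(s): %s", col,
                   paste(bad + 1L, collapse = ", ")))  # +1 for header line
    val
  }
  fr <- num("frame"); x <- num("x"); y <- num("y"); ang <- num("angle")
  if (any(is.na(fr))) stop("frame/time column contains missing values")
  if (any(diff(fr) <= 0)) stop("frame/time column is not strictly increasing")
  as_frames <- switch(time_unit,
    frames = TRUE, seconds = FALSE,
    auto = all(abs(fr - round(fr)) < 1e-9))
  t <- if (as_frames) fr / arena$frame_rate else fr
  valid <- if ("valid" %in% names(columns)) {
    v <- tab[[columns[["valid"]]]]
    !(v %in% c("0", "FALSE", "false", "F"))
  } else rep(TRUE, nrow(tab))
  raw_trajectory(t = t, x = x * scale, y = y * scale, alpha1 = ang,
                 valid = valid)
}

#' Write a trajectory or kinematics table to a delimited file
#'
#' @param x a data.frame (e.g. [raw_trajectory()], the output of
#'   [resolve_head_tail()] or [compute_kinematics()]).
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @export
write_trajectory <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Distance from the arena wall
#'
#' `d_i = R_arena - sqrt((x - x_center)^2 + (y - y_center)^2)`; negative
#' values indicate coordinates outside the nominal arena radius.
#'
#' @param x,y coordinates, mm.
#' @param arena an [arena_geometry()].
#' @return numeric vector of distances from the wall, mm.
#' @export
distance_from_wall <- function(x, y, arena) {
  arena$r_arena - sqrt((x - arena$x_center)^2 + (y - arena$y_center)^2)
}

#' Mask wall-contact and jump frames
#'
#' Flies climbing the wall are vertical and physically constrained, and jumps
#' are not planar walking; both are excluded from analysis. A frame is wall
#' contact when its distance from the wall is below `wall_boundary`. A frame
#' is a jump spike when both its incoming and outgoing frame-to-frame
#' displacements imply a speed above `jump_speed`; this marks the displaced
#' frame itself while leaving its neighbors valid, and is idempotent.
#'
#' @param raw a [raw_trajectory()].
#' @param arena an [arena_geometry()].
#' @param wall_boundary mm distance-from-wall below which a frame counts as
#'   wall contact (re-derivable from data via [partition_arena_zones()]).
#' @param jump_speed mm/s above which a displacement is not walking.
#' @return the trajectory with offending frames flagged invalid; all other
#'   flags preserved.
#' @export
mask_wall_and_jumps <- function(raw, arena, wall_boundary = 3,
                                jump_speed = 200) {
  stopifnot(wall_boundary >= 0, jump_speed > 0)
  d <- distance_from_wall(raw$x, raw$y, arena)
  wall <- !is.na(d) & d < wall_boundary
  n <- nrow(raw)
  jump <- rep(FALSE, n)
  if (n >= 3L) {
    dt <- traj_dt(raw)
    sp <- sqrt(diff(raw$x)^2 + diff(raw$y)^2) / dt  # sp[i]: speed i -> i+1
    mid <- 2:(n - 1L)
    jump[mid] <- !is.na(sp[mid - 1L]) & !is.na(sp[mid]) &
      sp[mid - 1L] > jump_speed & sp[mid] > jump_speed
  }
  raw$valid <- raw$valid & !wall & !jump
  raw
}

#' Resolve the head/tail ambiguity of the body axis
#'
#' The tracker reports the body axis as an angle `alpha1` with period 180
#' degrees: `alpha1` and `alpha1 + 180` describe the same axis and either
#' could be the head direction. Within each wall-to-wall segment (maximal run
#' of valid frames between wall/jump exclusions) the frame of maximum raw
#' centroid speed is taken as the reference: at high speed the head faces the
#' direction of progression. The head direction at the reference frame is the
#' conjugate angle closest to the velocity direction there, and is propagated
#' forward and backward by always choosing the conjugate that minimizes the
#' wrap-aware frame-to-frame change in orientation -- a fly does not rotate
#' its body by 180 degrees in 40 ms. A reversal of the velocity vector within
#' one frame therefore leaves the body orientation continuous and is read
#' downstream as backward walking.
#'
#' Segments whose maximum speed never reaches `min_speed` carry no reliable
#' progression direction; their orientation is resolved only up to conjugacy
#' and flagged `ambiguous`.
#'
#' @param raw a [raw_trajectory()] (typically after [mask_wall_and_jumps()]).
#' @param min_speed mm/s; reference frames must move at least this fast.
#' @return the trajectory with columns `alpha_b` (directed body orientation,
#'   degrees in `[0, 360)`), `wall_segment_id` (integer, `NA` on invalid
#'   frames) and `ambiguous` added.
#' @export
resolve_head_tail <- function(raw, min_speed = 1) {
  n <- nrow(raw)
  dt <- traj_dt(raw)
  alpha_b <- rep(NA_real_, n)
  seg_id <- rep(NA_integer_, n)
  ambig <- rep(FALSE, n)
  r <- rle(raw$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    k <- k + 1L
    idx <- starts[i]:ends[i]
    seg_id[idx] <- k
    m <- length(idx)
    ax <- unwrap_axis(raw$alpha1[idx])  # continuous axis, |step| < 90 deg
    if (m < 2L) {
      alpha_b[idx] <- ax %% 360
      ambig[idx] <- TRUE
      next
    }
    xx <- raw$x[idx]; yy <- raw$y[idx]
    # centered-difference raw speed and direction (one-sided at the edges)
    lo <- pmax(seq_len(m) - 1L, 1L); hi <- pmin(seq_len(m) + 1L, m)
    dx <- xx[hi] - xx[lo]; dy <- yy[hi] - yy[lo]
    sp <- sqrt(dx^2 + dy^2) / ((hi - lo) * dt)
    ref <- which.max(sp)  # ties: earliest frame
    vdir <- rad2deg(atan2(dy[ref], dx[ref]))
    flip <- angle_dist(ax[ref], vdir) > 90
    alpha_b[idx] <- (ax + if (flip) 180 else 0) %% 360
    if (sp[ref] < min_speed) ambig[idx] <- TRUE
  }
  out <- raw
  out$alpha_b <- alpha_b
  out$wall_segment_id <- seg_id
  out$ambiguous <- ambig
  class(out) <- c("oriented_trajectory", class(raw))
  out
}
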