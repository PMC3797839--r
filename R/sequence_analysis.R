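#' Find mode-specific clusters in a symbolic sequence
#'
#' Clusters are maximal runs of successive frames sharing the same mode
#' letter; runs of at least `min_len` frames (the `{3,}` quantifier of the
#' cluster pattern) are clusters, shorter runs are sub-clusters. Together
#' with gaps they partition the frames losslessly.
#'
#' @param seq a [encode_symbolic()] result (or anything with `letters` and
#'   `codes`).
#' @param min_len minimum cluster length in frames.
#' @return data.frame with `mode`, `start`, `end`, `length`, `is_cluster`
#'   and digit-count columns `n0..n4, n9`, in temporal order.
#' @export
find_clusters <- function(seq, min_len = 3L) {
  letters <- seq$letters
  codes <- seq$codes
  empty <- data.frame(mode = character(), start = integer(),
                      end = integer(), length = integer(),
                      is_cluster = logical(),
                      n0 = integer(), n1 = integer(), n2 = integer(),
                      n3 = integer(), n4 = integer(), n9 = integer())
  if (!length(letters)) return(empty)
  key <- ifelse(is.na(letters), "-", letters)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != "-")
  if (!length(keep)) return(empty)
  out <- empty
  for (i in keep) {
    cs <- codes[starts[i]:ends[i]]
    hist <- vapply(c(0:4, 9), function(d) sum(cs == d, na.rm = TRUE),
                   integer(1))
    out[nrow(out) + 1L, ] <- c(list(r$values[i], starts[i], ends[i],
                                    r$lengths[i],
                                    r$lengths[i] >= min_len),
                               as.list(hist))
  }
  out
}

#' Named regular-expression queries over the token alphabet
#'
#' The shipped pattern library for mining symbolic sequences. Token-mode
#' patterns are matched on the two-character token string (letter + digit
#' per frame); letters-mode patterns on the one-character-per-frame letter
#' string. `mode_cluster("B")` builds the mode-specific cluster query
#' `(B[0-4]){3,}` for any letter.
#'
#' @return a named list of `list(pattern, on)` queries:
#' * `hind_leg_backward_sideways` -- rotation around the hind legs
#'   superimposed on backward/sideways progression, `([BD][2-4])*`;
#' * `hind_leg_diagonal_forward` -- the same rotation superimposed on a
#'   diagonally forward translation, `([BD]1)*`;
#' * `fixed_orientation_only` -- a phase containing only fixed-orientation
#'   modes, `^[AC]+$` on letters;
#' * `initial_backward_shift` -- an initial backward/sideward shift,
#'   `^([AC][2-4]){3,}`.
#' @export
fly_patterns <- function() {
  list(
    hind_leg_backward_sideways = list(pattern = "([BD][2-4])*",
                                      on = "tokens"),
    hind_leg_diagonal_forward = list(pattern = "([BD]1)*", on = "tokens"),
    fixed_orientation_only = list(pattern = "^[AC]+$", on = "letters"),
    initial_backward_shift = list(pattern = "^([AC][2-4]){3,}",
                                  on = "tokens"))
}

#' @rdname fly_patterns
#' @param letter a mode letter.
#' @export
mode_cluster <- function(letter) {
  stopifnot(letter %in% MODE_LETTERS)
  list(pattern = sprintf("(%s[0-4]){3,}", letter), on = "tokens")
}

#' Match a regular-expression pattern against a symbolic sequence
#'
#' Returns the non-overlapping, leftmost-longest episodes matching
#' `pattern`. In `"tokens"` mode the pattern is applied to the
#' two-characters-per-frame token string and matches are required to start
#' and end on token boundaries; zero-length matches (possible with `*`
#' quantifiers) are dropped. In `"letters"` mode it is applied to the
#' one-character-per-frame letter string. Gap frames are encoded as `-`
#' and never matched by the alphabet classes.
#'
#' @param seq a [encode_symbolic()] result.
#' @param pattern regular expression, or a `list(pattern, on)` query as
#'   returned by [fly_patterns()].
#' @param on `"tokens"` or `"letters"` (ignored when `pattern` is a query).
#' @return data.frame with `start`, `end` (frame indices) and `match` (the
#'   matched text).
#' @export
match_pattern <- function(seq, pattern, on = c("tokens", "letters")) {
  if (is.list(pattern)) {
    on <- pattern$on
    pattern <- pattern$pattern
  } else on <- match.arg(on)
  subject <- if (on == "tokens") seq$as_string
             else paste(ifelse(is.na(seq$letters), "-", seq$letters),
                        collapse = "")
  m <- tryCatch(suppressWarnings(gregexpr(pattern, subject,
                                          perl = TRUE)[[1L]]),
                error = function(e)
                  stop("invalid pattern '", pattern, "': ",
                       conditionMessage(e)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ok <- starts > 0L & lens > 0L
  starts <- starts[ok]; lens <- lens[ok]
  if (on == "tokens") {
    aligned <- (starts %% 2L == 1L) & (lens %% 2L == 0L)
    starts <- starts[aligned]; lens <- lens[aligned]
  }
  if (!length(starts))
    return(data.frame(start = integer(), end = integer(),
                      match = character()))
  if (on == "tokens") {
    data.frame(start = (starts + 1L) %/% 2L,
               end = (starts + lens - 1L) %/% 2L,
               match = substring(subject, starts, starts + lens - 1L))
  } else {
    data.frame(start = starts, end = starts + lens - 1L,
               match = substring(subject, starts, starts + lens - 1L))
  }
}

#' Proportion of mode usage per temporal phase
#'
#' For each phase (start, midsection, end) the fraction of its frames spent
#' in each of the six modes; fractions within a phase sum to 1. Empty
#' phases yield `NA` fractions and are flagged in the `n_frames` attribute.
#'
#' @param letters per-frame mode letters.
#' @param phases factor of phases aligned with `letters` (e.g. from
#'   [partition_phases()]); `NA` frames are excluded.
#' @return matrix phases x modes of time fractions, with attribute
#'   `n_frames`.
#' @export
mode_usage_proportions <- function(letters, phases) {
  stopifnot(length(letters) == length(phases))
  lv <- levels(phases)
  out <- matrix(NA_real_, length(lv), length(MODE_LETTERS),
                dimnames = list(lv, MODE_LETTERS))
  nfr <- integer(length(lv)); names(nfr) <- lv
  for (p in lv) {
    sel <- !is.na(phases) & phases == p & !is.na(letters)
    nfr[p] <- sum(sel)
    if (nfr[p] > 0)
      out[p, ] <- vapply(MODE_LETTERS,
                         function(m) mean(letters[sel] == m), numeric(1))
  }
  attr(out, "n_frames") <- nfr
  out
}

#' Rotational-episode statistics
#'
#' A rotational episode is a body-angular-velocity inter-arrest segment
#' whose body-orientation angular spread exceeds `theta_ling`. For each
#' episode the cumulative rotation angle (max minus min of the unwrapped
#' smoothed orientation, so multi-turn episodes exceed 360 degrees), the
#' maximal absolute angular velocity and the duration are reported.
#'
#' @param kin a [compute_kinematics()] result.
#' @param thr a [threshold_set()].
#' @return data.frame with `start`, `end`, `cumulative_angle` (deg),
#'   `max_omega` (deg/s), `duration` (s).
#' @export
rotation_episode_stats <- function(kin, thr = threshold_set()) {
  dt <- attr(kin, "dt")
  out <- data.frame(start = integer(), end = integer(),
                    cumulative_angle = numeric(), max_omega = numeric(),
                    duration = numeric())
  for (s in unique(stats::na.omit(kin$segment_id[kin$valid]))) {
    idx <- which(kin$valid & !is.na(kin$segment_id) & kin$segment_id == s)
    bseg <- extract_inter_arrest_segments(kin$omega_b[idx], thr$eps_omega,
                                          include_partial = TRUE)
    for (r in seq_len(nrow(bseg))) {
      sub <- idx[bseg$start[r]:bseg$end[r]]
      ang <- angular_spread(kin$alpha_b_s[sub])
      if (ang > thr$theta_ling)
        out[nrow(out) + 1L, ] <- list(sub[1L], sub[length(sub)], ang,
                                      max(abs(kin$omega_b[sub])),
                                      length(sub) * dt)
    }
  }
  out
}

#' Label a movement segment as pre-circling or circling
#'
#' The drug response splits into a pre-circling and a circling stage. A
#' movement segment belongs to the circling stage when at least one
#' criterion holds: the time share of the three rotational modes (B, D, R)
#' within the segment exceeds `p_rot_circ`, or the maximal cumulative body
#' turn within one rotational episode exceeds `theta_circ`.
#'
#' @param p_rot rotational-mode time share of the segment, in `[0, 1]`.
#' @param theta_max maximal single-episode cumulative rotation, degrees.
#' @param thr a [threshold_set()].
#' @return `"circling"` or `"pre_circling"` (vectorized).
#' @export
classify_drug_stage <- function(p_rot, theta_max, thr = threshold_set()) {
  stopifnot(all(p_rot >= 0 & p_rot <= 1))
  ifelse(p_rot > thr$p_rot_circ | theta_max > thr$theta_circ,
         "circling", "pre_circling")
}

#' Summarize and stage every movement segment of a session
#'
#' Computes, per movement segment, the rotational-mode time share `p_rot`
#' (over frames, a time-weighted share), the maximal cumulative rotation of
#' any rotational episode overlapping the segment (`theta_max`), and the
#' resulting stage label.
#'
#' @param kin a [compute_kinematics()] result.
#' @param letters per-frame letters from [classify_frames()].
#' @param thr a [threshold_set()].
#' @return data.frame: `start`, `end`, `p_rot`, `theta_max`, `stage`.
#' @export
stage_movement_segments <- function(kin, letters, thr = threshold_set()) {
  segs <- movement_segments(kin, thr)
  eps <- rotation_episode_stats(kin, thr)
  p_rot <- theta_max <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    fr <- segs$start[i]:segs$end[i]
    p_rot[i] <- mean(letters[fr] %in% c("B", "D", "R"), na.rm = TRUE)
    ov <- eps$start <= segs$end[i] & eps$end >= segs$start[i]
    theta_max[i] <- if (any(ov)) max(eps$cumulative_angle[ov]) else 0
  }
  data.frame(start = segs$start, end = segs$end, p_rot = p_rot,
             theta_max = theta_max,
             stage = classify_drug_stage(p_rot, theta_max, thr))
}

#' Build the 6x6 mode-transition matrix
#'
#' Counts `t_ij` of a cluster of mode *i* being followed by a cluster of
#' mode *j*, over the temporal sequence of mode clusters. Sub-clusters
#' (runs shorter than the cluster minimum) are bypassed -- their neighbors
#' become adjacent -- and consecutive same-mode clusters arising from such
#' bypassing are merged, so the diagonal is structurally zero. Gap-separated
#' clusters do not transition into each other. Counts are normalized to
#' probabilities by row (the Markov convention: row i sums to 1 over the
#' destinations of mode i) or, optionally, by column.
#'
#' @param clusters a [find_clusters()] result (or any data.frame with
#'   `mode`, `start`, `end`, `is_cluster`).
#' @param normalize `"row"` or `"column"`.
#' @param max_gap largest frame gap (between consecutive clusters' end and
#'   start) across which a transition is still counted; `Inf` by default.
#' @return object of class `transition_matrix`: list with `counts`, `probs`
#'   (rows/columns without transitions left as zeros and flagged in
#'   `empty`), `normalize`.
#' @export
build_transition_matrix <- function(clusters,
                                    normalize = c("row", "column"),
                                    max_gap = Inf) {
  normalize <- match.arg(normalize)
  cl <- clusters[clusters$is_cluster, , drop = FALSE]
  counts <- matrix(0L, 6, 6, dimnames = list(MODE_LETTERS, MODE_LETTERS))
  if (nrow(cl) >= 2L) {
    # merge consecutive same-mode clusters (sub-cluster bypass artifacts)
    keep <- c(TRUE, cl$mode[-1L] != cl$mode[-nrow(cl)] |
                (cl$start[-1L] - cl$end[-nrow(cl)] - 1L) > max_gap)
    merged_mode <- cl$mode[keep]
    grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
    merged_start <- as.numeric(tapply(cl$start, grp, min))
    merged_end <- as.numeric(tapply(cl$end, grp, max))
    nm <- length(merged_mode)
    if (nm >= 2L) {
      from <- merged_mode[-nm]; to <- merged_mode[-1L]
      gap <- merged_start[-1L] - merged_end[-nm] - 1L
      ok <- gap <= max_gap & from != to
      for (i in which(ok))
        counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  probs <- matrix(0, 6, 6, dimnames = dimnames(counts))
  if (normalize == "row") {
    rs <- rowSums(counts)
    nz <- rs > 0
    probs[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
    empty <- MODE_LETTERS[!nz]
  } else {
    cs <- colSums(counts)
    nz <- cs > 0
    probs[, nz] <- sweep(counts[, nz, drop = FALSE], 2, cs[nz], "/")
    empty <- MODE_LETTERS[!nz]
  }
  structure(list(counts = counts, probs = probs, normalize = normalize,
                 empty = empty),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Mode-transition matrix (%s-normalized), counts:\n",
              x$normalize))
  print(x$counts)
  cat("probabilities:\n")
  print(round(x$probs, digits))
  if (length(x$empty))
    cat("modes with no outgoing/incoming transitions:",
        paste(x$empty, collapse = " "), "\n")
  invisible(x)
}
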