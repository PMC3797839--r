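#' Six-mode letters
#'
#' The six elementary coordination modes: `A` fixed-front-on-straight-path,
#' `B` rotation-on-straight-path, `C` fixated-front-on-curved-path, `D`
#' rotation-on-curved-path, `L` lingering, `R` rotation-in-place.
#' @export
MODE_LETTERS <- c("A", "B", "C", "D", "L", "R")

#' Classify every frame into one of the six coordination modes
#'
#' Three span-level predicates are evaluated from the inter-arrest
#' structure of the kinematic signals:
#' * *progressing* -- the frame lies in a speed (`v_c`) inter-arrest segment
#'   whose spatial spread exceeds `d_ling`;
#' * *rotating* -- it lies in a body-angular-velocity (`omega_b`)
#'   inter-arrest segment whose body-orientation angular spread exceeds
#'   `theta_ling`;
#' * *curved* -- it lies, within a progressing span, in a velocity-direction
#'   angular-velocity (`omega_v`) sub-segment whose direction-of-progression
#'   angular spread exceeds `psi_str` (path curvature is only meaningful
#'   while progressing).
#'
#' The letter is then: A (progressing only), B (progressing + rotating),
#' C (progressing + curved), D (all three), L (neither progressing nor
#' rotating -- lingering frames may still move, just within a sub-threshold
#' neighborhood), R (rotating without progressing). Frames in a speed
#' segment that fails the spread test are lingering even though
#' instantaneously moving.
#'
#' @param kin a [compute_kinematics()] result.
#' @param thr a [threshold_set()].
#' @return character vector of per-frame letters (`NA` on invalid frames).
#' @export
classify_frames <- function(kin, thr = threshold_set()) {
  n <- nrow(kin)
  progressing <- rep(FALSE, n)
  rotating <- rep(FALSE, n)
  curved <- rep(FALSE, n)
  for (s in unique(stats::na.omit(kin$segment_id[kin$valid]))) {
    idx <- which(kin$valid & !is.na(kin$segment_id) & kin$segment_id == s)
    v <- kin$v_c[idx]
    vseg <- extract_inter_arrest_segments(v, thr$eps_v,
                                          include_partial = TRUE)
    for (r in seq_len(nrow(vseg))) {
      sub <- idx[vseg$start[r]:vseg$end[r]]
      if (spatial_spread(kin$x_s[sub], kin$y_s[sub]) > thr$d_ling) {
        progressing[sub] <- TRUE
        # curvature sub-segmentation within the progressing span
        wv <- kin$omega_v[sub]
        cseg <- extract_inter_arrest_segments(wv, thr$eps_omega,
                                              include_partial = TRUE)
        for (q in seq_len(nrow(cseg))) {
          csub <- sub[cseg$start[q]:cseg$end[q]]
          av <- kin$alpha_v[csub]
          av <- av[!is.na(av)]
          if (length(av) && angular_spread(av) > thr$psi_str)
            curved[csub] <- TRUE
        }
      }
    }
    bseg <- extract_inter_arrest_segments(kin$omega_b[idx], thr$eps_omega,
                                          include_partial = TRUE)
    for (r in seq_len(nrow(bseg))) {
      sub <- idx[bseg$start[r]:bseg$end[r]]
      if (angular_spread(kin$alpha_b_s[sub]) > thr$theta_ling)
        rotating[sub] <- TRUE
    }
  }
  letters <- rep(NA_character_, n)
  ok <- kin$valid
  letters[ok] <- ifelse(progressing[ok],
                        ifelse(rotating[ok],
                               ifelse(curved[ok], "D", "B"),
                               ifelse(curved[ok], "C", "A")),
                        ifelse(rotating[ok], "R", "L"))
  letters
}

#' Digitize an angular interval at 45-degree resolution
#'
#' The angular interval `phi` (signed shortest-arc difference between
#' direction of progression and body orientation) is digitized into 8
#' half-open 45-degree bins which are collapsed into 5 by not distinguishing
#' right from left: `|phi| <= 22.5` is 0 (forward), `(22.5, 67.5]` is 1
#' (diagonally forward), `(67.5, 112.5]` is 2 (sideways), `(112.5, 157.5]`
#' is 3 (diagonally backward), above 157.5 is 4 (backward). Boundary values
#' fall in the lower-`|phi|` bin. Lingering frames, where `phi` is
#' undefined, are coded 9.
#'
#' @param phi angular interval, degrees in `(-180, 180]` (`NA` allowed).
#' @param lingering logical; frames whose interval is undefined.
#' @return integer codes in `{0, 1, 2, 3, 4, 9}`.
#' @export
digitize_interval <- function(phi, lingering = is.na(phi)) {
  a <- abs(wrap_angle(phi))
  code <- ifelse(a <= 22.5, 0L,
          ifelse(a <= 67.5, 1L,
          ifelse(a <= 112.5, 2L,
          ifelse(a <= 157.5, 3L, 4L))))
  code[lingering] <- 9L
  code
}

#' Compute and digitize the angular interval series
#'
#' `phi = wrap(alpha_v - alpha_b)` on progressing frames (letters A-D);
#' positive `phi` means the direction of progression lies counterclockwise
#' of the body orientation. Non-progressing frames (L, R) have no defined
#' progression direction and receive code 9.
#'
#' @param kin a [compute_kinematics()] result.
#' @param letters per-frame letters from [classify_frames()].
#' @return data.frame with `phi` (deg, `NA` where undefined) and `code`.
#' @export
compute_angular_interval <- function(kin, letters) {
  prog <- !is.na(letters) & letters %in% c("A", "B", "C", "D")
  phi <- rep(NA_real_, nrow(kin))
  phi[prog] <- wrap_angle(kin$alpha_v[prog] - kin$alpha_b_s[prog])
  code <- rep(NA_integer_, nrow(kin))
  code[!is.na(letters)] <- digitize_interval(
    phi[!is.na(letters)], lingering = !prog[!is.na(letters)])
  data.frame(phi = phi, code = code)
}

#' Encode per-frame letters and codes as a symbolic sequence
#'
#' Re-synthesizes the kinematic time series into one string: every frame
#' contributes a two-character token, its mode letter followed by its
#' direction code. Invalid frames contribute the gap token `"--"`, which no
#' token-alphabet pattern matches, so the string length is always twice the
#' frame count. Letter/code combinations must satisfy the mode semantics:
#' L and R imply code 9; A-D imply a code in 0-4.
#'
#' @param letters character vector over `A B C D L R` (`NA` = gap).
#' @param codes integer vector over `0:4, 9` (`NA` = gap).
#' @return object of class `symbolic_sequence`: a list with `letters`,
#'   `codes` and `as_string`.
#' @export
encode_symbolic <- function(letters, codes) {
  stopifnot(length(letters) == length(codes))
  ok <- !is.na(letters)
  if (any(is.na(codes[ok])))
    stop("valid frames must carry a direction code")
  bad_lr <- ok & letters %in% c("L", "R") & codes != 9L
  bad_ad <- ok & letters %in% c("A", "B", "C", "D") & !(codes %in% 0:4)
  bad_letter <- ok & !(letters %in% MODE_LETTERS)
  if (any(bad_lr | bad_ad | bad_letter))
    stop(sprintf(
      "inconsistent letter/code combination at frame(s): %s",
      paste(utils::head(which(bad_lr | bad_ad | bad_letter), 10L),
            collapse = ", ")))
  tok <- ifelse(ok, paste0(letters, codes), "--")
  structure(list(letters = letters, codes = codes,
                 as_string = paste(tok, collapse = "")),
            class = "symbolic_sequence")
}

#' Decode a symbolic string back into letters and codes
#' @param string a token string produced by [encode_symbolic()].
#' @return a `symbolic_sequence`.
#' @export
decode_symbolic <- function(string) {
  if (nchar(string) %% 2L != 0L)
    stop("token string length must be even (two characters per frame)")
  nfr <- nchar(string) %/% 2L
  if (nfr == 0L) return(encode_symbolic(character(), integer()))
  lets <- substring(string, 2 * seq_len(nfr) - 1L, 2 * seq_len(nfr) - 1L)
  digs <- substring(string, 2 * seq_len(nfr), 2 * seq_len(nfr))
  gap <- lets == "-"
  lets[gap] <- NA_character_
  codes <- suppressWarnings(as.integer(digs))
  codes[gap] <- NA_integer_
  encode_symbolic(lets, codes)
}

#' @export
print.symbolic_sequence <- function(x, ...) {
  n <- length(x$letters)
  cat(sprintf("Symbolic sequence: %d frames\n", n))
  s <- x$as_string
  cat(if (nchar(s) > 120) paste0(substr(s, 1, 120), "...") else s, "\n")
  invisible(x)
}

#' Movement segments of a session
#'
#' Speed inter-arrest segments whose spatial spread exceeds `d_ling`; the
#' unit over which phases, rotational-mode shares and drug stages are
#' computed.
#'
#' @param kin a [compute_kinematics()] result.
#' @param thr a [threshold_set()].
#' @param include_partial include unbounded leading/trailing spans.
#' @return data.frame with `start`, `end` (1-based inclusive frame indices),
#'   `spread` (mm), `bounded`.
#' @export
movement_segments <- function(kin, thr = threshold_set(),
                              include_partial = TRUE) {
  out <- data.frame(start = integer(), end = integer(), spread = numeric(),
                    bounded = logical())
  for (s in unique(stats::na.omit(kin$segment_id[kin$valid]))) {
    idx <- which(kin$valid & !is.na(kin$segment_id) & kin$segment_id == s)
    vseg <- extract_inter_arrest_segments(kin$v_c[idx], thr$eps_v,
                                          include_partial = include_partial)
    for (r in seq_len(nrow(vseg))) {
      sub <- idx[vseg$start[r]:vseg$end[r]]
      sp <- spatial_spread(kin$x_s[sub], kin$y_s[sub])
      if (sp > thr$d_ling)
        out[nrow(out) + 1L, ] <- list(sub[1L], sub[length(sub)], sp,
                                      vseg$bounded[r])
    }
  }
  out
}

#' Partition a movement segment into start, midsection and end phases
#'
#' A start extends from the initiation of movement until speed first reaches
#' half of its maximum within the segment; a midsection extends from there
#' until speed falls for the *last* time below half of its maximum; the end
#' is the remainder. A segment that terminates while still at or above half
#' maximum has an empty end (flagged `truncated_end`); a segment already at
#' half maximum on its first frame has an empty start.
#'
#' @param v_c speed series of the segment frames, mm/s.
#' @return factor vector (levels `start`, `midsection`, `end`) with
#'   attributes `empty_start` and `truncated_end`.
#' @export
partition_phases <- function(v_c) {
  stopifnot(length(v_c) >= 1L, max(v_c) > 0)
  half <- max(v_c) / 2
  n <- length(v_c)
  first_half <- which(v_c >= half)[1L]
  last_half <- max(which(v_c >= half))
  phase <- rep("end", n)
  if (first_half > 1L) phase[seq_len(first_half - 1L)] <- "start"
  phase[first_half:last_half] <- "midsection"
  out <- factor(phase, levels = c("start", "midsection", "end"))
  attr(out, "empty_start") <- first_half == 1L
  attr(out, "truncated_end") <- last_half == n
  out
}

#' Detect backward-walking bouts
#'
#' Maximal runs of progressing frames whose digitized angular interval is 4
#' (progression opposite to the body orientation, `|phi| > 157.5` degrees).
#' Because head/tail resolution keeps body orientation continuous through a
#' one-frame reversal of the velocity vector, genuine backward walking shows
#' up here rather than as a spurious instantaneous body flip.
#'
#' @param letters per-frame letters.
#' @param codes per-frame direction codes.
#' @param min_len minimum bout length, frames.
#' @return data.frame with `start`, `end`, `length`.
#' @export
find_backward_bouts <- function(letters, codes, min_len = 3L) {
  back <- !is.na(letters) & letters %in% c("A", "B", "C", "D") &
    !is.na(codes) & codes == 4L
  r <- rle(back)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}
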