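# Shared fixtures and independent oracles, built in code at test time.

# frame-level agreement between recovered letters and planted labels,
# excluding a +/-buffer window around every planted transition
recovery_agreement <- function(session, letters, buffer = 2L) {
  tr <- session_transitions(session)
  buf <- unique(unlist(lapply(tr, function(i)
    (i - buffer):(i + buffer + 1L))))
  core <- setdiff(seq_len(nrow(session$truth)), buf)
  core <- core[!is.na(session$truth$mode[core])]
  list(agreement = mean(letters[core] == session$truth$mode[core],
                        na.rm = FALSE),
       n_core = length(core))
}

# brute-force O(n^2) diameter
oracle_spread <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  best <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    best <- max(best, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  best
}

# exhaustive frame-by-frame scan for inter-arrest segments
oracle_segments <- function(signal, eps, include_partial = FALSE) {
  n <- length(signal)
  above <- abs(signal) > eps
  out <- data.frame(start = integer(), end = integer(), bounded = logical())
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      out[nrow(out) + 1L, ] <- list(i, j, i > 1L && j < n)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!include_partial) out <- out[out$bounded, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive anchored scan over token positions (leftmost, greedy,
# non-overlapping); independent of match_pattern's gregexpr route
oracle_token_matches <- function(string, pattern) {
  n <- nchar(string) %/% 2L
  out <- data.frame(start = integer(), end = integer())
  s <- 1L
  while (s <= n) {
    m <- regexpr(paste0("^(?:", pattern, ")"),
                 substr(string, 2L * s - 1L, 2L * n), perl = TRUE)
    len <- attr(m, "match.length")
    if (m == 1L && len > 0L && len %% 2L == 0L) {
      out[nrow(out) + 1L, ] <- list(s, s + len %/% 2L - 1L)
      s <- s + len %/% 2L
    } else s <- s + 1L
  }
  out
}

# random symbolic sequence with mode-consistent codes
random_sequence <- function(n) {
  lets <- sample(MODE_LETTERS, n, replace = TRUE)
  codes <- ifelse(lets %in% c("L", "R"), 9L,
                  sample(0:4, n, replace = TRUE))
  encode_symbolic(lets, codes)
}

# hand-built kinematic series with planted signal spans (positions move
# along x so spatial spread equals net displacement)
planted_kinematics <- function(v_c, omega_b, omega_v, dt = 0.04) {
  n <- length(v_c)
  x_s <- cumsum(v_c) * dt
  alpha_b_s <- cumsum(omega_b) * dt
  alpha_v <- cumsum(omega_v) * dt
  kin <- data.frame(t = (seq_len(n) - 1) * dt, x_s = x_s, y_s = 0,
                    v_c = v_c, alpha_v = alpha_v, omega_v = omega_v,
                    alpha_b_s = alpha_b_s, omega_b = omega_b,
                    valid = TRUE, segment_id = 1L)
  attr(kin, "dt") <- dt
  class(kin) <- c("kinematic_series", "data.frame")
  kin
}

# independent frame-by-frame evaluation of the six-mode predicates
oracle_letters <- function(kin, thr) {
  n <- nrow(kin)
  prog <- rep(FALSE, n); rot <- rep(FALSE, n); curv <- rep(FALSE, n)
  vseg <- oracle_segments(kin$v_c, thr$eps_v, include_partial = TRUE)
  for (r in seq_len(nrow(vseg))) {
    fr <- vseg$start[r]:vseg$end[r]
    if (oracle_spread(kin$x_s[fr], kin$y_s[fr]) > thr$d_ling) {
      prog[fr] <- TRUE
      cseg <- oracle_segments(kin$omega_v[fr], thr$eps_omega,
                              include_partial = TRUE)
      for (q in seq_len(nrow(cseg))) {
        sub <- fr[cseg$start[q]:cseg$end[q]]
        av <- kin$alpha_v[sub]
        if (max(av) - min(av) > thr$psi_str) curv[sub] <- TRUE
      }
    }
  }
  bseg <- oracle_segments(kin$omega_b, thr$eps_omega,
                          include_partial = TRUE)
  for (r in seq_len(nrow(bseg))) {
    fr <- bseg$start[r]:bseg$end[r]
    if (max(kin$alpha_b_s[fr]) - min(kin$alpha_b_s[fr]) > thr$theta_ling)
      rot[fr] <- TRUE
  }
  ifelse(prog, ifelse(rot, ifelse(curv, "D", "B"),
                      ifelse(curv, "C", "A")),
         ifelse(rot, "R", "L"))
}
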