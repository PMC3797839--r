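test_that("clusters are maximal same-letter runs with a length floor", {
  sq <- decode_symbolic("A0A0A0B1B1B1")
  cl <- find_clusters(sq)
  expect_equal(cl$mode, c("A", "B"))
  expect_equal(cl$length, c(3L, 3L))
  expect_true(all(cl$is_cluster))
  expect_equal(cl$n0, c(3L, 0L))
  expect_equal(cl$n1, c(0L, 3L))

  cl2 <- find_clusters(decode_symbolic("A0A0B1A0A0A0"))
  expect_equal(cl2$mode, c("A", "B", "A"))
  expect_equal(cl2$is_cluster, c(FALSE, FALSE, TRUE))
  expect_equal(cl2$start[3], 4L)

  expect_equal(nrow(find_clusters(encode_symbolic(character(0),
                                                  integer(0)))), 0L)

  # lossless partition of non-gap frames
  set.seed(3)
  rs <- random_sequence(150)
  cl3 <- find_clusters(rs)
  expect_equal(sum(cl3$length), 150L)
  expect_true(all(diff(cl3$start) > 0))
})

test_that("pattern matching equals the naive scan oracle", {
  pats <- fly_patterns()
  hind <- pats$hind_leg_backward_sideways
  m <- match_pattern(decode_symbolic("B2B2B2"), hind)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 3L))
  expect_equal(nrow(match_pattern(decode_symbolic("A0A0A0"), hind)), 0L)

  set.seed(29)
  for (i in 1:25) {
    rs <- random_sequence(80)
    for (p in c("([BD][2-4])*", "([BD]1)*", "(R9){2,}", "[AC][0-4](L9)+")) {
      got <- match_pattern(rs, p)
      want <- oracle_token_matches(rs$as_string, p)
      expect_equal(got$start, want$start, info = p)
      expect_equal(got$end, want$end, info = p)
    }
  }

  # letters-mode anchored query
  fixed <- pats$fixed_orientation_only
  expect_equal(nrow(match_pattern(decode_symbolic("A0C1A2"), fixed)), 1L)
  expect_equal(nrow(match_pattern(decode_symbolic("A0B1A2"), fixed)), 0L)
  expect_error(match_pattern(decode_symbolic("A0"), "(["), "invalid")
})

test_that("mode-usage proportions are per-phase time fractions", {
  letters <- c(rep("A", 6), rep("D", 4))
  phases <- factor(rep("midsection", 10),
                   levels = c("start", "midsection", "end"))
  p <- mode_usage_proportions(letters, phases)
  expect_equal(p["midsection", "A"], 0.6)
  expect_equal(p["midsection", "D"], 0.4)
  expect_equal(sum(p["midsection", ]), 1, tolerance = 1e-12)
  expect_true(all(is.na(p["start", ])))  # empty phase flagged
  expect_equal(attr(p, "n_frames")[["start"]], 0L)
})

test_that("rotational episodes report cumulative angle, peak speed, duration", {
  # steady 90 deg/s for 5 s planted directly
  n <- 125L
  kin <- planted_kinematics(v_c = rep(0, n), omega_b = rep(90, n),
                            omega_v = rep(0, n))
  eps <- rotation_episode_stats(kin, threshold_set())
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$cumulative_angle, (n - 1) * 90 * 0.04, tolerance = 1e-9)
  expect_equal(eps$max_omega, 90)
  expect_equal(eps$duration, n * 0.04)

  # a single-frame wobble below tolerance is no episode
  blip <- planted_kinematics(v_c = rep(0, 50),
                             omega_b = c(rep(0, 24), 8, rep(0, 25)),
                             omega_v = rep(0, 50))
  expect_equal(nrow(rotation_episode_stats(blip, threshold_set())), 0L)

  # generator bookkeeping oracle: two planted rotation bouts
  sc <- mode_script(script_step("L", 1.5), script_step("R", 2),
                    script_step("L", 1.5),
                    script_step("R", 1.5, rotation = -60),
                    script_step("L", 1.5))
  ss <- generate_session(sc, gain_model(seed = 5))
  ses <- analyze_session(ss$trajectory, ss$arena)
  got <- rotation_episode_stats(ses$kinematics, ses$thresholds)
  expect_equal(nrow(got), 2L)
  expect_equal(got$cumulative_angle, c(45 * 2, 60 * 1.5), tolerance = 0.12)
  expect_equal(got$max_omega, c(45, 60), tolerance = 0.05)
})

test_that("drug staging applies the disjunctive circling criteria", {
  thr <- threshold_set()
  expect_equal(classify_drug_stage(0.9, 100, thr), "circling")
  expect_equal(classify_drug_stage(0.5, 400, thr), "circling")
  expect_equal(classify_drug_stage(0.5, 200, thr), "pre_circling")
  # monotone in both arguments
  set.seed(10)
  p <- runif(50); th <- runif(50, 0, 800)
  base <- classify_drug_stage(p, th, thr)
  up <- classify_drug_stage(pmin(p * 1.2, 1), th * 1.2, thr)
  expect_true(all(!(base == "circling" & up == "pre_circling")))
})

test_that("stage_movement_segments computes time-weighted rotational shares", {
  ss <- generate_session(six_mode_script(), gain_model(seed = 6))
  ses <- analyze_session(ss$trajectory, ss$arena)
  st <- stage_movement_segments(ses$kinematics, ses$letters,
                                ses$thresholds)
  expect_true(nrow(st) >= 1L)
  expect_true(all(st$p_rot >= 0 & st$p_rot <= 1))
  expect_true(all(st$stage %in% c("circling", "pre_circling")))
  i <- which.max(st$p_rot)
  fr <- st$start[i]:st$end[i]
  expect_equal(st$p_rot[i],
               mean(ses$letters[fr] %in% c("B", "D", "R"), na.rm = TRUE))
})

test_that("transition matrices tally cluster successions", {
  mk <- function(modes, len = 3L) {
    lets <- rep(modes, each = len)
    decode_symbolic(paste0(lets, ifelse(lets %in% c("L", "R"), 9, 0),
                           collapse = ""))
  }
  tm <- build_transition_matrix(find_clusters(mk(c("A", "B", "A", "B"))))
  expect_equal(tm$probs["A", "B"], 1)
  expect_equal(tm$probs["B", "A"], 1)
  expect_equal(sum(tm$counts), 3L)
  expect_true(all(diag(tm$counts) == 0L))

  set.seed(91)
  for (i in 1:20) {
    modes <- character(0)
    for (j in 1:15) {
      m <- sample(MODE_LETTERS, 1)
      while (length(modes) && m == modes[length(modes)])
        m <- sample(MODE_LETTERS, 1)
      modes <- c(modes, m)
    }
    tm2 <- build_transition_matrix(find_clusters(mk(modes)))
    want <- matrix(0L, 6, 6, dimnames = list(MODE_LETTERS, MODE_LETTERS))
    for (j in seq_len(length(modes) - 1L))
      want[modes[j], modes[j + 1L]] <- want[modes[j], modes[j + 1L]] + 1L
    expect_identical(tm2$counts, want)
    rs <- rowSums(tm2$probs)
    expect_true(all(abs(rs[rowSums(tm2$counts) > 0] - 1) < 1e-12))

    # cluster-level statistic: duplicating internal frames changes nothing
    tm3 <- build_transition_matrix(find_clusters(mk(modes, len = 6L)))
    expect_identical(tm3$counts, tm2$counts)
  }

  # sub-clusters are bypassed and same-mode neighbors merge (zero diagonal)
  sq <- decode_symbolic("A0A0A0B1A0A0A0R9R9R9")
  tm4 <- build_transition_matrix(find_clusters(sq))
  expect_equal(unname(tm4$counts["A", "R"]), 1L)
  expect_equal(sum(tm4$counts), 1L)
})

test_that("session reports assemble the descriptive outputs", {
  ss <- generate_session(six_mode_script(),
                         gain_model(noise_pos = 0.1, noise_angle = 2,
                                    seed = 8))
  ses <- analyze_session(ss$trajectory, ss$arena)
  rep <- session_report(ses)
  expect_named(rep, c("mode_proportions", "segments", "episodes",
                      "episode_q95", "transitions"))
  p <- rep$mode_proportions["midsection", ]
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_s3_class(rep$transitions, "transition_matrix")
  expect_true(rep$episode_q95 > 12)
})
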