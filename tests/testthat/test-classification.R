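test_that("the digitizer implements the collapsed 45-degree bins", {
  expect_equal(digitize_interval(0), 0L)
  expect_equal(digitize_interval(90), 2L)
  expect_equal(digitize_interval(-90), 2L)   # left/right collapsed
  expect_equal(digitize_interval(45), 1L)
  expect_equal(digitize_interval(-135), 3L)
  expect_equal(digitize_interval(180), 4L)
  expect_equal(digitize_interval(NA), 9L)
  expect_equal(digitize_interval(0, lingering = TRUE), 9L)
  # boundary values fall into the lower-|phi| bin
  expect_equal(digitize_interval(c(22.5, 67.5, 112.5, 157.5)),
               c(0L, 1L, 2L, 3L))
  # wrap-aware difference: 10 vs -170 is a 180-degree interval
  expect_equal(digitize_interval(wrap_angle(10 - (-170))), 4L)
  # the collapsed code set has exactly 5 categories for progressing frames
  grid <- seq(-179.9, 180, by = 0.1)
  expect_equal(sort(unique(digitize_interval(grid))), 0:4)
})

test_that("classification matches the frame-by-frame oracle on planted spans", {
  thr <- threshold_set()
  set.seed(44)
  for (i in 1:10) {
    n <- 200L
    blocks <- function(hi, k) {  # random piecewise-constant signal
      v <- numeric(n)
      for (b in 1:k) {
        at <- sample(n - 20, 1)
        v[at:(at + sample(10:20, 1))] <- hi * sample(c(-1, 1), 1)
      }
      v[seq_len(n)]
    }
    kin <- planted_kinematics(v_c = abs(blocks(80, 3)),
                              omega_b = blocks(60, 3),
                              omega_v = blocks(50, 3))
    expect_identical(classify_frames(kin, thr), oracle_letters(kin, thr))
  }
})

test_that("pure straight runs are A and rest is L", {
  ss <- generate_session(mode_script(script_step("A", 2)), gain_model())
  ses <- analyze_session(ss$trajectory, ss$arena)
  expect_true(all(ses$letters == "A"))
  expect_true(all(ses$codes == 0L))

  still <- generate_session(mode_script(script_step("L", 2)), gain_model())
  ses_l <- analyze_session(still$trajectory, still$arena)
  expect_true(all(ses_l$letters == "L"))
  expect_true(all(ses_l$codes == 9L))
})

test_that("raising a threshold only demotes frames (monotonicity)", {
  ss <- generate_session(six_mode_script(),
                         gain_model(noise_pos = 0.2, noise_angle = 3,
                                    seed = 13))
  ses <- analyze_session(ss$trajectory, ss$arena)
  kin <- ses$kinematics
  prog <- function(l) !is.na(l) & l %in% c("A", "B", "C", "D")
  rot <- function(l) !is.na(l) & l %in% c("B", "D", "R")
  crv <- function(l) !is.na(l) & l %in% c("C", "D")
  l1 <- ses$letters
  l2 <- classify_frames(kin, threshold_set(d_ling = 9))
  expect_true(all(prog(l2) <= prog(l1)))
  l3 <- classify_frames(kin, threshold_set(theta_ling = 30))
  expect_true(all(rot(l3) <= rot(l1)))
  l4 <- classify_frames(kin, threshold_set(psi_str = 40))
  expect_true(all(crv(l4) <= crv(l1)))
})

test_that("every valid frame gets exactly one letter and a consistent code", {
  ss <- generate_session(six_mode_script(),
                         gain_model(noise_pos = 0.2, noise_angle = 3,
                                    seed = 3))
  ses <- analyze_session(ss$trajectory, ss$arena)
  ok <- ses$kinematics$valid
  expect_true(all(ses$letters[ok] %in% MODE_LETTERS))
  lr <- ok & ses$letters %in% c("L", "R")
  expect_true(all(ses$codes[lr] == 9L))
  ad <- ok & ses$letters %in% c("A", "B", "C", "D")
  expect_true(all(ses$codes[ad] %in% 0:4))
  expect_equal(nchar(ses$sequence$as_string), 2L * nrow(ses$kinematics))
})

test_that("symbolic encoding is invertible and validates combinations", {
  sq <- encode_symbolic(c("A", "A", "B"), c(0L, 0L, 1L))
  expect_equal(sq$as_string, "A0A0B1")
  back <- decode_symbolic(sq$as_string)
  expect_equal(back$letters, sq$letters)
  expect_equal(back$codes, sq$codes)

  set.seed(77)
  rs <- random_sequence(200)
  rt <- decode_symbolic(rs$as_string)
  expect_equal(rt$letters, rs$letters)
  expect_equal(rt$codes, rs$codes)

  expect_error(encode_symbolic("L", 2L), "inconsistent")
  expect_error(encode_symbolic("A", 9L), "inconsistent")

  # gap frames encode as an unmatchable token
  g <- encode_symbolic(c("A", NA, "B"), c(0L, NA, 1L))
  expect_equal(g$as_string, "A0--B1")
  expect_equal(decode_symbolic(g$as_string)$letters, c("A", NA, "B"))
})

test_that("phases split segments at half-maximum speed", {
  v <- c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2, 1)
  ph <- partition_phases(v)
  # half-max 3: first frame at/above is 3, last is 9 (direct scan)
  expect_equal(as.character(ph),
               c("start", "start", rep("midsection", 7), "end", "end"))
  expect_false(attr(ph, "empty_start"))
  expect_false(attr(ph, "truncated_end"))

  const <- partition_phases(rep(5, 6))
  expect_true(all(const == "midsection"))
  expect_true(attr(const, "empty_start"))
  expect_true(attr(const, "truncated_end"))

  # two-peaked profile: the midsection runs to the *last* half-max crossing
  v2 <- c(1, 6, 1, 1, 6, 1)
  ph2 <- partition_phases(v2)
  expect_equal(as.character(ph2),
               c("start", "midsection", "midsection", "midsection",
                 "midsection", "end"))
})

test_that("noise-free sessions are recovered perfectly outside transition buffers", {
  ss <- generate_session(six_mode_script(), gain_model(seed = 2))
  ses <- analyze_session(ss$trajectory, ss$arena)
  rec <- recovery_agreement(ss, ses$letters)
  expect_equal(rec$agreement, 1)
  expect_gt(rec$n_core, 300)
})
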