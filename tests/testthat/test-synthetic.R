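test_that("triangle protocol trace matches the waveform exactly", {
  sp <- protocol_spec("triangle", peak = 2, ramp_duration = 1,
                      sample_rate = 300, lead_hold = 0, tail_hold = 0)
  tr <- gen_force_trace(sp)
  expect_equal(max(tr$value), 2)
  expect_equal(tr$time_s[which.max(tr$value)], 1)
  expect_equal(max(tr$time_s), 2, tolerance = 1e-9)
  expect_equal(tr$value[1], 0)
  expect_equal(tr$value[nrow(tr)], 0, tolerance = 1e-9)
})

test_that("constant-rate protocol: duration and terminal value", {
  sp <- protocol_spec("constant-rate", peak = 2, rate = 1, sample_rate = 300,
                      lead_hold = 0, tail_hold = 0)
  tr <- gen_force_trace(sp)
  expect_equal(max(tr$time_s), 2, tolerance = 1e-2)
  expect_equal(tr$value[nrow(tr)], 2, tolerance = 1e-9)
})

test_that("noisy protocol traces close the loop with the signal pipeline", {
  for (rate in c(0.5, 2)) {
    sp <- protocol_spec("constant-rate", peak = 2, rate = rate,
                        sample_rate = 300, noise_sd = 0.02)
    tr <- smooth_trace(gen_force_trace(sp, seed = 7), 100)
    expect_lt(abs(force_rate(extract_ramp(tr), tr) - rate) / rate, 0.02)
  }
})

test_that("displacement traces follow the stiffness source", {
  sp <- protocol_spec("constant-rate", peak = 2, rate = 1, sample_rate = 100)
  ftr <- gen_force_trace(sp)
  d1 <- gen_displacement_trace(ftr, 1) # 1 N/mm
  expect_equal(max(d1$value), 2, tolerance = 1e-9)
  d2 <- gen_displacement_trace(ftr, 0.5) # softer: larger displacement
  expect_gt(max(d2$value), max(d1$value))
  fd <- data.frame(displacement_mm = c(0, 1, 2), force_N = c(0, 0.5, 1.5))
  expect_error(gen_displacement_trace(ftr, fd), "exceeds")
  # reproducible under seed
  a <- gen_displacement_trace(ftr, 1, noise_sd = 0.01, seed = 3)
  b <- gen_displacement_trace(ftr, 1, noise_sd = 0.01, seed = 3)
  expect_identical(a$value, b$value)
})

test_that("synthetic ink images carry exact ground truth", {
  gi <- gen_ink_image(1.0, scale = 0.01, seed = 2)
  expect_equal(gi$truth$bar_pixels, 5 / 0.01)
  # blob pixel count matches the requested area
  expect_lt(abs(sum(gi$truth$mask) - 1.0 / 0.01^2) / (1.0 / 0.01^2), 0.02)
  expect_error(gen_ink_image(-1), "positive")
})

test_that("session generation follows the factorial design", {
  spec <- session_spec(participants = 2, seed = 4)
  tr <- gen_session(spec)
  # per participant: 2 reps x 9 pairs for the three passive tasks, 3 x 9 active
  one <- tr[tr$participant == 1, ]
  expect_identical(nrow(one[one$condition == "passive-same-rate", ]), 18L)
  expect_identical(nrow(one[one$condition == "active-same-rate", ]), 27L)
  # presentation order is a permutation of the design
  tab <- table(one$first, one$second)[, ]
  expect_true(all(tab["10kPa-4mm", ] >= 2))
  counts <- table(paste(one$first, one$second))
  expect_true(all(counts == 9)) # 2+2+2+3 per ordered pair
  # reproducible
  expect_identical(gen_session(spec), tr)
})

test_that("a d' = 0 condition converges to its chance level", {
  # with 6 different-pairs and 3 same-pairs per block, the d' = 0 observer's
  # expected percent correct is 100 * (6 F + 3 (1 - F)) / 9 with
  # F = 2 Phi(-criterion); an unbiased criterion (F = 1/2) gives 50%
  crit <- -qnorm(0.25)
  spec <- session_spec(conditions = data.frame(
    condition = "null", dprime = 0, criterion = crit, repetitions = 40L),
    participants = 10, seed = 9)
  tr <- gen_session(spec)
  pc <- percent_correct(tr)$percent_correct
  expect_lt(abs(pc - 50), 3)
  # biased criterion shifts the chance level exactly as the model predicts
  spec2 <- session_spec(conditions = data.frame(
    condition = "null", dprime = 0, criterion = 0.8, repetitions = 40L),
    participants = 10, seed = 9)
  F0 <- 2 * pnorm(-0.8)
  expected <- 100 * (6 * F0 + 3 * (1 - F0)) / 9
  pc2 <- percent_correct(gen_session(spec2))$percent_correct
  expect_lt(abs(pc2 - expected), 3)
})

test_that("calibration targets: reproducibility and stiffness ordering", {
  cfg <- calibration_config(n_interface = 21L, divisions = c(1L, 1L, 1L),
                            deflection_depths = 0.4,
                            fd_displacements = c(0.3, 0.6))
  t1 <- gen_calibration_targets(c(40, 20, 8), seed = 5, cfg = cfg)
  t2 <- gen_calibration_targets(c(40, 20, 8), seed = 5, cfg = cfg)
  expect_identical(t1$fd_curve, t2$fd_curve)
  expect_identical(attr(t1, "truth")$moduli, c(40, 20, 8))
  # doubled moduli double the forces, i.e. smaller displacement at equal force
  t3 <- gen_calibration_targets(2 * c(40, 20, 8), cfg = cfg)
  expect_equal(t3$fd_curve$force_N, 2 * t1$fd_curve$force_N, tolerance = 0.02)
  u_at <- function(tt, f) approx(tt$fd_curve$force_N,
                                 tt$fd_curve$displacement_mm, f)$y
  f_probe <- max(t1$fd_curve$force_N) * 0.9
  expect_lt(u_at(t3, f_probe), u_at(t1, f_probe))
})
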