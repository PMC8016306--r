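test_that("trace constructors validate sampling", {
  tr <- new_trace(c(0, 1, 2), 100)
  expect_equal(tr$time_s, c(0, 0.01, 0.02))
  expect_error(new_trace(1, 100), "2 samples")
  df <- data.frame(time_s = c(0, 0.1, 0.25), value = 1:3)
  expect_error(as_trace(df), "uniform")
  df2 <- data.frame(time_s = c(0, 0.1, 0.2), value = 1:3)
  expect_equal(attr(as_trace(df2), "sample_rate"), 10)
})

test_that("moving filter: constants, impulse plateau, variance reduction", {
  const <- new_trace(rep(2, 500), 300)
  expect_equal(smooth_trace(const, 100)$value, rep(2, 500))
  # unit impulse -> plateau of height 1/window
  imp <- new_trace(c(rep(0, 300), 1, rep(0, 300)), 300)
  sm <- smooth_trace(imp, 100)
  expect_equal(max(sm$value), 1 / 100)
  expect_identical(sum(sm$value > 1 / 100 - 1e-12), 100L)
  # white noise variance shrinks by ~ the window length
  set.seed(9)
  wn <- new_trace(rnorm(2e4), 300)
  v <- var(smooth_trace(wn, 100)$value[200:19800])
  expect_lt(abs(v - 1 / 100) / (1 / 100), 0.25)
  expect_error(smooth_trace(const, 1000), "exceeds")
})

test_that("ramp extraction finds the loading limb with tight boundaries", {
  # hold 1 s, ramp 1 N/s for 2 s, hold: boundaries known exactly
  sr <- 100
  f <- c(rep(0, 100), seq(0, 2, length.out = 201)[-1], rep(2, 100))
  tr <- new_trace(f, sr)
  seg <- extract_ramp(tr)
  expect_lte(abs(seg$start_index - 101), 2)
  expect_lte(abs(seg$end_index - 301), 2)
  expect_equal(seg$slope, 1, tolerance = 1e-9)
  expect_error(extract_ramp(new_trace(rep(1, 50), 100)), "no-ramp")
  # triangle: ascending limb only
  tri <- gen_force_trace(protocol_spec("triangle", peak = 2, sample_rate = 300))
  st <- extract_ramp(tri)
  expect_gt(st$slope, 0)
  expect_equal(st$slope, 2, tolerance = 1e-6)
})

test_that("force rate is unbiased across the protocol rates at >= 20 dB SNR", {
  for (rate in c(0.5, 1, 2)) {
    sp <- protocol_spec("constant-rate", peak = 2, rate = rate,
                        sample_rate = 300, noise_sd = 0.115) # ~20 dB SNR
    tr <- smooth_trace(gen_force_trace(sp, seed = round(100 * rate)), 100)
    est <- force_rate(extract_ramp(tr), tr)
    expect_lt(abs(est - rate) / rate, 0.02)
  }
  # ideal ramps are exact
  ideal <- new_trace(seq(0, 2, by = 0.01), 100) # 1 N/s at 100 Hz
  expect_equal(force_rate(extract_ramp(ideal), ideal), 1, tolerance = 1e-9)
})

test_that("net displacement between landmarks", {
  tr <- new_trace(c(10, 9, 8, 7), 100)
  expect_equal(net_displacement(tr, 1, 4), 3)
  expect_equal(net_displacement(tr, 2, 2), 0)
  expect_error(net_displacement(tr, 0, 4), "out of range")
  expect_error(net_displacement(tr, 1, 9), "out of range")
})

test_that("identical trace and settings give identical outputs", {
  sp <- protocol_spec("constant-rate", peak = 2, rate = 1, noise_sd = 0.05)
  t1 <- gen_force_trace(sp, seed = 33)
  t2 <- gen_force_trace(sp, seed = 33)
  expect_identical(t1$value, t2$value)
  s1 <- extract_ramp(smooth_trace(t1, 100))
  s2 <- extract_ramp(smooth_trace(t2, 100))
  expect_identical(s1$slope, s2$slope)
})
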