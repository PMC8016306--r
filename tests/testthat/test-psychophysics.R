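test_that("ordered pair enumeration matches the sampling-with-replacement design", {
  p3 <- enumerate_pairs(c("10kPa-4mm", "90kPa-6mm", "90kPa-8mm"))
  expect_identical(nrow(p3), 9L)
  expect_identical(sum(p3$first == p3$second), 3L)
  expect_identical(nrow(enumerate_pairs(c("a", "b"))), 4L)
  expect_identical(nrow(enumerate_pairs("a")), 1L)
  expect_error(enumerate_pairs(character(0)), "at least one")
})

test_that("percent correct and the 75% threshold flag", {
  tr <- data.frame(condition = "c", correct = rep(TRUE, 10))
  pc <- percent_correct(tr)
  expect_equal(pc$percent_correct, 100)
  expect_true(pc$above_threshold)
  tr$correct[1:3] <- FALSE
  expect_false(percent_correct(tr)$above_threshold) # 70%
  tr$correct[1] <- TRUE # 80%
  expect_true(percent_correct(tr)$above_threshold)
  expect_error(percent_correct(tr, "other"), "no trials")
})

test_that("d' inversion is the exact inverse of the forward differencing model", {
  for (d in c(0.3, 0.8, 1.5, 2.5, 4)) {
    for (k in c(0.8, 1.5, 2.5)) {
      hf <- tactillusion:::dprime_forward(d, k)
      inv <- dprime_differencing(hf$H, hf$F)
      expect_equal(inv$dprime, d, tolerance = 1e-6)
      expect_equal(inv$criterion, k, tolerance = 1e-9)
    }
  }
  expect_equal(dprime_differencing(0.3, 0.3)$dprime, 0)
  expect_equal(dprime_differencing(0.2, 0.4)$dprime, 0) # H < F
  expect_error(dprime_differencing(1, 0.2), "rate error")
  expect_error(dprime_differencing(0.8, 0), "rate error")
})

test_that("d' is monotone increasing in the hit rate at fixed false alarms", {
  H <- seq(0.3, 0.95, by = 0.05)
  d <- vapply(H, function(h) dprime_differencing(h, 0.25)$dprime, 0)
  expect_true(all(diff(d) > 0))
})

test_that("simulated observer behaves like the differencing model", {
  pairs <- enumerate_pairs(c("a", "b", "c"))
  # d' = 0: indistinguishable, H ~ F
  t0 <- simulate_observer(0, 1, pairs, n_trials = 4e4, seed = 1)
  r0 <- rates_from_trials(t0)
  expect_lt(abs(r0$H - r0$F), 0.02)
  # extreme criterion: everything "same"
  tinf <- simulate_observer(1, 50, pairs, n_trials = 500, seed = 2)
  expect_true(all(tinf$response == "same"))
  # high sensitivity: well above the 75% threshold
  t35 <- simulate_observer(3.5, 1.2, pairs, n_trials = 2e4, seed = 3)
  expect_gt(percent_correct(t35)$percent_correct, 75)
  expect_error(simulate_observer(-1, 1, pairs), "parameter error")
})

test_that("Monte-Carlo observer round trip recovers d'", {
  pairs <- enumerate_pairs(c("a", "b", "c"))
  tr <- simulate_observer(2, 1, pairs, n_trials = 1e5, seed = 11)
  rt <- rates_from_trials(tr)
  expect_equal(dprime_differencing(rt$H, rt$F)$dprime, 2, tolerance = 0.02)
})

test_that("condition report: extreme rates, warnings, d' ordering recovery", {
  pairs <- enumerate_pairs(c("a", "b", "c"))
  # all-correct condition: rates corrected, d' large but finite
  allc <- data.frame(condition = "perfect", first = pairs$first,
                     second = pairs$second,
                     response = ifelse(pairs$first != pairs$second,
                                       "different", "same"),
                     correct = TRUE, stringsAsFactors = FALSE)
  rep1 <- condition_report(allc)
  expect_true(is.finite(rep1$conditions$dprime_pooled))
  expect_gt(rep1$conditions$dprime_pooled, 1)
  expect_equal(rep1$conditions$percent_correct, 100)
  # same-pairs only: d' undefined for that cell
  sameonly <- data.frame(condition = "deg", first = "a", second = "a",
                         response = rep(c("same", "different"), 5),
                         correct = rep(c(TRUE, FALSE), 5),
                         stringsAsFactors = FALSE)
  expect_warning(rep2 <- condition_report(sameonly), "undefined")
  expect_true(is.na(rep2$conditions$dprime_pooled))
  # simulated session: generating ordering preserved in recovered d'
  gen <- rbind(
    simulate_observer(0.4, 1.2, pairs, n_trials = 3000, seed = 21,
                      condition = "low"),
    simulate_observer(1.2, 1.2, pairs, n_trials = 3000, seed = 22,
                      condition = "mid"),
    simulate_observer(3.5, 1.2, pairs, n_trials = 3000, seed = 23,
                      condition = "high"))
  rep3 <- condition_report(gen)
  d <- with(rep3$conditions, setNames(dprime_pooled, condition))
  expect_true(d[["low"]] < d[["mid"]] && d[["mid"]] < d[["high"]])
  expect_identical(nrow(rep3$pairs), 27L)
})
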