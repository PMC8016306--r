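# Same-different psychophysics: design enumeration, scoring and sensitivity
# (d') under the differencing rule, plus a simulated differencing observer.
#
# Differencing model for the same-different task: the observer draws one noisy
# internal observation per interval (unit variance; means separated by d' on
# different-pairs) and responds "different" when the absolute difference of
# the two observations exceeds a criterion.  Hit and false-alarm rates follow
#   F = 2 * Phi(-k / sqrt(2))
#   H = Phi((d' - k) / sqrt(2)) + Phi((-d' - k) / sqrt(2))
# with k the criterion on the difference axis.

#' Enumerate ordered stimulus pairs
#'
#' All ordered pairs with replacement, in deterministic order (first id varies
#' slowest).  Three stimuli give the design's nine ordered pairs.
#'
#' @param stimuli character or numeric vector of stimulus ids (non-empty).
#' @return Data frame with columns \code{first}, \code{second}.
#' @examples
#' nrow(enumerate_pairs(c("a", "b", "c")))  # 9
#' @export
enumerate_pairs <- function(stimuli) {
  if (length(stimuli) < 1) stop("need at least one stimulus")
  stimuli <- as.character(stimuli)
  data.frame(first = rep(stimuli, each = length(stimuli)),
             second = rep(stimuli, times = length(stimuli)),
             stringsAsFactors = FALSE)
}

#' Percent correct responses
#'
#' @param trials trial data frame with logical column \code{correct} and
#'   (optionally) \code{condition}.
#' @param condition restrict to one condition label (default: all trials).
#' @return List: \code{percent_correct} (0-100) and \code{above_threshold}
#'   (TRUE iff >= the 75% same-different detection threshold).
#' @export
percent_correct <- function(trials, condition = NULL) {
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  if (nrow(trials) < 1) stop("no trials", if (!is.null(condition))
    paste0(" in condition '", condition, "'"))
  pc <- 100 * mean(trials$correct)
  list(percent_correct = pc, above_threshold = pc >= 75)
}

#' Extreme-rate correction
#'
#' Replaces observed rates of 0 and 1 by 1/(2N) and 1 - 1/(2N).
#'
#' @param rate observed proportion.
#' @param n number of trials behind the rate.
#' @return Corrected rate in (0, 1).
#' @export
correct_extreme_rate <- function(rate, n) {
  stopifnot(n >= 1)
  pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
}

dprime_forward <- function(dprime, k) {
  F <- 2 * stats::pnorm(-k / sqrt(2))
  H <- stats::pnorm((dprime - k) / sqrt(2)) + stats::pnorm((-dprime - k) / sqrt(2))
  list(H = H, F = F)
}

#' Sensitivity d' under the differencing rule
#'
#' Inverts the same-different differencing model: the criterion follows in
#' closed form from the false-alarm rate, \eqn{k = -\sqrt{2}\,
#' \Phi^{-1}(F/2)}, and d' is found by root-finding on the hit-rate equation.
#' d' is 0 when H <= F.
#'
#' @param H hit rate (proportion "different" on different-pairs), in (0, 1).
#' @param F false-alarm rate (proportion "different" on same-pairs), in (0, 1).
#' @return A \code{sensitivity_result} list: \code{H}, \code{F},
#'   \code{dprime}, \code{criterion} (the model's k).
#' @examples
#' r <- dprime_differencing(H = 0.8, F = 0.2)
#' r$dprime
#' @export
dprime_differencing <- function(H, F) {
  if (!is.finite(H) || !is.finite(F) || H <= 0 || H >= 1 || F <= 0 || F >= 1) {
    stop("rate error: H and F must lie strictly in (0, 1) after correction")
  }
  k <- -sqrt(2) * stats::qnorm(F / 2)
  if (H <= F) {
    d <- 0
  } else {
    fn <- function(d) dprime_forward(d, k)$H - H
    upper <- 1
    while (fn(upper) < 0 && upper < 100) upper <- upper * 2
    d <- stats::uniroot(fn, c(0, upper), tol = 1e-10)$root
  }
  structure(list(H = H, F = F, dprime = d, criterion = k),
            class = "sensitivity_result")
}

#' Simulated differencing observer
#'
#' Generates same-different responses from the differencing model: per trial,
#' two unit-variance internal observations whose means differ by \code{dprime}
#' on different-pairs; the observer responds "different" when the absolute
#' difference exceeds \code{criterion * sqrt(2)} (so the model criterion is
#' \eqn{k = criterion \cdot \sqrt 2}).
#'
#' @param dprime true sensitivity (>= 0).
#' @param criterion observer criterion (per-observation scale; the
#'   difference-axis criterion is \code{criterion * sqrt(2)}).
#' @param pairs data frame of ordered pairs ([enumerate_pairs()]), presented
#'   in row order; with \code{n_trials} set, trials are drawn uniformly with
#'   replacement from the rows instead.
#' @param n_trials optional number of trials to sample.
#' @param seed optional integer seed.
#' @param condition condition label stored on the records.
#' @return Trial data frame: \code{condition}, \code{first}, \code{second},
#'   \code{response} ("same"/"different"), \code{correct}.
#' @export
simulate_observer <- function(dprime, criterion, pairs, n_trials = NULL,
                              seed = NULL, condition = "sim") {
  if (!is.finite(dprime) || dprime < 0) stop("parameter error: dprime must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(n_trials)) {
    if (n_trials < 1) stop("n_trials must be >= 1")
    pairs <- pairs[sample.int(nrow(pairs), n_trials, replace = TRUE), ,
                   drop = FALSE]
  }
  n <- nrow(pairs)
  different <- pairs$first != pairs$second
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n, mean = ifelse(different, dprime, 0))
  resp <- ifelse(abs(x2 - x1) > criterion * sqrt(2), "different", "same")
  data.frame(condition = condition, first = pairs$first,
             second = pairs$second, response = resp,
             correct = (resp == "different") == different,
             stringsAsFactors = FALSE)
}

#' Observed hit and false-alarm rates of a trial table
#'
#' Proportion of "different" responses on different-pairs (H) and same-pairs
#' (F), extreme rates corrected to 1/(2N).
#'
#' @param trials trial data frame with columns \code{first}, \code{second},
#'   \code{response}.
#' @return List: \code{H}, \code{F}, \code{n_diff}, \code{n_same}.
#' @export
rates_from_trials <- function(trials) {
  diffpair <- trials$first != trials$second
  n_diff <- sum(diffpair)
  n_same <- sum(!diffpair)
  H <- if (n_diff > 0) {
    correct_extreme_rate(mean(trials$response[diffpair] == "different"), n_diff)
  } else NA_real_
  F <- if (n_same > 0) {
    correct_extreme_rate(mean(trials$response[!diffpair] == "different"), n_same)
  } else NA_real_
  list(H = H, F = F, n_diff = n_diff, n_same = n_same)
}

#' Per-condition psychophysics report
#'
#' One row per condition with percent correct (and the 75% threshold flag),
#' corrected hit / false-alarm rates, pooled d' and the unweighted mean of
#' per-pair d' (per-pair hit rates against the condition false-alarm rate),
#' plus a per-pair percent-correct breakdown.  Conditions lacking same-pairs
#' or different-pairs get NA sensitivity with a warning; empty conditions are
#' omitted with a warning.
#'
#' @param trials trial data frame (columns \code{condition}, \code{first},
#'   \code{second}, \code{response}, \code{correct}).
#' @return List of data frames: \code{conditions} and \code{pairs}.
#' @export
condition_report <- function(trials) {
  stopifnot(all(c("condition", "first", "second", "response", "correct")
                %in% names(trials)))
  conds <- unique(trials$condition)
  cond_rows <- list()
  pair_rows <- list()
  for (cc in conds) {
    tr <- trials[trials$condition == cc, ]
    if (nrow(tr) == 0) {
      warning("condition '", cc, "' has no trials; omitted")
      next
    }
    pc <- percent_correct(tr)
    rt <- rates_from_trials(tr)
    if (is.na(rt$H) || is.na(rt$F)) {
      warning("condition '", cc,
              "' lacks same-pairs or different-pairs; d' undefined")
      dp <- NA_real_
      kk <- NA_real_
      dp_pair <- NA_real_
    } else {
      sens <- dprime_differencing(rt$H, rt$F)
      dp <- sens$dprime
      kk <- sens$criterion
      # unweighted mean of per-pair d' over different-pairs
      dps <- c()
      dp_tr <- tr[tr$first != tr$second, ]
      for (key in unique(paste(dp_tr$first, dp_tr$second, sep = "|"))) {
        sel <- paste(dp_tr$first, dp_tr$second, sep = "|") == key
        Hp <- correct_extreme_rate(mean(dp_tr$response[sel] == "different"),
                                   sum(sel))
        dps <- c(dps, dprime_differencing(Hp, rt$F)$dprime)
      }
      dp_pair <- mean(dps)
    }
    cond_rows[[cc]] <- data.frame(
      condition = cc, n_trials = nrow(tr),
      percent_correct = pc$percent_correct,
      above_threshold = pc$above_threshold,
      H = rt$H, F = rt$F, dprime_pooled = dp, dprime_pair_mean = dp_pair,
      criterion = kk, stringsAsFactors = FALSE)
    ag <- stats::aggregate(correct ~ first + second, data = tr, FUN = mean)
    ag$n <- stats::aggregate(correct ~ first + second, data = tr,
                             FUN = length)$correct
    pair_rows[[cc]] <- data.frame(condition = cc, first = ag$first,
                                  second = ag$second, n = ag$n,
                                  percent_correct = 100 * ag$correct,
                                  stringsAsFactors = FALSE)
  }
  list(conditions = do.call(rbind, c(cond_rows, make.row.names = FALSE)),
       pairs = do.call(rbind, c(pair_rows, make.row.names = FALSE)))
}
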