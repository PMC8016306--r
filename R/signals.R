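# Force / laser-displacement trace processing: moving-average smoothing, ramp
# segmentation from first differences, force-rate regression, and net
# displacement between movement landmarks.

#' Construct a uniformly sampled trace
#'
#' @param values numeric signal (N for force, mm for displacement).
#' @param sample_rate sampling rate (Hz); protocol defaults are 300 Hz
#'   (passive force), 80 Hz (active force) and 1500 Hz (laser displacement).
#' @param t0 time of the first sample (s).
#' @return A \code{trace}: data frame (time_s, value) with a
#'   \code{sample_rate} attribute.
#' @export
new_trace <- function(values, sample_rate, t0 = 0) {
  if (length(values) < 2) stop("trace needs at least 2 samples")
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive")
  }
  structure(data.frame(time_s = t0 + (seq_along(values) - 1) / sample_rate,
                       value = as.numeric(values)),
            sample_rate = sample_rate, class = c("trace", "data.frame"))
}

#' Validate and convert a (time, value) data frame into a trace
#'
#' Timestamps must be strictly increasing and uniform within 1%.
#'
#' @param df data frame with columns \code{time_s} and \code{value}.
#' @return A \code{trace}.
#' @export
as_trace <- function(df) {
  stopifnot(all(c("time_s", "value") %in% names(df)), nrow(df) >= 2)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if ((max(dt) - min(dt)) > 0.01 * mean(dt)) {
    stop("timestamps must be uniform within 1%")
  }
  structure(data.frame(time_s = df$time_s, value = df$value),
            sample_rate = 1 / mean(dt), class = c("trace", "data.frame"))
}

#' Moving-average smoothing
#'
#' Moving mean over \code{window} neighbouring readings (default 100), output
#' the same length as the input; the window is truncated (shrinks) at the
#' trace boundaries.  Constant traces are unchanged.
#'
#' @param trace a [new_trace()] object.
#' @param window window length in samples (>= 1, <= trace length).
#' @return Smoothed \code{trace}.
#' @export
smooth_trace <- function(trace, window = 100) {
  stopifnot(inherits(trace, "trace"))
  n <- nrow(trace)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds trace length (", n, ")")
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- cumsum(c(0, trace$value))
  out <- trace
  out$value <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out
}

#' Extract the loading ramp of a force trace
#'
#' Finds the longest contiguous run of samples whose first-order derivative
#' exceeds a fraction (default 0.2) of the peak positive rate, i.e. the
#' ascending limb of the protocol waveform.
#'
#' The ascending limb is found on a lagged central-difference derivative (lag
#' \code{deriv_lag} samples), which keeps the detection robust to sensor noise
#' that per-sample first differences would amplify.  The segment boundaries
#' are then refined to the intersections of a line fitted to the ramp interior
#' with lines fitted just before and just after the detected run (the
#' hold/baseline before, and the plateau or descending limb after), so on a
#' clean piecewise-linear signal the reported boundaries are the exact
#' corners.  The slope is fitted on the interior of the segment
#' (\code{fit_margin} trimmed from each end) so the rounded shoulders left by
#' a moving-average filter do not bias the rate.
#'
#' @param trace a (smoothed) force \code{trace}.
#' @param threshold fraction of the peak derivative (default 0.2).
#' @param min_run minimum run length in samples (default 2).
#' @param deriv_lag half-width of the lagged derivative (samples); default
#'   \code{max(2, min(50, n \%/\% 8))}.
#' @param fit_margin fraction of the segment trimmed from each end for the
#'   slope fit (default 0.15).
#' @return A \code{ramp_segment} list: \code{start_index}, \code{end_index}
#'   (inclusive, into the trace), \code{fit_start}, \code{fit_end},
#'   \code{slope} (N/s), \code{r2}.
#' @export
extract_ramp <- function(trace, threshold = 0.2, min_run = 2L,
                         deriv_lag = NULL, fit_margin = 0.15) {
  stopifnot(inherits(trace, "trace"))
  n <- nrow(trace)
  v <- trace$value
  tt <- trace$time_s
  if (is.null(deriv_lag)) deriv_lag <- max(2L, min(50L, n %/% 8L))
  lag <- min(as.integer(deriv_lag), (n - 1L) %/% 2L)
  lag <- max(lag, 1L)
  i <- (lag + 1L):(n - lag)
  rate <- (v[i + lag] - v[i - lag]) / (tt[i + lag] - tt[i - lag])
  peak <- max(rate)
  if (!is.finite(peak) || peak <= 1e-12) {
    stop("no-ramp error: trace has no rising segment")
  }
  above <- rate > threshold * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= max(1L, min_run - 1L))
  if (length(cand) == 0) stop("no-ramp error: no run above the rate threshold")
  best <- cand[which.max(r$lengths[cand])]
  s <- i[starts[best]] # coarse boundaries in trace indices
  e <- i[ends[best]]

  line_fit <- function(idx) {
    if (length(idx) < 2) return(NULL)
    cf <- stats::coef(stats::lm(v[idx] ~ tt[idx]))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  # interior ramp line
  pad <- max(1L, floor(0.25 * (e - s)))
  L1 <- line_fit(max(s, s + pad):min(e, e - pad))
  if (is.null(L1)) L1 <- line_fit(s:e)
  cross <- function(L1, L2, fallback) {
    if (is.null(L1) || is.null(L2) ||
        abs(L1["slope"] - L2["slope"]) < 1e-9 * max(1, abs(L1["slope"]))) {
      return(fallback)
    }
    t_star <- (L2["intercept"] - L1["intercept"]) / (L1["slope"] - L2["slope"])
    idx <- which.min(abs(tt - t_star))
    idx
  }
  pre <- if (s - lag >= 2) line_fit(max(1L, s - 6L * lag):(s - 1L)) else NULL
  post <- if (e + lag <= n - 1) line_fit((e + 1L):min(n, e + 6L * lag)) else NULL
  s_ref <- if (is.null(pre)) if (s <= 2L * lag) 1L else s else cross(L1, pre, s)
  e_ref <- if (is.null(post)) if (e >= n - 2L * lag) n else e else cross(L1, post, e)
  s <- max(1L, min(s_ref, e_ref - 1L))
  e <- min(n, max(e_ref, s + 1L))

  m <- max(0L, floor(fit_margin * (e - s)))
  fit_s <- min(s + m, e - 1L)
  fit_e <- max(e - m, fit_s + 1L)
  seg <- structure(list(start_index = s, end_index = e,
                        fit_start = fit_s, fit_end = fit_e,
                        slope = NA_real_, r2 = NA_real_),
                   class = "ramp_segment")
  fit <- ramp_fit(seg, trace)
  seg$slope <- fit$slope
  seg$r2 <- fit$r2
  seg
}

ramp_fit <- function(segment, trace) {
  fs <- segment$fit_start
  fe <- segment$fit_end
  if (is.null(fs) || is.null(fe)) {
    fs <- segment$start_index
    fe <- segment$end_index
  }
  idx <- fs:fe
  tt <- trace$time_s[idx]
  vv <- trace$value[idx]
  if (diff(range(tt)) <= 0) stop("degenerate time span in ramp segment")
  fit <- stats::lm(vv ~ tt)
  ss_tot <- sum((vv - mean(vv))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(slope = unname(stats::coef(fit)[2]), r2 = r2)
}

#' Force rate of a ramp segment
#'
#' Ordinary-least-squares slope of force against time over the segment (N/s).
#'
#' @param segment a [extract_ramp()] result.
#' @param trace the force \code{trace} the segment indexes into.
#' @return Slope in N/s.
#' @export
force_rate <- function(segment, trace) {
  stopifnot(inherits(segment, "ramp_segment"), inherits(trace, "trace"))
  if (segment$start_index < 1 || segment$end_index > nrow(trace) ||
      segment$start_index >= segment$end_index) {
    stop("invalid segment indices")
  }
  ramp_fit(segment, trace)$slope
}

#' Net displacement between movement landmarks
#'
#' Absolute difference of the displacement trace between the initiation and
#' conclusion of a movement (indices typically taken from the time-aligned
#' force-trace ramp boundaries).
#'
#' @param trace displacement \code{trace} (mm).
#' @param start_index,end_index sample indices of movement initiation and
#'   conclusion.
#' @return Net displacement (mm).
#' @export
net_displacement <- function(trace, start_index, end_index) {
  stopifnot(inherits(trace, "trace"))
  n <- nrow(trace)
  if (start_index < 1 || end_index < 1 || start_index > n || end_index > n) {
    stop("indices out of range")
  }
  abs(trace$value[end_index] - trace$value[start_index])
}
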