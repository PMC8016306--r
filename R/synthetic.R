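# Seeded generators for every input the pipeline consumes: protocol force
# traces, laser displacement traces consistent with a force-displacement
# relation, ink-stamped fingerprint images with known ground-truth area and a
# 5.0 cm reference bar, full same-different sessions from the differencing
# observer, and material-calibration target curves.  Every generator is a pure
# function of (spec, seed) and returns ground truth alongside the data.

#' Indentation protocol specification
#'
#' Triangle-wave profiles (ramp up / ramp down, peaks 1, 2 or 3 N) for the
#' biomechanical measurements, and constant-rate ramps (0.5, 1 or 2 N/s to
#' 2 N) for the psychophysical force-rate conditions.
#'
#' @param kind "triangle" or "constant-rate".
#' @param peak peak / terminal force (N).
#' @param rate force rate (N/s; constant-rate only).
#' @param ramp_duration ramp duration per limb (s; triangle only, default 1).
#' @param sample_rate sampling rate (Hz, default 300).
#' @param noise_sd additive Gaussian sensor noise SD (N).
#' @param lead_hold,tail_hold flat zero / terminal hold durations (s).
#' @return A \code{protocol_spec} list.
#' @export
protocol_spec <- function(kind = c("triangle", "constant-rate"),
                          peak = 2, rate = 1, ramp_duration = 1,
                          sample_rate = 300, noise_sd = 0,
                          lead_hold = 0.5, tail_hold = 0.5) {
  kind <- match.arg(kind)
  if (peak <= 0) stop("peak force must be positive")
  if (kind == "constant-rate" && rate <= 0) stop("rate must be positive")
  if (kind == "triangle" && ramp_duration <= 0) stop("ramp duration must be positive")
  structure(list(kind = kind, peak = peak, rate = rate,
                 ramp_duration = ramp_duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, lead_hold = lead_hold,
                 tail_hold = tail_hold),
            class = "protocol_spec")
}

protocol_backbone <- function(spec, t) {
  t1 <- spec$lead_hold
  if (spec$kind == "triangle") {
    up <- spec$ramp_duration
    f <- ifelse(t < t1, 0,
         ifelse(t < t1 + up, (t - t1) / up * spec$peak,
         ifelse(t < t1 + 2 * up, spec$peak - (t - t1 - up) / up * spec$peak, 0)))
  } else {
    dur <- spec$peak / spec$rate
    f <- ifelse(t < t1, 0,
         ifelse(t < t1 + dur, (t - t1) * spec$rate, spec$peak))
  }
  pmax(f, 0)
}

#' Generate a protocol force trace
#'
#' Noiseless backbone is the exact protocol waveform (with lead/tail holds);
#' additive Gaussian noise at the specified SD; reproducible under the seed.
#'
#' @param spec a [protocol_spec()].
#' @param seed optional integer seed.
#' @return A force \code{trace} (N) with attribute \code{spec}.
#' @export
gen_force_trace <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (!is.null(seed)) set.seed(seed)
  dur <- spec$lead_hold + spec$tail_hold +
    if (spec$kind == "triangle") 2 * spec$ramp_duration else spec$peak / spec$rate
  n <- round(dur * spec$sample_rate) + 1
  t <- (seq_len(n) - 1) / spec$sample_rate
  f <- protocol_backbone(spec, t)
  if (spec$noise_sd > 0) f <- f + stats::rnorm(n, 0, spec$noise_sd)
  out <- new_trace(f, spec$sample_rate)
  attr(out, "spec") <- spec
  out
}

#' Generate a laser displacement trace from a force trace
#'
#' Maps the force channel through a force-displacement relation (a
#' \code{force_displacement} data frame from the contact model, or a scalar
#' linear stiffness k in N/mm) and adds seeded Gaussian noise; time-aligned
#' with the force trace.
#'
#' @param force_trace a force \code{trace} (N).
#' @param stiffness_source \code{force_displacement} data frame or scalar
#'   stiffness (N/mm).
#' @param noise_sd displacement noise SD (mm).
#' @param seed optional integer seed.
#' @return A displacement \code{trace} (mm).
#' @export
gen_displacement_trace <- function(force_trace, stiffness_source,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(inherits(force_trace, "trace"))
  if (!is.null(seed)) set.seed(seed)
  f <- force_trace$value
  if (is.numeric(stiffness_source) && length(stiffness_source) == 1) {
    u <- f / stiffness_source
  } else {
    fd <- stiffness_source
    stopifnot(all(c("displacement_mm", "force_N") %in% names(fd)))
    if (max(f) > max(fd$force_N) + 1e-9) {
      stop("force exceeds the range of the force-displacement curve")
    }
    u <- stats::approx(fd$force_N, fd$displacement_mm, pmax(f, 0),
                       rule = 2, ties = "ordered")$y
  }
  if (noise_sd > 0) u <- u + stats::rnorm(length(u), 0, noise_sd)
  out <- new_trace(u, attr(force_trace, "sample_rate"))
  out$time_s <- force_trace$time_s
  out
}

#' Generate a synthetic ink-stamped fingerprint image
#'
#' Elliptical ink blob of the requested physical area, a reference bar of the
#' requested physical length, seeded speckle noise (white dropouts inside the
#' blob, ink specks outside) and boundary jitter.  Ground truth (pixel mask,
#' bar pixels, suggested ROI) is returned alongside.
#'
#' @param true_area blob area (cm^2).
#' @param scale image scale (cm per pixel, default 0.005).
#' @param bar_length reference bar length (cm, default 5.0).
#' @param aspect blob axis ratio (default 1.35, fingerprint-like).
#' @param speckle fraction of blob/background pixels flipped (default 0.01).
#' @param jitter relative boundary radius jitter (default 0.01).
#' @param seed optional integer seed.
#' @return List: \code{image} (an [ink_image()] with ROI attribute) and
#'   \code{truth} (mask, area_cm2, bar_pixels, roi).
#' @export
gen_ink_image <- function(true_area, scale = 0.005, bar_length = 5.0,
                          aspect = 1.35, speckle = 0.01, jitter = 0.01,
                          seed = NULL) {
  if (true_area <= 0) stop("true_area must be positive")
  if (!is.null(seed)) set.seed(seed)
  area_px <- true_area / scale^2
  a <- sqrt(area_px * aspect / pi) # semi-axis along rows
  b <- area_px / (pi * a)
  bar_px <- round(bar_length / scale)
  bar_rows <- 2:5
  margin <- 20
  roi_r <- max(a, b) * (1 + jitter) * 1.05 + 8
  # blob centre low enough that the ROI clears the reference bar
  cr <- ceiling(max(bar_rows) + 8 + roi_r)
  h <- ceiling(cr + a * (1 + jitter) + margin)
  w <- max(ceiling(2 * b * (1 + jitter) + 2 * margin), bar_px + 2 * margin)
  cc <- w / 2
  if (2 * a + max(bar_rows) + 2 > h || 2 * b + 2 > w) {
    stop("blob larger than canvas")
  }
  ri <- matrix(seq_len(h), h, w)
  ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  ang <- atan2(ri - cr, ci - cc)
  wob <- 1 + jitter * sin(3 * ang + stats::runif(1, 0, 2 * pi))
  mask <- ((ri - cr) / (a * wob))^2 + ((ci - cc) / (b * wob))^2 <= 1
  img <- array(1, dim = c(h, w, 3))
  ink <- c(0.25, 0.25, 0.6) # washable blue
  for (k in 1:3) {
    ch <- img[, , k]
    ch[mask] <- ink[k] + stats::rnorm(sum(mask), 0, 0.03)
    img[, , k] <- ch
  }
  # speckle: white dropouts inside, ink specks outside
  if (speckle > 0) {
    drop <- mask & (matrix(stats::runif(h * w), h, w) < speckle)
    spk <- !mask & (matrix(stats::runif(h * w), h, w) < speckle / 4)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[drop] <- 1
      ch[spk] <- ink[k]
      img[, , k] <- ch
    }
  }
  # reference bar (top-left, outside the ROI)
  img[bar_rows, margin + seq_len(bar_px), ] <- 0
  img <- pmin(pmax(img, 0), 1)
  roi <- c(cr, cc, roi_r)
  out <- ink_image(img, bar_pixels = bar_px, bar_length = bar_length)
  attr(out, "roi") <- roi
  list(image = out,
       truth = list(mask = mask, area_cm2 = true_area, bar_pixels = bar_px,
                    roi = roi, scale_cm_px = scale))
}

#' Session specification for synthetic psychophysics
#'
#' @param conditions data frame with columns \code{condition}, \code{dprime},
#'   \code{criterion}, \code{repetitions}.  Defaults mirror the four
#'   experimental tasks (passive same / inverse / direct force-rate and
#'   active same force-rate; 2 repetitions per pair for passive tasks, 3 for
#'   active) with observer sensitivities spanning chance to high.
#' @param stimuli stimulus ids (default the three illusion case spheres).
#' @param participants number of simulated participants.
#' @param seed integer seed.
#' @return A \code{session_spec} list.
#' @export
session_spec <- function(conditions = NULL,
                         stimuli = c("10kPa-4mm", "90kPa-6mm", "90kPa-8mm"),
                         participants = 10L, seed = 1L) {
  if (is.null(conditions)) {
    conditions <- data.frame(
      condition = c("passive-same-rate", "passive-inverse-rate",
                    "passive-direct-rate", "active-same-rate"),
      dprime = c(0.4, 1.2, 2.4, 3.5),
      criterion = 1.2,
      repetitions = c(2L, 2L, 2L, 3L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(conditions$repetitions >= 1), all(conditions$dprime >= 0),
            participants >= 1)
  structure(list(conditions = conditions, stimuli = stimuli,
                 participants = as.integer(participants),
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Generate a full synthetic same-different session
#'
#' Full factorial design (all ordered pairs x repetitions x participants x
#' conditions) with a seeded randomised presentation order per participant and
#' condition; responses from the differencing observer at each condition's
#' sensitivity.
#'
#' @param spec a [session_spec()].
#' @return Trial data frame: participant, condition, first, second, response,
#'   correct.
#' @export
gen_session <- function(spec = session_spec()) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(spec$seed)
  pairs <- enumerate_pairs(spec$stimuli)
  out <- list()
  for (p in seq_len(spec$participants)) {
    for (i in seq_len(nrow(spec$conditions))) {
      cn <- spec$conditions[i, ]
      design <- pairs[rep(seq_len(nrow(pairs)), cn$repetitions), ]
      design <- design[sample.int(nrow(design)), ] # randomised presentation
      tr <- simulate_observer(cn$dprime, cn$criterion, design,
                              condition = cn$condition)
      tr$participant <- p
      out[[length(out) + 1]] <- tr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("participant", "condition", "first", "second", "response", "correct")]
}

#' Generate material-calibration target curves from known moduli
#'
#' Runs the calibration forward models (plane-strain deflection profiles and
#' axisymmetric force-displacement) at the given layer moduli and adds seeded
#' Gaussian noise; the generating truth is recorded.
#'
#' @param moduli numeric vector of three layer shear moduli (kPa):
#'   epidermis, dermis, subcutaneous.
#' @param noise_sd relative noise SD applied to both curve families
#'   (default 0).
#' @param seed optional integer seed.
#' @param cfg forward-model configuration ([calibration_config()]).
#' @return A [calibration_targets()] with attribute \code{truth}.
#' @export
gen_calibration_targets <- function(moduli, noise_sd = 0, seed = NULL,
                                    cfg = calibration_config()) {
  stopifnot(length(moduli) == 3, all(moduli > 0))
  if (!is.null(seed)) set.seed(seed)
  defl <- calib_forward_deflection(moduli, cfg, window = TRUE)
  if (noise_sd > 0) {
    defl <- lapply(defl, function(d) {
      d$deflection_mm <- d$deflection_mm +
        stats::rnorm(nrow(d), 0, noise_sd * max(abs(d$deflection_mm)))
      d
    })
  }
  fd <- calib_forward_fd(moduli, cfg)
  if (noise_sd > 0) {
    fd$force_N <- fd$force_N + stats::rnorm(nrow(fd), 0, noise_sd * max(fd$force_N))
    fd$force_N <- cummax(pmax(fd$force_N, 0)) # keep targets monotone
  }
  out <- calibration_targets(defl, fd, provenance = "synthetic")
  attr(out, "truth") <- list(moduli = moduli,
                             ratios = moduli[2:3] / moduli[1], cfg = cfg)
  out
}
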