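# Two-step material calibration of the layered fingertip:
#   1. layer-modulus RATIOS from surface-deflection targets (plane-strain
#      model, displacement-controlled indentation -- the deflection field is
#      invariant to a uniform modulus scaling, so ratios are identified
#      separately from the scale),
#   2. a single global SCALE from force-displacement targets (axisymmetric
#      model; by homogeneity of the equilibrium equations in the modulus,
#      forces at fixed displacement scale linearly, so one forward run
#      suffices).
# Grid points with R^2 >= 0.8 are averaged to give the selected ratios.

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res} / SS_{tot}} of aligned equal-length curves.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Dimensionless scalar (<= 1).
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("curves must be aligned")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= .Machine$double.eps) {
    stop("undefined R^2: observed curve is constant")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Default forward-model configuration for calibration runs
#'
#' Coarse fingertip discretisations and indenter settings used by the
#' calibration forward models and by [gen_calibration_targets()].
#'
#' @param n_interface interface nodes of the calibration meshes.
#' @param divisions element rows per layer.
#' @param thicknesses layer thicknesses (mm).
#' @param kappa_ratio bulk/shear ratio.
#' @param indenter_radius rigid indenter radius (mm).
#' @param deflection_depths indentation depths for the deflection step (mm);
#'   shallow and deep depths probe different layers.
#' @param deflection_window arc-length range (mm) of the deflection targets:
#'   the free surface outside the indenter footprint, i.e. what an optical
#'   measurement around the probe can see.  The in-contact region carries the
#'   imposed indenter shape and no layer information.
#' @param fd_displacements indenter depths for the force-displacement step (mm).
#' @return Config list.
#' @export
calibration_config <- function(n_interface = 31L, divisions = c(2L, 2L, 2L),
                               thicknesses = c(0.470, 1.2, 3.0),
                               kappa_ratio = 50,
                               indenter_radius = 2,
                               deflection_depths = c(0.3, 0.8, 1.3),
                               deflection_window = c(2.5, 12),
                               fd_displacements = seq(0.2, 1.2, by = 0.2)) {
  list(n_interface = as.integer(n_interface), divisions = as.integer(divisions),
       thicknesses = thicknesses, kappa_ratio = kappa_ratio,
       indenter_radius = indenter_radius,
       deflection_depths = deflection_depths,
       deflection_window = deflection_window,
       fd_displacements = fd_displacements)
}

calib_model <- function(moduli, cfg, formulation) {
  layers <- default_layer_stack(moduli = moduli, thicknesses = cfg$thicknesses,
                                divisions = cfg$divisions,
                                kappa_ratio = cfg$kappa_ratio)
  build_fingertip_model(fingertip_geometry(formulation = formulation,
                                           layers = layers,
                                           n_interface = cfg$n_interface))
}

# Surface deflection profiles at prescribed indenter depths (plane strain),
# windowed to the visible free surface when the config requests it.
calib_forward_deflection <- function(moduli, cfg = calibration_config(),
                                     window = FALSE) {
  model <- calib_model(moduli, cfg, "plane-strain")
  states <- indent_rigid_sphere(model, radius = cfg$indenter_radius,
                                depths = cfg$deflection_depths)
  lapply(seq_along(states), function(k) {
    pr <- surface_deflection_profile(states[[k]], model)
    d <- data.frame(location_mm = pr$location_mm, deflection_mm = pr$value,
                    depth_mm = cfg$deflection_depths[k])
    if (window && !is.null(cfg$deflection_window)) {
      d <- d[d$location_mm >= cfg$deflection_window[1] &
             d$location_mm <= cfg$deflection_window[2], ]
    }
    d
  })
}

# Force at prescribed indenter depths (axisymmetric).
calib_forward_fd <- function(moduli, cfg = calibration_config()) {
  model <- calib_model(moduli, cfg, "axisymmetric")
  states <- indent_rigid_sphere(model, radius = cfg$indenter_radius,
                                depths = cfg$fd_displacements)
  data.frame(displacement_mm = cfg$fd_displacements,
             force_N = vapply(states, function(s) s$load, 0))
}

#' Calibration target container
#'
#' @param deflection_curves list of data frames (location_mm, deflection_mm,
#'   depth_mm), one per indenter depth.
#' @param fd_curve data frame (displacement_mm, force_N), displacement
#'   monotone.
#' @param provenance "synthetic" or "user-supplied".
#' @return A \code{calibration_targets} list.
#' @export
calibration_targets <- function(deflection_curves, fd_curve,
                                provenance = "user-supplied") {
  for (cv in deflection_curves) {
    if (nrow(cv) < 3) stop("each deflection curve needs >= 3 samples")
  }
  if (!is.null(fd_curve)) {
    if (nrow(fd_curve) < 1) stop("data error: empty force-displacement targets")
    if (any(fd_curve$displacement_mm < 0)) stop("displacements must be non-negative")
  }
  structure(list(deflection_curves = deflection_curves, fd_curve = fd_curve,
                 provenance = provenance),
            class = "calibration_targets")
}

#' Fit layer-modulus ratios to surface-deflection targets
#'
#' Evaluates the plane-strain forward model on a grid of
#' (dermis : epidermis, subcutaneous : epidermis) modulus ratios, scores each
#' grid point by R^2 against the pooled deflection targets, and returns the
#' mean of all grid points reaching the acceptance threshold (default 0.8).
#'
#' @param targets a [calibration_targets()] with deflection curves.
#' @param grid list with numeric vectors \code{dermis} and \code{subcutaneous}
#'   (>= 2 points per axis).
#' @param cfg forward-model configuration ([calibration_config()]).
#' @param threshold R^2 acceptance threshold (default 0.8).
#' @return A \code{layer_ratio_fit}: \code{grid} (data frame with r2 per
#'   point), \code{selected} (named ratios), \code{threshold}.
#' @export
fit_layer_ratios <- function(targets, grid = list(dermis = c(0.25, 0.5, 0.75, 1),
                                                  subcutaneous = c(0.125, 0.25, 0.5)),
                             cfg = calibration_config(), threshold = 0.8) {
  stopifnot(inherits(targets, "calibration_targets"))
  if (length(grid$dermis) < 2 || length(grid$subcutaneous) < 2) {
    stop("grid needs >= 2 points per ratio axis")
  }
  obs <- unlist(lapply(targets$deflection_curves, function(d) d$deflection_mm))
  pts <- expand.grid(dermis = grid$dermis, subcutaneous = grid$subcutaneous)
  pts$r2 <- NA_real_
  for (i in seq_len(nrow(pts))) {
    pred_curves <- calib_forward_deflection(
      c(1, pts$dermis[i], pts$subcutaneous[i]), cfg)
    pred <- unlist(lapply(seq_along(pred_curves), function(k) {
      stats::approx(pred_curves[[k]]$location_mm,
                    pred_curves[[k]]$deflection_mm,
                    targets$deflection_curves[[k]]$location_mm, rule = 2)$y
    }))
    pts$r2[i] <- r_squared(pred, obs)
  }
  ok <- pts$r2 >= threshold
  if (!any(ok)) {
    stop(sprintf("fit-failure: no grid point reaches R^2 >= %.2f (best %.3f)",
                 threshold, max(pts$r2)))
  }
  structure(list(grid = pts,
                 selected = c(dermis = mean(pts$dermis[ok]),
                              subcutaneous = mean(pts$subcutaneous[ok])),
                 threshold = threshold),
            class = "layer_ratio_fit")
}

#' Scale fitted layer ratios to force-displacement targets
#'
#' Finds the positive global modulus scale minimising the squared force error
#' of the axisymmetric model against the targets, by golden-section/parabolic
#' 1-D minimisation on the log-scale.  The forward model is run once: by
#' homogeneity, forces at fixed displacement are proportional to the scale.
#'
#' @param ratios named ratios from [fit_layer_ratios()] (or a
#'   \code{layer_ratio_fit}).
#' @param fd_targets data frame (displacement_mm, force_N), monotone.
#' @param cfg forward-model configuration.
#' @return Named numeric vector of absolute layer shear moduli (kPa):
#'   epidermis, dermis, subcutaneous; attribute \code{scale}.
#' @export
scale_to_force_displacement <- function(ratios, fd_targets,
                                        cfg = calibration_config()) {
  if (inherits(ratios, "layer_ratio_fit")) ratios <- ratios$selected
  if (is.null(fd_targets) || nrow(fd_targets) < 1) {
    stop("data error: empty force-displacement targets")
  }
  if (is.unsorted(fd_targets$displacement_mm) ||
      is.unsorted(fd_targets$force_N)) {
    stop("data error: force-displacement targets must be monotone")
  }
  cfg$fd_displacements <- fd_targets$displacement_mm
  base <- calib_forward_fd(c(1, ratios[["dermis"]], ratios[["subcutaneous"]]),
                           cfg)
  fm <- base$force_N
  fo <- fd_targets$force_N
  obj <- function(logs) sum((exp(logs) * fm - fo)^2)
  opt <- stats::optimize(obj, interval = log(c(1e-4, 1e6)), tol = 1e-10)
  s <- exp(opt$minimum)
  out <- s * c(epidermis = 1, dermis = ratios[["dermis"]],
               subcutaneous = ratios[["subcutaneous"]])
  attr(out, "scale") <- s
  out
}
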