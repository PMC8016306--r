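# Cutaneous and proprioceptive cue extraction from solved contact states.
#
# Cutaneous cues live at the epidermal-dermal interface (stress, strain energy
# density) and at the skin surface (deflection); the proprioceptive cue is the
# fingertip force-displacement relation.  Interface profiles follow the
# neighbour-averaging rule: the value at an interface node is the arithmetic
# mean of the element field over all elements adjacent to that node.

new_cue_profile <- function(location, value, cue, load = NA_real_) {
  structure(data.frame(location_mm = location, value = value),
            cue = cue, load_N = load,
            class = c("cue_profile", "data.frame"))
}

node_average_field <- function(state, model, column) {
  stopifnot(inherits(state, "solution_state"))
  fields <- state$element_fields
  nodes <- model$interface_nodes$node
  vapply(nodes, function(nd) {
    adj <- model$node2elem[[nd]]
    if (length(adj) == 0) {
      stop("mesh-integrity error: interface node ", nd, " has no adjacent elements")
    }
    mean(fields[adj, column])
  }, 0)
}

#' Interface stress profile
#'
#' Scalar stress at each epidermal-dermal interface node, averaged over the
#' elements adjacent to the node, against the interface arc-length coordinate.
#' The default scalar is the von Mises stress; "normal" selects the axial
#' normal component.
#'
#' @param state a \code{solution_state} from [solve_contact()].
#' @param model the fingertip model the state was solved on.
#' @param measure "von_mises" or "normal".
#' @return A \code{cue_profile} data frame (location_mm, value), value in kPa.
#' @export
interface_stress_profile <- function(state, model,
                                     measure = c("von_mises", "normal")) {
  measure <- match.arg(measure)
  col <- if (measure == "von_mises") "von_mises" else "s_zz"
  v <- node_average_field(state, model, col)
  new_cue_profile(model$interface_nodes$arc, v, paste0("stress_", measure),
                  state$load)
}

#' Interface strain-energy-density profile
#'
#' @inheritParams interface_stress_profile
#' @return A \code{cue_profile}, value in kPa (mJ/mm^3 x 1e-3).
#' @export
interface_sed_profile <- function(state, model) {
  v <- node_average_field(state, model, "sed")
  new_cue_profile(model$interface_nodes$arc, v, "sed", state$load)
}

#' Skin-surface deflection profile
#'
#' Inward normal displacement of the epidermis surface nodes against the
#' surface arc-length coordinate (positive = skin pressed inward).
#'
#' @inheritParams interface_stress_profile
#' @return A \code{cue_profile}, value in mm.
#' @export
surface_deflection_profile <- function(state, model) {
  sn <- model$surface_nodes$node
  ux <- state$u[2 * sn - 1]
  uz <- state$u[2 * sn]
  if (identical(state$mode, "active")) {
    # the fingertip core is the driven body: deflection is measured in the
    # body frame, net of the rigid travel
    uz <- uz - state$rigid_body_travel
  }
  if (!is.null(model$outer_radius) && is.finite(model$outer_radius)) {
    ctr <- c(0, -model$outer_radius)
    dx <- model$nodes[sn, 1] - ctr[1]
    dz <- model$nodes[sn, 2] - ctr[2]
    nrm <- sqrt(dx^2 + dz^2)
    defl <- -(ux * dx + uz * dz) / nrm
  } else {
    defl <- -uz
  }
  new_cue_profile(model$surface_nodes$arc, defl, "deflection", state$load)
}

#' Force-displacement curve of the fingertip
#'
#' Proprioceptive cue: the normal force against the fingertip travel needed to
#' reach it, assembled from the states of an active-mode solve.  The curve
#' always includes the origin.
#'
#' @param states a \code{solution_set} or list of \code{solution_state} from an
#'   active-mode problem.
#' @return Data frame (displacement_mm, force_N), class
#'   \code{force_displacement}.
#' @export
force_displacement_curve <- function(states) {
  if (inherits(states, "solution_set")) states <- states$states
  if (length(states) < 1) stop("need at least one solved state")
  modes <- unique(vapply(states, function(s) s$mode, ""))
  if (length(modes) > 1) stop("mixed-mode states are not a single curve")
  if (modes != "active") {
    stop("force_displacement_curve requires active-mode states")
  }
  d <- vapply(states, function(s) s$rigid_body_travel, 0)
  f <- vapply(states, function(s) s$load, 0)
  o <- order(f)
  d <- d[o]
  f <- f[o]
  if (f[1] > 1e-12) {
    d <- c(0, d)
    f <- c(0, f)
  }
  if (is.unsorted(d)) stop("displacement not monotone with force")
  structure(data.frame(displacement_mm = d, force_N = f),
            class = c("force_displacement", "data.frame"))
}

#' Normalised RMS distance between two cue profiles
#'
#' Dimensionless dissimilarity: the root-mean-square difference between the
#' profiles over their common location range, divided by the RMS of the pooled
#' profiles.  Zero iff identical; symmetric.  Profiles sampled at different
#' locations are linearly resampled onto the overlap.
#'
#' @param a,b \code{cue_profile} data frames.
#' @return Non-negative scalar.
#' @export
cue_distance <- function(a, b) {
  stopifnot(inherits(a, "cue_profile"), inherits(b, "cue_profile"))
  la <- a$location_mm
  lb <- b$location_mm
  if (isTRUE(all.equal(la, lb))) {
    va <- a$value
    vb <- b$value
  } else {
    lo <- max(min(la), min(lb))
    hi <- min(max(la), max(lb))
    if (hi <= lo) stop("cue profiles have disjoint location ranges")
    grid <- sort(unique(c(la[la >= lo & la <= hi], lb[lb >= lo & lb <= hi])))
    va <- stats::approx(la, a$value, grid)$y
    vb <- stats::approx(lb, b$value, grid)$y
  }
  pooled <- sqrt(mean(c(va, vb)^2))
  if (pooled < .Machine$double.eps) return(0)
  sqrt(mean((va - vb)^2)) / pooled
}
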