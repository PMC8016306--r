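# Quasi-static frictionless contact solver.
#
# Both bodies are discretised with the F-bar Neo-Hookean quadrilaterals from
# src/fe_core.cpp.  Contact is node-to-segment penalty: the fingertip (or slab)
# surface nodes are slaves against the stimulus surface polyline (or an
# analytic rigid sphere).  Loading is displacement-controlled through a rigid
# driver; an outer secant loop on the driver travel hits each target normal
# force within the configured tolerance.  The discrete system is conservative,
# so equilibrium is found by Newton iterations on the gradient of the total
# potential (strain + penalty energy), safeguarded by an energy/residual line
# search and adaptive sub-stepping of the driver.
#
# Internal units: mm - kPa - mN.  Public interfaces use N.

#' Contact problem definition
#'
#' @param fingertip a [build_fingertip_model()] (or [build_slab_model()]) body.
#' @param stimulus a [build_stimulus_model()] body.
#' @param mode "passive" (stimulus driven into the fixed fingertip) or
#'   "active" (fingertip driven into the fixed stimulus).
#' @param load_schedule ordered terminal normal forces (N), strictly
#'   increasing; a leading 0 is permitted and yields the reference state.
#' @param ramp_resolution sub-steps per Newton of force for dynamic-phase
#'   output (0 = record terminal loads only; 8 reproduces the default ramp
#'   discretisation).
#' @param penalty penalty stiffness (kPa/mm); default auto-scales to
#'   100x the softer body's shear modulus per slave-node spacing.
#' @param tol_force relative force tolerance for the driver loop (default 1%).
#' @param newton_tol relative force-residual tolerance of the equilibrium
#'   solve.
#' @param max_iter maximum Newton iterations per driver step.
#' @param du_max maximum driver increment (mm).
#' @param plate_tie attachment of the hemisphere's flat face to the rigid
#'   plate: "bonded" (default; both dofs tied) or "frictionless" (normal dof
#'   tied, radial slip allowed).
#' @return A \code{contact_problem} list.
#' @export
contact_problem <- function(fingertip, stimulus,
                            mode = c("passive", "active"),
                            load_schedule = c(0.25, 0.5, 1, 2),
                            ramp_resolution = 0,
                            penalty = NULL,
                            tol_force = 0.01,
                            newton_tol = 1e-3,
                            max_iter = 40L,
                            du_max = 0.25,
                            plate_tie = c("bonded", "frictionless")) {
  mode <- match.arg(mode)
  plate_tie <- match.arg(plate_tie)
  stopifnot(inherits(fingertip, "fingertip_model"),
            inherits(stimulus, "stimulus_model"))
  if (length(load_schedule) < 1 || any(!is.finite(load_schedule))) {
    stop("load_schedule must be finite")
  }
  if (any(load_schedule < 0) || any(diff(load_schedule) <= 0)) {
    stop("load_schedule must be non-negative and strictly increasing")
  }
  structure(list(fingertip = fingertip, stimulus = stimulus, mode = mode,
                 load_schedule = load_schedule,
                 ramp_resolution = ramp_resolution, penalty = penalty,
                 tol_force = tol_force, newton_tol = newton_tol,
                 max_iter = as.integer(max_iter), du_max = du_max,
                 plate_tie = plate_tie),
            class = "contact_problem")
}

# --- contact geometry ------------------------------------------------------

# Tributary reference "area" of ordered surface nodes (2*pi*r*ds axisym, ds
# plane strain); the measure that converts penalty pressure (kPa) to force (mN)
slave_areas <- function(nodes, surf, axisym) {
  xy <- nodes[surf$node, , drop = FALSE]
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  ds <- (c(0, seg) + c(seg, 0)) / 2
  if (!axisym) return(ds)
  # strip boundaries at arc midpoints; radius averaged across each strip
  s <- cumsum(c(0, seg))
  b <- c(s[1], (s[-length(s)] + s[-1]) / 2, s[length(s)])
  rb <- stats::approx(s, xy[, 1], b)$y
  rbar <- (rb[-length(rb)] + rb[-1]) / 2
  2 * pi * pmax(rbar, 1e-9) * ds
}

# Closest-point projection of slave points onto a polyline.
# Returns per-slave: segment index, parameter t, distance vector d = xs - proj.
project_polyline <- function(P, xs) {
  ns <- nrow(xs)
  nseg <- nrow(P) - 1L
  A <- P[-nrow(P), , drop = FALSE]
  Bv <- P[-1, , drop = FALSE] - A
  len2 <- pmax(rowSums(Bv^2), 1e-30)
  seg <- integer(ns)
  tt <- numeric(ns)
  dvec <- matrix(0, ns, 2)
  for (s in seq_len(ns)) {
    t <- pmin(1, pmax(0, ((xs[s, 1] - A[, 1]) * Bv[, 1] +
                          (xs[s, 2] - A[, 2]) * Bv[, 2]) / len2))
    px <- A[, 1] + t * Bv[, 1]
    py <- A[, 2] + t * Bv[, 2]
    d2 <- (xs[s, 1] - px)^2 + (xs[s, 2] - py)^2
    k <- which.min(d2)
    seg[s] <- k
    tt[s] <- t[k]
    dvec[s, ] <- c(xs[s, 1] - px[k], xs[s, 2] - py[k])
  }
  list(seg = seg, t = tt, d = dvec)
}

# Penalty contact: energy, residual contribution and tangent triplets.
# cd: list(kpen, nf = node count of the body whose net contact force is
#     reported, passes = list of passes).  Each pass:
#     list(slave, area, master = node ids | NULL,
#          rigid = list(center0, radius) | NULL,
#          inside_node = master body node used to orient normals,
#          driver = c(dr, dz) rigid-center translation per unit travel).
# Two-pass (symmetric) node-to-segment keeps either surface from folding
# through the other when their resolutions differ.
contact_eval_pass <- function(nodes0, u, U, pass, kpen) {
  xs <- nodes0[pass$slave, , drop = FALSE] +
    cbind(u[2 * pass$slave - 1], u[2 * pass$slave])
  n_act <- 0L
  energy <- 0
  fsum <- 0
  force_i <- integer(0)
  force_x <- numeric(0)
  ki <- integer(0)
  kj <- integer(0)
  kx <- numeric(0)
  pressure <- numeric(length(pass$slave))
  gap <- numeric(length(pass$slave))

  # exact local tangent: central FD of the local penalty gradient `gfun`
  # over the involved dofs (captures normal rotation and weight variation)
  add_hessian <- function(rows, q, gfun, h = 1e-7) {
    nq <- length(q)
    H <- matrix(0, nq, nq)
    for (c_ in seq_len(nq)) {
      qp <- q; qp[c_] <- q[c_] + h
      qm <- q; qm[c_] <- q[c_] - h
      H[, c_] <- (gfun(qp) - gfun(qm)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    dofs <- as.vector(rbind(2 * rows - 1, 2 * rows))
    ki <<- c(ki, rep(dofs, times = nq))
    kj <<- c(kj, rep(dofs, each = nq))
    kx <<- c(kx, as.vector(H))
  }

  if (!is.null(pass$rigid)) {
    ctr <- pass$rigid$center0 + pass$driver * U
    dvec <- cbind(xs[, 1] - ctr[1], xs[, 2] - ctr[2])
    dist <- sqrt(rowSums(dvec^2))
    g <- dist - pass$rigid$radius
    gap <- g
    act <- which(g < 0 & dist > 1e-12)
    n_act <- length(act)
    R0 <- pass$rigid$radius
    for (s in act) {
      kA <- kpen * pass$area[s]
      nvec <- dvec[s, ] / dist[s]
      fs <- kA * g[s] * nvec
      energy <- energy + 0.5 * kA * g[s]^2
      force_i <- c(force_i, 2 * pass$slave[s] - 1, 2 * pass$slave[s])
      force_x <- c(force_x, fs)
      fsum <- fsum + kA * abs(g[s])
      pressure[s] <- kpen * abs(g[s])
      add_hessian(pass$slave[s], xs[s, ], function(q) {
        dv <- q - ctr
        dd <- sqrt(sum(dv^2))
        kA * (dd - R0) * dv / dd
      })
    }
  } else {
    P <- nodes0[pass$master, , drop = FALSE] +
      cbind(u[2 * pass$master - 1], u[2 * pass$master])
    inside <- nodes0[pass$inside_node, ] +
      c(u[2 * pass$inside_node - 1], u[2 * pass$inside_node])
    pr <- project_polyline(P, xs)
    for (s in seq_along(pass$slave)) {
      k <- pr$seg[s]
      tpar <- pr$t[s]
      d <- pr$d[s, ]
      dist <- sqrt(sum(d^2))
      # outward segment normal (away from the master body interior)
      tg <- P[k + 1, ] - P[k, ]
      nseg <- c(tg[2], -tg[1])
      mid <- (P[k, ] + P[k + 1, ]) / 2
      if (sum(nseg * (mid - inside)) < 0) nseg <- -nseg
      nseg <- nseg / sqrt(sum(nseg^2))
      g <- if (dist > 1e-12) dist * sign(sum(d * nseg)) else 0
      gap[s] <- g
      if (g >= 0) next
      n_act <- n_act + 1L
      kA <- kpen * pass$area[s]
      m1 <- pass$master[k]
      m2 <- pass$master[k + 1]
      w1 <- 1 - tpar
      w2 <- tpar
      # residual = gradient of 0.5*kA*g^2: +kA*d on slave, -w*kA*d on master
      energy <- energy + 0.5 * kA * g^2
      force_i <- c(force_i, 2 * pass$slave[s] - 1, 2 * pass$slave[s],
                   2 * m1 - 1, 2 * m1, 2 * m2 - 1, 2 * m2)
      force_x <- c(force_x, kA * d, -w1 * kA * d, -w2 * kA * d)
      fsum <- fsum + kA * abs(g)
      pressure[s] <- kpen * abs(g)
      add_hessian(c(pass$slave[s], m1, m2),
                  c(xs[s, ], P[k, ], P[k + 1, ]), function(q) {
        e <- q[5:6] - q[3:4]
        tq <- max(0, min(1, sum((q[1:2] - q[3:4]) * e) / sum(e^2)))
        dq <- q[1:2] - (q[3:4] + tq * e)
        kA * c(dq, -(1 - tq) * dq, -tq * dq)
      })
    }
  }
  list(energy = energy, force_i = force_i, force_x = force_x,
       ki = ki, kj = kj, kx = kx, fsum = fsum,
       n_active = n_act, pressure = pressure, gap = gap)
}

contact_eval <- function(nodes0, u, U, cd) {
  parts <- lapply(cd$passes, function(p) contact_eval_pass(nodes0, u, U, p, cd$kpen))
  force_i <- unlist(lapply(parts, `[[`, "force_i"))
  force_x <- unlist(lapply(parts, `[[`, "force_x"))
  # net normal (z) contact force transmitted to the reported body
  on_body <- force_i %% 2 == 0 & force_i <= 2 * cd$nf
  # contact pressure at the primary slave nodes: magnitude of the total
  # contact force gathered on each node (all passes) per tributary area
  sl <- cd$passes[[1]]$slave
  fvec <- numeric(2 * nrow(nodes0))
  if (length(force_i)) {
    agg <- rowsum(force_x, force_i)
    fvec[as.integer(rownames(agg))] <- agg[, 1]
  }
  pressure <- sqrt(fvec[2 * sl - 1]^2 + fvec[2 * sl]^2) / cd$passes[[1]]$area
  list(energy = sum(vapply(parts, `[[`, 0, "energy")),
       force_i = force_i, force_x = force_x,
       ki = unlist(lapply(parts, `[[`, "ki")),
       kj = unlist(lapply(parts, `[[`, "kj")),
       kx = unlist(lapply(parts, `[[`, "kx")),
       fz = abs(sum(force_x[on_body])),
       fsum = sum(vapply(parts, `[[`, 0, "fsum")),
       n_active = sum(vapply(parts, `[[`, 0L, "n_active")),
       pressure = pressure, gap = parts[[1]]$gap)
}

# --- equilibrium -----------------------------------------------------------

full_eval <- function(sys, u, U, cd) {
  asm <- fe_assemble(sys$nodes, sys$elems, u, sys$c10, sys$d1, sys$axisym, TRUE)
  if (!isTRUE(asm$ok)) return(NULL)
  ct <- contact_eval(sys$nodes, u, U, cd)
  r <- asm$force
  if (length(ct$force_i)) {
    agg <- rowsum(ct$force_x, ct$force_i)
    r[as.integer(rownames(agg))] <- r[as.integer(rownames(agg))] + agg[, 1]
  }
  list(E = asm$energy + ct$energy, Eint = asm$energy, r = r, ct = ct)
}

newton_solve <- function(sys, u, U, cd, ctl) {
  ndof <- length(u)
  u[ctl$pres_dofs] <- ctl$pres_base + ctl$pres_dir * U
  free <- ctl$free
  cur <- full_eval(sys, u, U, cd)
  if (is.null(cur)) return(list(converged = FALSE, u = u))
  for (it in seq_len(ctl$max_iter)) {
    rf <- cur$r[free]
    fscale <- max(cur$ct$fsum, 1)
    rmax <- max(abs(rf))
    if (rmax < ctl$newton_tol * fscale) {
      return(list(converged = TRUE, u = u, eval = cur, resid = rmax,
                  iters = it - 1L))
    }
    Kt <- fe_stiffness_triplets(sys$nodes, sys$elems, u, sys$c10, sys$d1,
                                sys$axisym, 1e-6)
    if (!isTRUE(Kt$ok)) return(list(converged = FALSE, u = u, resid = rmax))
    K <- Matrix::sparseMatrix(i = c(Kt$i, cur$ct$ki), j = c(Kt$j, cur$ct$kj),
                              x = c(Kt$x, cur$ct$kx), dims = c(ndof, ndof))
    du <- tryCatch(as.numeric(Matrix::solve(K[free, free, drop = FALSE], -rf)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      return(list(converged = FALSE, u = u, resid = rmax))
    }
    step <- 1
    accepted <- FALSE
    while (step >= 1 / 64) {
      utry <- u
      utry[free] <- u[free] + step * du
      trial <- full_eval(sys, utry, U, cd)
      if (!is.null(trial)) {
        if (trial$E <= cur$E + 1e-6 * (abs(cur$E) + 1e-6) ||
            max(abs(trial$r[free])) < rmax) {
          if (max(abs(step * du)) < 1e-6) {
            return(list(converged = TRUE, u = utry, eval = trial,
                        resid = max(abs(trial$r[free])), iters = it))
          }
          u <- utry
          cur <- trial
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) return(list(converged = FALSE, u = u, resid = rmax))
  }
  list(converged = FALSE, u = u, resid = max(abs(cur$r[free])))
}

# --- driver loop -----------------------------------------------------------

build_contact_system <- function(problem) {
  ft <- problem$fingertip
  st <- problem$stimulus
  if (!identical(ft$formulation, "axisymmetric")) {
    stop("contact_problem requires the axisymmetric formulation")
  }
  nf <- nrow(ft$nodes)
  nodes <- rbind(ft$nodes, st$nodes)
  elems <- rbind(ft$elems, st$elems + nf)
  sys <- list(nodes = nodes, elems = elems,
              c10 = c(ft$c10, st$c10), d1 = c(ft$d1, st$d1),
              axisym = TRUE, n_fingertip = nf,
              m_fingertip = nrow(ft$elems))

  slave <- ft$surface_nodes$node
  G_soft <- min(min(ft$c10) * 2, st$tip$shear_modulus)
  spacing <- mean(sqrt(diff(ft$nodes[slave, 1])^2 + diff(ft$nodes[slave, 2])^2))
  kpen <- if (is.null(problem$penalty)) 100 * G_soft / spacing else problem$penalty
  # symmetric node-to-segment: fingertip surface nodes against the stimulus
  # surface, and stimulus surface nodes against the fingertip surface
  pass1 <- list(slave = slave,
                area = slave_areas(ft$nodes, ft$surface_nodes, TRUE),
                master = st$surface_nodes$node + nf, rigid = NULL,
                driver = c(0, 0), inside_node = st$plate_nodes[1] + nf)
  pass2 <- list(slave = st$surface_nodes$node + nf,
                area = slave_areas(st$nodes, st$surface_nodes, TRUE),
                master = slave, rigid = NULL, driver = c(0, 0),
                inside_node = ft$core_nodes[1])
  cd <- list(kpen = kpen, nf = nf, passes = list(pass1, pass2))

  ndof <- 2L * nrow(nodes)
  # base constraints: symmetry axis (radial dof), fixed body, driven body
  axis_dofs <- 2 * c(ft$axis_nodes, st$axis_nodes + nf) - 1
  plate <- st$plate_nodes + nf
  core <- ft$core_nodes
  pres <- data.frame(dof = axis_dofs, base = 0, dir = 0)
  plate_r <- if (identical(problem$plate_tie, "frictionless")) {
    integer(0) # radial slip allowed on the rigid plate
  } else {
    2 * plate - 1
  }
  if (problem$mode == "passive") {
    pres <- rbind(pres,
                  data.frame(dof = c(2 * core - 1, 2 * core), base = 0, dir = 0),
                  if (length(plate_r)) data.frame(dof = plate_r, base = 0, dir = 0),
                  data.frame(dof = 2 * plate, base = 0, dir = -1))
  } else {
    pres <- rbind(pres,
                  if (length(plate_r)) data.frame(dof = plate_r, base = 0, dir = 0),
                  data.frame(dof = 2 * plate, base = 0, dir = 0),
                  data.frame(dof = 2 * core - 1, base = 0, dir = 0),
                  data.frame(dof = 2 * core, base = 0, dir = 1))
  }
  pres <- pres[!duplicated(pres$dof), ]
  ctl <- list(pres_dofs = pres$dof, pres_base = pres$base, pres_dir = pres$dir,
              free = setdiff(seq_len(ndof), pres$dof),
              max_iter = problem$max_iter, newton_tol = problem$newton_tol)
  list(sys = sys, cd = cd, ctl = ctl, ndof = ndof)
}

make_state <- function(problem, built, u, U, ev, target_N, terminal, work) {
  sys <- built$sys
  fields <- fe_element_fields(sys$nodes, sys$elems, u, sys$c10, sys$d1,
                              sys$axisym)
  structure(list(load = ev$ct$fz / 1000, target = target_N,
                 rigid_body_travel = U, u = u,
                 element_fields = fields,
                 strain_energy = ev$Eint / 1000,      # mJ
                 penalty_energy = (ev$E - ev$Eint) / 1000,
                 external_work = work / 1000,          # mJ
                 contact = data.frame(node = built$cd$passes[[1]]$slave,
                                      r = sys$nodes[built$cd$passes[[1]]$slave, 1],
                                      pressure = ev$ct$pressure,
                                      gap = ev$ct$gap),
                 mode = problem$mode, terminal = terminal),
            class = "solution_state")
}

#' Solve a quasi-static frictionless contact problem under force control
#'
#' Drives the rigid plate (passive mode) or the fingertip core (active mode)
#' until each scheduled normal force is reached within \code{tol_force}
#' (relative).  Returns one converged [SolutionState][solve_contact] per
#' scheduled load (plus ramp sub-steps when \code{ramp_resolution > 0}), each
#' carrying displacements, element stress / strain-energy-density fields,
#' contact pressures, the driver travel and the accumulated external work.
#'
#' @param problem a [contact_problem()].
#' @param quiet suppress progress messages.
#' @return An object of class \code{solution_set}: list of
#'   \code{solution_state} (fields \code{load} (N), \code{rigid_body_travel}
#'   (mm), \code{u}, \code{element_fields}, \code{contact}, energies), with the
#'   problem attached.
#' @export
solve_contact <- function(problem, quiet = TRUE) {
  stopifnot(inherits(problem, "contact_problem"))
  built <- build_contact_system(problem)
  sys <- built$sys

  sched <- problem$load_schedule * 1000 # mN
  targets <- sched
  if (problem$ramp_resolution > 0) {
    sub <- seq(0, max(sched), by = 1000 / problem$ramp_resolution)[-1]
    targets <- sort(unique(c(sched, sub)))
  }
  is_terminal <- targets %in% sched

  u <- numeric(built$ndof)
  U <- 0
  work <- 0
  F_cur <- 0
  ev <- full_eval(sys, u, U, built$cd)
  hist_U <- 0
  hist_F <- 0
  dU_probe <- problem$stimulus$standoff + 0.05
  states <- list()

  solve_to <- function(U_new) {
    # adaptive sub-stepping of the driver increment
    U0 <- U
    dU <- U_new - U0
    n_sub <- 1L
    repeat {
      ok <- TRUE
      u_try <- u
      U_try <- U0
      w_try <- work
      F_try <- F_cur
      ev_try <- ev
      for (k in seq_len(n_sub)) {
        U_next <- U0 + dU * k / n_sub
        res <- newton_solve(sys, u_try, U_next, built$cd, built$ctl)
        if (!res$converged) { ok <- FALSE; break }
        w_try <- w_try + 0.5 * (F_try + res$eval$ct$fz) * (U_next - U_try)
        u_try <- res$u
        U_try <- U_next
        F_try <- res$eval$ct$fz
        ev_try <- res$eval
      }
      if (ok) {
        u <<- u_try; U <<- U_try; work <<- w_try
        F_cur <<- F_try; ev <<- ev_try
        return(TRUE)
      }
      n_sub <- n_sub * 2L
      if (n_sub > 64L) return(FALSE)
    }
  }

  for (ti in seq_along(targets)) {
    Ft <- targets[ti]
    if (Ft <= 0) {
      states[[length(states) + 1]] <-
        make_state(problem, built, u, U, ev, 0, TRUE, work)
      next
    }
    attempts <- 0L
    while (abs(F_cur - Ft) > problem$tol_force * Ft) {
      attempts <- attempts + 1L
      if (attempts > 60L) {
        stop(sprintf(
          "solver error: force target %.3g N not reached (at %.3g N, travel %.3g mm)",
          Ft / 1000, F_cur / 1000, U))
      }
      # propose next driver travel
      if (F_cur < 1e-9 && max(hist_F) < 1e-9) {
        U_next <- U + dU_probe
        dU_probe <- min(2 * dU_probe, problem$du_max)
      } else {
        i2 <- length(hist_F)
        slope <- NA
        for (i1 in rev(seq_len(i2 - 1))) {
          if (abs(hist_F[i2] - hist_F[i1]) > 1e-9) {
            slope <- (hist_U[i2] - hist_U[i1]) / (hist_F[i2] - hist_F[i1])
            break
          }
        }
        if (!is.finite(slope) || slope <= 0) slope <- 0.05 / max(F_cur, 1)
        U_next <- U + max(-problem$du_max,
                          min(problem$du_max, slope * (Ft - F_cur)))
      }
      if (!solve_to(U_next)) {
        stop(sprintf(
          "solver error: non-convergence near travel %.4g mm (last force %.3g N)",
          U, F_cur / 1000))
      }
      hist_U <- c(hist_U, U)
      hist_F <- c(hist_F, F_cur)
      if (!quiet) {
        message(sprintf("  target %.3g N: travel %.4g mm -> %.4g N",
                        Ft / 1000, U, F_cur / 1000))
      }
    }
    states[[length(states) + 1]] <-
      make_state(problem, built, u, U, ev, Ft / 1000, is_terminal[ti], work)
  }
  structure(list(states = states, problem = problem,
                 penalty = built$cd$kpen),
            class = "solution_set")
}

#' @exportS3Method base::print
print.solution_set <- function(x, ...) {
  loads <- vapply(x$states, function(s) s$load, 0)
  cat(sprintf("solution_set: %d states, loads %s N (%s mode)\n",
              length(loads), paste(signif(loads, 3), collapse = ", "),
              x$problem$mode))
  invisible(x)
}

#' Indent a body with a displacement-controlled rigid sphere
#'
#' Analytic rigid spherical (axisymmetric) or cylindrical (plane strain)
#' indenter pressed into the body surface to prescribed depths.  Used for
#' material calibration forward runs and solver verification.
#'
#' @param model a \code{fingertip_model} or \code{slab_model}.
#' @param radius indenter radius (mm).
#' @param depths indentation depths below the undeformed surface apex (mm),
#'   increasing.
#' @param penalty penalty stiffness (kPa/mm), default auto-scaled.
#' @param max_iter,newton_tol Newton controls.
#' @return List of states: \code{depth} (mm), \code{load} (N), \code{u},
#'   surface deflection handled via [surface_deflection_profile()].
#' @export
indent_rigid_sphere <- function(model, radius, depths, penalty = NULL,
                                max_iter = 40L, newton_tol = 1e-3) {
  stopifnot(inherits(model, "fingertip_model"), all(depths > 0),
            !is.unsorted(depths))
  z_top <- max(model$nodes[model$surface_nodes$node, 2])
  sys <- list(nodes = model$nodes, elems = model$elems, c10 = model$c10,
              d1 = model$d1, axisym = model$axisym)
  slave <- model$surface_nodes$node
  area <- slave_areas(model$nodes, model$surface_nodes, model$axisym)
  spacing <- mean(sqrt(diff(model$nodes[slave, 1])^2 +
                       diff(model$nodes[slave, 2])^2))
  G_soft <- 2 * min(model$c10)
  kpen <- if (is.null(penalty)) 100 * G_soft / spacing else penalty
  cd <- list(kpen = kpen, nf = nrow(model$nodes),
             passes = list(list(
               slave = slave, area = area, master = NULL,
               rigid = list(center0 = c(0, z_top + radius), radius = radius),
               driver = c(0, -1), inside_node = NULL)))
  ndof <- 2L * nrow(model$nodes)
  core <- model$core_nodes
  pres <- data.frame(dof = c(2 * model$axis_nodes - 1, 2 * core - 1, 2 * core),
                     base = 0, dir = 0)
  pres <- pres[!duplicated(pres$dof), ]
  ctl <- list(pres_dofs = pres$dof, pres_base = pres$base, pres_dir = pres$dir,
              free = setdiff(seq_len(ndof), pres$dof),
              max_iter = max_iter, newton_tol = newton_tol)
  u <- numeric(ndof)
  U <- 0
  out <- vector("list", length(depths))
  for (k in seq_along(depths)) {
    U_target <- depths[k]
    n_sub <- max(1L, ceiling((U_target - U) / 0.2))
    repeat {
      ok <- TRUE
      u_try <- u
      U_try <- U
      for (s in seq_len(n_sub)) {
        U_next <- U + (U_target - U) * s / n_sub
        res <- newton_solve(sys, u_try, U_next, cd, ctl)
        if (!res$converged) { ok <- FALSE; break }
        u_try <- res$u
        U_try <- U_next
      }
      if (ok) break
      n_sub <- n_sub * 2L
      if (n_sub > 128L) stop("solver error: rigid indentation did not converge")
    }
    u <- u_try
    U <- U_try
    ev <- full_eval(sys, u, U, cd)
    fields <- fe_element_fields(sys$nodes, sys$elems, u, sys$c10, sys$d1,
                                sys$axisym)
    out[[k]] <- structure(list(load = ev$ct$fz / 1000, target = NA_real_,
                               rigid_body_travel = U, u = u,
                               element_fields = fields,
                               strain_energy = ev$Eint / 1000,
                               penalty_energy = (ev$E - ev$Eint) / 1000,
                               external_work = NA_real_,
                               contact = data.frame(node = slave,
                                                    r = model$nodes[slave, 1],
                                                    pressure = ev$ct$pressure,
                                                    gap = ev$ct$gap),
                               mode = "rigid-indenter", terminal = TRUE),
                          class = "solution_state")
  }
  out
}
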