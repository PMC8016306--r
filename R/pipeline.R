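# End-to-end orchestration of the study's three experiments on synthetic (or
# user-supplied) data: contact simulation of the stimulus grid with cue
# distances and illusion flags, ink-image contact-area analytics, and
# psychophysical scoring -- each emitting plain data frames ready for CSV/JSON.

#' Study configuration
#'
#' @param radii stimulus radii grid (mm).
#' @param moduli stimulus elasticity grid (kPa).
#' @param illusion_set ids of the illusion case spheres.
#' @param distinct_id id of the distinct comparison sphere.
#' @param loads force schedule (N).
#' @param n_interface,divisions fingertip mesh resolution (defaults
#'   deliberately coarse; the full-resolution mesh uses 111 interface nodes).
#' @param fine_edge stimulus mesh fine edge (mm).
#' @param plate_tie stimulus plate attachment ("frictionless" or "bonded").
#' @param kappa_ratio bulk/shear ratio of the skin layers.
#' @param fd_stimuli ids solved in active mode for force-displacement curves
#'   (default: illusion pair + distinct).
#' @param ramp_resolution force sub-steps per Newton recorded during the
#'   loading ramp (0 = terminal loads only); with the same-rate protocol
#'   (1 N/s) the sub-step times equal the sub-step loads.
#' @param seed integer seed for downstream stochastic stages.
#' @return A \code{study_config} list.
#' @export
study_config <- function(radii = c(4, 6, 8), moduli = c(10, 50, 90),
                         illusion_set = c("10kPa-4mm", "90kPa-6mm", "90kPa-8mm"),
                         distinct_id = "10kPa-8mm",
                         loads = c(0.25, 0.5, 1, 2),
                         n_interface = 56L, divisions = c(1L, 2L, 3L),
                         fine_edge = 0.35, plate_tie = "frictionless",
                         kappa_ratio = 1e3,
                         fd_stimuli = NULL, ramp_resolution = 0,
                         seed = 1L) {
  if (length(radii) < 1 || length(moduli) < 1) stop("config error: empty stimulus grid")
  grid <- expand.grid(radius = radii, modulus = moduli)
  grid$id <- sprintf("%gkPa-%gmm", grid$modulus, grid$radius)
  if (!all(illusion_set %in% grid$id)) {
    stop("config error: illusion set must be a subset of the stimulus grid")
  }
  if (distinct_id %in% illusion_set) {
    stop("config error: the distinct sphere cannot be an illusion case sphere")
  }
  if (is.null(fd_stimuli)) {
    fd_stimuli <- unique(c(illusion_set[1], illusion_set[length(illusion_set)],
                           distinct_id))
  }
  structure(list(grid = grid, illusion_set = illusion_set,
                 distinct_id = distinct_id, loads = loads,
                 n_interface = as.integer(n_interface),
                 divisions = as.integer(divisions), fine_edge = fine_edge,
                 plate_tie = plate_tie, kappa_ratio = kappa_ratio,
                 fd_stimuli = fd_stimuli, ramp_resolution = ramp_resolution,
                 seed = as.integer(seed)),
            class = "study_config")
}

config_fingertip <- function(config) {
  build_fingertip_model(fingertip_geometry(
    layers = default_layer_stack(divisions = config$divisions,
                                 kappa_ratio = config$kappa_ratio),
    n_interface = config$n_interface))
}

state_profiles <- function(state, model) {
  list(stress = interface_stress_profile(state, model),
       sed = interface_sed_profile(state, model),
       deflection = surface_deflection_profile(state, model))
}

#' Experiment 1: contact simulation of the stimulus grid
#'
#' Solves passive contact for every grid stimulus at every scheduled load,
#' extracts the three cutaneous cue profiles, computes the cue-distance matrix
#' per load and cue, flags the illusion (illusion-pair distances smaller than
#' the illusion-vs-distinct distance at every load), and solves active-mode
#' force-displacement curves for the configured subset.  Solver failures are
#' reported per stimulus without aborting the grid.
#'
#' @param config a [study_config()].
#' @param quiet suppress progress output.
#' @return List: \code{profiles} (long data frame), \code{distances},
#'   \code{illusion} (per-cue flags), \code{fd_curves}, \code{ramp_rates}
#'   (NULL unless \code{ramp_resolution > 0}), \code{failures}.
#' @export
run_experiment1 <- function(config = study_config(), quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  ft <- config_fingertip(config)
  profiles <- list()
  fail <- list()
  sols <- list()
  for (i in seq_len(nrow(config$grid))) {
    id <- config$grid$id[i]
    res <- tryCatch({
      tip <- stimulus_tip(config$grid$radius[i], config$grid$modulus[i],
                          fine_edge = config$fine_edge)
      pb <- contact_problem(ft, build_stimulus_model(tip), mode = "passive",
                            load_schedule = config$loads,
                            ramp_resolution = config$ramp_resolution,
                            plate_tie = config$plate_tie)
      solve_contact(pb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[id]] <- conditionMessage(res)
      if (!quiet) message(id, " FAILED: ", conditionMessage(res))
      next
    }
    sols[[id]] <- res
    for (s in Filter(function(x) x$terminal, res$states)) {
      pr <- state_profiles(s, ft)
      for (cue in names(pr)) {
        profiles[[length(profiles) + 1]] <- data.frame(
          stimulus_id = id, load_N = s$load, cue = cue,
          location_mm = pr[[cue]]$location_mm, value = pr[[cue]]$value,
          stringsAsFactors = FALSE)
      }
    }
    if (!quiet) message(id, " solved")
  }
  profiles <- do.call(rbind, profiles)

  # ramp-phase rates: change of the contact-region mean of each cue per unit
  # time, with sub-step times linearly coupled to the sub-step loads (the
  # same-rate protocol drives 1 N per second)
  ramp_rates <- NULL
  if (config$ramp_resolution > 0) {
    rr <- list()
    for (id in names(sols)) {
      states <- sols[[id]]$states
      loads_all <- vapply(states, function(s) s$load, 0)
      means <- lapply(states, function(s) {
        pr <- state_profiles(s, ft)
        extent <- max(c(0, s$contact$r[s$contact$pressure > 0]))
        vapply(pr, function(p) {
          sel <- p$location_mm <= max(extent, p$location_mm[2])
          mean(p$value[sel])
        }, 0)
      })
      mm <- do.call(rbind, means)
      for (cue in colnames(mm)) {
        rr[[length(rr) + 1]] <- data.frame(
          stimulus_id = id, cue = cue,
          load_N = (loads_all[-1] + loads_all[-length(loads_all)]) / 2,
          rate_per_s = diff(mm[, cue]) / diff(loads_all),
          stringsAsFactors = FALSE)
      }
    }
    ramp_rates <- do.call(rbind, rr)
  }

  # pairwise cue distances per load and cue
  ids <- names(sols)
  dist_rows <- list()
  for (li in seq_along(config$loads)) {
    prs <- lapply(sols, function(so) {
      term <- Filter(function(x) x$terminal, so$states)
      state_profiles(term[[li]], ft)
    })
    for (cue in c("stress", "sed", "deflection")) {
      for (a in seq_along(ids)) {
        for (b in seq_along(ids)) {
          if (a >= b) next
          dist_rows[[length(dist_rows) + 1]] <- data.frame(
            load_N = config$loads[li], cue = cue,
            a = ids[a], b = ids[b],
            distance = cue_distance(prs[[a]][[cue]], prs[[b]][[cue]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  distances <- do.call(rbind, dist_rows)

  getd <- function(x, y, cue, load) {
    r <- distances[distances$cue == cue & distances$load_N == load &
                   ((distances$a == x & distances$b == y) |
                    (distances$a == y & distances$b == x)), "distance"]
    if (length(r)) r[1] else NA_real_
  }
  # the illusion pair: small-compliant (first) vs large-stiff (last) sphere
  anchor <- config$illusion_set[1]
  partner <- config$illusion_set[length(config$illusion_set)]
  illusion <- do.call(rbind, lapply(c("stress", "sed", "deflection"),
    function(cue) {
      per_load <- vapply(config$loads, function(L) {
        dd <- getd(anchor, config$distinct_id, cue, L)
        dp <- getd(anchor, partner, cue, L)
        all(is.finite(c(dd, dp))) && dp < dd
      }, TRUE)
      data.frame(cue = cue, illusion = all(per_load),
                 stringsAsFactors = FALSE)
    }))

  fd_rows <- list()
  for (id in config$fd_stimuli) {
    i <- match(id, config$grid$id)
    res <- tryCatch({
      tip <- stimulus_tip(config$grid$radius[i], config$grid$modulus[i],
                          fine_edge = config$fine_edge)
      pb <- contact_problem(ft, build_stimulus_model(tip), mode = "active",
                            load_schedule = config$loads,
                            plate_tie = config$plate_tie)
      fd <- force_displacement_curve(solve_contact(pb))
      fd$stimulus_id <- id
      fd
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[paste0(id, "-active")]] <- conditionMessage(res)
    } else {
      fd_rows[[id]] <- res
    }
    if (!quiet) message(id, " active done")
  }
  list(profiles = profiles, distances = distances, illusion = illusion,
       fd_curves = do.call(rbind, fd_rows), ramp_rates = ramp_rates,
       failures = fail, fingertip = ft)
}

#' Experiment 2: ink-image contact-area analytics
#'
#' Measures the contact area of every PNG image in the study directory (with
#' JSON sidecars for the bar and ROI), joins the per-trial metadata, builds
#' per-stimulus force-area curves, and tests illusion-set against distinct-set
#' areas (Mann-Whitney, absolute Cohen's d, bootstrap CIs of the group means).
#' Unreadable images are reported and skipped.
#'
#' @param data_dir study directory with \code{images/} and \code{trials.csv}
#'   (columns \code{image}, \code{stimulus_id}, \code{force_N}, \code{group}
#'   where group is "illusion" or "distinct").
#' @param alpha significance level.
#' @param seed seed for the bootstrap.
#' @return List: \code{areas}, \code{force_area}, \code{tests},
#'   \code{failures}.
#' @export
run_experiment2 <- function(data_dir, alpha = 0.05, seed = 1L) {
  trials_file <- file.path(data_dir, "trials.csv")
  if (!dir.exists(data_dir) || !file.exists(trials_file)) {
    stop("data error: study directory must contain trials.csv")
  }
  trials <- utils::read.csv(trials_file, stringsAsFactors = FALSE)
  fail <- list()
  trials$area_cm2 <- NA_real_
  for (i in seq_len(nrow(trials))) {
    path <- file.path(data_dir, trials$image[i])
    res <- tryCatch({
      img <- read_ink_image(path)
      measure_contact_area(img)$area_cm2
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[trials$image[i]]] <- conditionMessage(res)
    } else {
      trials$area_cm2[i] <- res
    }
  }
  ok <- trials[is.finite(trials$area_cm2), ]
  if (nrow(ok) == 0) stop("data error: no readable images in ", data_dir)
  fa <- stats::aggregate(area_cm2 ~ stimulus_id + force_N, data = ok, FUN = mean)
  ill <- ok$area_cm2[ok$group == "illusion"]
  dis <- ok$area_cm2[ok$group == "distinct"]
  tests <- NULL
  if (length(ill) >= 2 && length(dis) >= 2) {
    mw <- mann_whitney_u(ill, dis, alpha = alpha)
    tests <- data.frame(
      comparison = "illusion-vs-distinct",
      U = mw$U, p_value = mw$p_value, significant = mw$significant,
      cohens_d = cohens_d(ill, dis),
      illusion_mean = mean(ill), distinct_mean = mean(dis),
      illusion_lo = bootstrap_ci(ill, mean, seed = seed)[["lower"]],
      illusion_hi = bootstrap_ci(ill, mean, seed = seed)[["upper"]],
      distinct_lo = bootstrap_ci(dis, mean, seed = seed + 1L)[["lower"]],
      distinct_hi = bootstrap_ci(dis, mean, seed = seed + 1L)[["upper"]],
      stringsAsFactors = FALSE)
  }
  list(areas = trials, force_area = fa, tests = tests, failures = fail)
}

#' Experiment 3: psychophysical scoring
#'
#' Per-condition percent correct with 75% threshold flags, per-pair breakdown,
#' pooled and per-pair-mean d' under the differencing rule, and pairwise
#' condition comparisons on participant-level percent correct (Mann-Whitney,
#' absolute Cohen's d).  Malformed rows are counted and skipped.
#'
#' @param trials trial table (data frame or CSV path) with columns
#'   participant, condition, first, second, response, correct.
#' @param alpha significance level.
#' @return List: \code{report} ([condition_report()]), \code{participants},
#'   \code{comparisons}, \code{n_skipped}.
#' @export
run_experiment3 <- function(trials, alpha = 0.05) {
  if (is.character(trials)) trials <- utils::read.csv(trials, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "first", "second", "response", "correct")
  if (!all(need %in% names(trials))) {
    stop("data error: trial table must have columns ",
         paste(need, collapse = ", "))
  }
  bad <- !stats::complete.cases(trials[, need]) |
    !(trials$response %in% c("same", "different"))
  n_skipped <- sum(bad)
  if (n_skipped > 0) warning(n_skipped, " malformed trial rows skipped")
  trials <- trials[!bad, ]
  if (is.character(trials$correct)) trials$correct <- trials$correct == "TRUE"
  trials$correct <- as.logical(trials$correct)
  rep_ <- condition_report(trials)
  part <- stats::aggregate(correct ~ participant + condition, data = trials,
                           FUN = mean)
  part$percent_correct <- 100 * part$correct
  conds <- unique(part$condition)
  comp <- list()
  for (a in seq_along(conds)) {
    for (b in seq_along(conds)) {
      if (a >= b) next
      pa <- part$percent_correct[part$condition == conds[a]]
      pb <- part$percent_correct[part$condition == conds[b]]
      if (length(pa) < 2 || length(pb) < 2) next
      mw <- mann_whitney_u(pa, pb, alpha = alpha)
      comp[[length(comp) + 1]] <- data.frame(
        a = conds[a], b = conds[b], U = mw$U, p_value = mw$p_value,
        significant = mw$significant,
        cohens_d = if (stats::sd(c(pa, pb)) > 0) cohens_d(pa, pb) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(report = rep_, participants = part,
       comparisons = do.call(rbind, comp), n_skipped = n_skipped)
}

#' Write a complete synthetic study directory
#'
#' Emits everything [run_experiment2()] and [run_experiment3()] consume:
#' ink images (PNG + JSON sidecars) whose ground-truth areas follow a
#' power-law force-area relation (illusion spheres share one relation, the
#' distinct sphere a larger one), per-trial force/displacement traces, the
#' psychophysical trial table from the differencing observer, and a
#' \code{truth.json} ledger of every generating value.
#'
#' @param dir output directory (created).
#' @param forces indentation force levels (N).
#' @param reps ink measurements per stimulus and force.
#' @param scale image scale (cm/px).
#' @param area_noise_sd relative SD of per-trial true areas.
#' @param session a [session_spec()] for the trial table.
#' @param seed integer seed.
#' @return Invisibly, the truth list.
#' @export
write_synthetic_study <- function(dir, forces = c(1, 2, 3), reps = 3L,
                                  scale = 0.005, area_noise_sd = 0.05,
                                  session = session_spec(), seed = 1L) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  set.seed(seed)
  stim <- data.frame(
    id = c("10kPa-4mm", "90kPa-6mm", "90kPa-8mm", "10kPa-8mm"),
    group = c("illusion", "illusion", "illusion", "distinct"),
    coef = c(0.72, 0.72, 0.72, 1.33), # area (cm^2) at 1 N
    stringsAsFactors = FALSE)
  rows <- list()
  truth_area <- list()
  for (i in seq_len(nrow(stim))) {
    for (f in forces) {
      for (r in seq_len(reps)) {
        a_true <- stim$coef[i] * f^0.35 *
          exp(stats::rnorm(1, 0, area_noise_sd))
        gi <- gen_ink_image(a_true, scale = scale,
                            seed = sample.int(1e6, 1))
        fname <- sprintf("%s_F%g_r%d.png", stim$id[i], f, r)
        png::writePNG(gi$image$raster, file.path(dir, "images", fname))
        jsonlite::write_json(list(bar_pixels = gi$truth$bar_pixels,
                                  bar_length_cm = 5.0,
                                  roi = gi$truth$roi),
                             file.path(dir, "images", paste0(fname, ".json")),
                             auto_unbox = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          image = file.path("images", fname), stimulus_id = stim$id[i],
          force_N = f, group = stim$group[i], stringsAsFactors = FALSE)
        truth_area[[fname]] <- a_true
      }
    }
  }
  trials_meta <- do.call(rbind, rows)
  utils::write.csv(trials_meta, file.path(dir, "trials.csv"), row.names = FALSE)

  # force / displacement traces per force-rate condition
  k_lin <- c("10kPa-4mm" = 0.45, "90kPa-6mm" = 0.75, "90kPa-8mm" = 0.9,
             "10kPa-8mm" = 0.55) # N/mm linear surrogates
  for (rate in c(0.5, 1, 2)) {
    sp <- protocol_spec("constant-rate", peak = 2, rate = rate,
                        sample_rate = 300, noise_sd = 0.01)
    ftr <- gen_force_trace(sp, seed = sample.int(1e6, 1))
    utils::write.csv(ftr, file.path(dir, "traces",
                                    sprintf("force_rate%g.csv", rate)),
                     row.names = FALSE)
    dtr <- gen_displacement_trace(ftr, k_lin[["10kPa-4mm"]], noise_sd = 0.002,
                                  seed = sample.int(1e6, 1))
    utils::write.csv(dtr, file.path(dir, "traces",
                                    sprintf("laser_rate%g.csv", rate)),
                     row.names = FALSE)
  }

  session$seed <- seed
  trials <- gen_session(session)
  utils::write.csv(trials, file.path(dir, "psycho_trials.csv"),
                   row.names = FALSE)
  truth <- list(seed = seed, scale_cm_px = scale,
                area_model = stim, areas = truth_area,
                linear_stiffness_N_per_mm = as.list(k_lin),
                session_conditions = session$conditions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(truth)
}
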