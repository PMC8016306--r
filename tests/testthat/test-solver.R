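# Small-problem solver behaviour; the Hertz closed-form benchmark and the
# illusion reproduction run in test-acceptance.R at the resolutions those
# checks need.

small_problem <- function(mode = "passive", loads = c(0.1, 0.3), G_tip = 50,
                          moduli = c(45, 22, 9)) {
  ft <- build_fingertip_model(fingertip_geometry(
    layers = default_layer_stack(moduli = moduli, divisions = c(1L, 1L, 2L),
                                 kappa_ratio = 1e3),
    n_interface = 31L))
  sph <- build_stimulus_model(stimulus_tip(4, G_tip, fine_edge = 0.8))
  contact_problem(ft, sph, mode = mode, load_schedule = loads,
                  plate_tie = "frictionless")
}

test_that("zero target load leaves the reference state untouched", {
  pb <- small_problem(loads = 0)
  sol <- solve_contact(pb)
  s <- sol$states[[1]]
  expect_equal(s$load, 0)
  expect_equal(max(abs(s$u)), 0)
  expect_lt(max(abs(s$element_fields[, "von_mises"])), 1e-10)
  expect_equal(s$element_fields[, "J"], rep(1, nrow(s$element_fields)))
})

test_that("force control hits each scheduled load within 1%", {
  sol <- solve_contact(small_problem())
  loads <- vapply(sol$states, function(s) s$load, 0)
  expect_equal(loads, c(0.1, 0.3), tolerance = 0.01)
  travels <- vapply(sol$states, function(s) s$rigid_body_travel, 0)
  expect_true(all(diff(travels) > 0))
  # strain energy density is non-negative everywhere
  for (s in sol$states) expect_true(all(s$element_fields[, "sed"] >= -1e-10))
})

test_that("passive and active modes give the same contact state at equal force", {
  sp <- solve_contact(small_problem("passive", loads = 0.3))
  sa <- solve_contact(small_problem("active", loads = 0.3))
  ft <- sp$problem$fingertip
  pp <- interface_stress_profile(sp$states[[1]], ft)
  pa <- interface_stress_profile(sa$states[[1]], ft)
  expect_lt(cue_distance(pp, pa), 0.02)
  dp <- surface_deflection_profile(sp$states[[1]], ft)
  da <- surface_deflection_profile(sa$states[[1]], ft)
  expect_lt(cue_distance(dp, da), 0.02)
  expect_equal(sa$states[[1]]$rigid_body_travel,
               sp$states[[1]]$rigid_body_travel, tolerance = 0.02)
})

test_that("external work balances stored energy on the frictionless path", {
  pb <- small_problem(loads = 0.3)
  pb$du_max <- 0.04 # fine path for the work integral
  sol <- solve_contact(pb)
  s <- sol$states[[length(sol$states)]]
  stored <- s$strain_energy + s$penalty_energy
  expect_gte(s$external_work + 1e-9, s$strain_energy)
  expect_lt(abs(s$external_work - stored) / stored, 0.01)
  # penalty energy is a small fraction of the total
  expect_lt(s$penalty_energy / stored, 0.05)
})

test_that("scaling all moduli and loads together leaves displacements unchanged", {
  s1 <- solve_contact(small_problem(loads = 0.2))
  s3 <- solve_contact(small_problem(loads = 0.6, G_tip = 150,
                                    moduli = 3 * c(45, 22, 9)))
  expect_equal(s3$states[[1]]$rigid_body_travel,
               s1$states[[1]]$rigid_body_travel, tolerance = 0.02)
  u1 <- s1$states[[1]]$u
  u3 <- s3$states[[1]]$u
  expect_lt(sqrt(mean((u3 - u1)^2)) / sqrt(mean(u1^2)), 0.02)
})

test_that("rigid-sphere indentation is monotone and shapes the surface", {
  m <- tiny_slab()
  st <- indent_rigid_sphere(m, radius = 2, depths = c(0.1, 0.25))
  expect_gt(st[[1]]$load, 0)
  expect_gt(st[[2]]$load, st[[1]]$load)
  d <- surface_deflection_profile(st[[2]], m)
  expect_gte(d$value[1], d$value[nrow(d)]) # centre deflects most
  # centre deflection tracks the indenter depth (penalty penetration and the
  # coarse fixture mesh account for a few percent)
  expect_equal(max(d$value), 0.25, tolerance = 0.05)
})

test_that("problem validation rejects bad schedules and formulations", {
  ft <- coarse_fingertip()
  sph <- build_stimulus_model(stimulus_tip(4, 50, fine_edge = 0.8))
  expect_error(contact_problem(ft, sph, load_schedule = c(1, 0.5)),
               "strictly increasing")
  expect_error(contact_problem(ft, sph, load_schedule = -1), "strictly increasing")
  ps <- build_fingertip_model(fingertip_geometry(
    formulation = "plane-strain",
    layers = default_layer_stack(divisions = c(1, 1, 1)), n_interface = 15L))
  expect_error(solve_contact(contact_problem(ps, sph, load_schedule = 1)),
               "axisymmetric")
})

test_that("force-displacement curves demand active-mode states", {
  sa <- solve_contact(small_problem("active", loads = c(0.1, 0.3)))
  fd <- force_displacement_curve(sa)
  expect_equal(fd$displacement_mm[1], 0)
  expect_equal(fd$force_N[1], 0)
  expect_true(all(diff(fd$displacement_mm) > 0))
  sp <- solve_contact(small_problem("passive", loads = 0.1))
  expect_error(force_displacement_curve(sp), "active-mode")
  mixed <- c(sa$states, sp$states)
  expect_error(force_displacement_curve(mixed), "mixed-mode")
})
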