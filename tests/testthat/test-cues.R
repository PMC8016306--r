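test_that("interface profiles average the neighbouring elements", {
  m <- tiny_slab() # structured grid; surface row doubles as the interface
  st <- fake_state(m)
  # uniform stress field -> constant profile
  st$element_fields[, "von_mises"] <- 4
  pr <- interface_stress_profile(st, m)
  expect_true(all(pr$value == 4))
  expect_identical(nrow(pr), nrow(m$interface_nodes))
  # two neighbouring elements with stress 1 and 3: shared node averages to 2
  st2 <- fake_state(m)
  n2 <- m$interface_nodes$node[2] # interior surface node, two adjacent elements
  adj <- m$node2elem[[n2]]
  expect_identical(length(adj), 2L)
  st2$element_fields[adj[1], "von_mises"] <- 1
  st2$element_fields[adj[2], "von_mises"] <- 3
  pr2 <- interface_stress_profile(st2, m)
  expect_equal(pr2$value[2], 2)
  # SED profile obeys the same rule
  st2$element_fields[adj, "sed"] <- c(1, 3)
  expect_equal(interface_sed_profile(st2, m)$value[2], 2)
})

test_that("unloaded states give all-zero profiles", {
  m <- tiny_slab()
  st <- fake_state(m)
  expect_true(all(interface_stress_profile(st, m)$value == 0))
  expect_true(all(interface_sed_profile(st, m)$value == 0))
  expect_true(all(surface_deflection_profile(st, m)$value == 0))
})

test_that("default-resolution profiles carry 111 samples over 0-15.2 mm", {
  m <- build_fingertip_model(fingertip_geometry())
  st <- fake_state(m)
  pr <- interface_stress_profile(st, m)
  expect_identical(nrow(pr), 111L)
  expect_equal(range(pr$location_mm), c(0, 15.2))
})

test_that("cue distance: identity, symmetry, normalisation, resampling", {
  a <- tactillusion:::new_cue_profile(0:10, sin(0:10), "stress")
  b <- tactillusion:::new_cue_profile(0:10, cos(0:10), "stress")
  expect_equal(cue_distance(a, a), 0)
  expect_equal(cue_distance(a, b), cue_distance(b, a))
  expect_gt(cue_distance(a, b), 0)
  # scale-normalised: scaling both profiles together changes nothing
  a2 <- a; a2$value <- 10 * a$value
  b2 <- b; b2$value <- 10 * b$value
  expect_equal(cue_distance(a2, b2), cue_distance(a, b))
  # different sampling grids are linearly resampled over the overlap
  c1 <- tactillusion:::new_cue_profile(seq(0, 10, 0.5), seq(0, 10, 0.5), "x")
  c2 <- tactillusion:::new_cue_profile(seq(2, 12, 1), seq(2, 12, 1), "x")
  expect_lt(cue_distance(c1, c2), 1e-12)
  d1 <- tactillusion:::new_cue_profile(0:3, 1:4, "x")
  d2 <- tactillusion:::new_cue_profile(7:9, 1:3, "x")
  expect_error(cue_distance(d1, d2), "disjoint")
})

test_that("profiles flag mesh-integrity problems", {
  m <- tiny_slab()
  st <- fake_state(m)
  m$node2elem[[m$interface_nodes$node[1]]] <- integer(0)
  expect_error(interface_stress_profile(st, m), "mesh-integrity")
})
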