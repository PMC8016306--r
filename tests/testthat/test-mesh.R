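test_that("default fingertip mesh: 111 interface nodes spanning 0-15.2 mm", {
  m <- build_fingertip_model(fingertip_geometry())
  expect_identical(nrow(m$interface_nodes), 111L)
  expect_equal(range(m$interface_nodes$arc), c(0, 15.2))
  expect_true(all(m$nodes[, 1] >= 0)) # axisymmetric: r >= 0
  expect_gte(max(m$surface_nodes$arc), 15.2)
})

test_that("degenerate layer configurations are rejected", {
  expect_error(layer_spec("epidermis", 0, soft_rubber()), "config error")
  expect_error(layer_spec("epidermis", -1, soft_rubber()), "config error")
  expect_error(
    fingertip_geometry(layers = default_layer_stack(), interface_depth = 10),
    "config error")
  expect_error(
    fingertip_geometry(layers = default_layer_stack(), interface_depth = 1),
    "layer boundary")
})

test_that("mesh refinement grows the element count, not the interface span", {
  coarse <- build_fingertip_model(fingertip_geometry(
    layers = default_layer_stack(divisions = c(1, 2, 2)), n_interface = 28L))
  fine <- build_fingertip_model(fingertip_geometry(
    layers = default_layer_stack(divisions = c(2, 4, 4)), n_interface = 55L))
  expect_gt(nrow(fine$elems), 3 * nrow(coarse$elems))
  expect_equal(range(fine$interface_nodes$arc), range(coarse$interface_nodes$arc))
})

test_that("stimulus meshes honour the edge-length contract", {
  for (R in c(4, 8)) {
    sph <- build_stimulus_model(stimulus_tip(R, 10))
    # ordered contact-surface polyline: all edges at most the fine size
    surf <- sph$surface_nodes$node
    edge <- sqrt(diff(sph$nodes[surf, 1])^2 + diff(sph$nodes[surf, 2])^2)
    expect_lte(max(edge), 0.25 + 1e-9)
    # every element edge at most the coarse size
    for (k in 1:4) {
      a <- sph$elems[, k]
      b <- sph$elems[, k %% 4 + 1]
      el <- sqrt(rowSums((sph$nodes[a, ] - sph$nodes[b, ])^2))
      expect_lte(max(el), 1.0 + 1e-9)
    }
    expect_true(all(sph$nodes[, 1] >= -1e-12))
  }
})

test_that("degenerate stimulus configurations are rejected", {
  expect_error(stimulus_tip(0.1, 10, fine_edge = 0.25), "config error")
  expect_error(stimulus_tip(4, 10, plate_poisson = 0.6), "config error")
  expect_error(stimulus_tip(4, 10, fine_edge = 2, coarse_edge = 1), "config error")
  expect_error(stimulus_tip(4, -5), "config error")
})

test_that("meshes assemble to a stress-free reference state", {
  ft <- coarse_fingertip()
  a <- tactillusion:::fe_assemble(ft$nodes, ft$elems, numeric(2 * nrow(ft$nodes)),
                   ft$c10, ft$d1, TRUE, TRUE)
  expect_true(a$ok)
  expect_equal(a$energy, 0)
  expect_lt(max(abs(a$force)), 1e-10)
  sph <- build_stimulus_model(stimulus_tip(4, 50, fine_edge = 0.5))
  a2 <- tactillusion:::fe_assemble(sph$nodes, sph$elems, numeric(2 * nrow(sph$nodes)),
                    sph$c10, sph$d1, TRUE, TRUE)
  expect_true(a2$ok)
  expect_lt(max(abs(a2$force)), 1e-10)
})

test_that("element nodal force is the exact gradient of the element energy", {
  m <- tiny_slab()
  set.seed(2)
  u <- rnorm(2 * nrow(m$nodes), 0, 0.02)
  for (axisym in c(TRUE, FALSE)) {
    a <- tactillusion:::fe_assemble(m$nodes, m$elems, u, m$c10, m$d1, axisym, TRUE)
    h <- 1e-6
    for (k in sample(2 * nrow(m$nodes), 6)) {
      up <- u; up[k] <- u[k] + h
      um <- u; um[k] <- u[k] - h
      g <- (tactillusion:::fe_assemble(m$nodes, m$elems, up, m$c10, m$d1, axisym, FALSE)$energy -
            tactillusion:::fe_assemble(m$nodes, m$elems, um, m$c10, m$d1, axisym, FALSE)$energy) /
        (2 * h)
      expect_equal(a$force[k], g, tolerance = 1e-6)
    }
  }
})
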