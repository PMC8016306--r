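# Structured quadrilateral meshes for the fingertip, the stimulus tip and a
# benchmark slab substrate.  All meshes live in the (r, z) half-plane
# (axisymmetric) or the (x, z) symmetric half (plane strain); units are mm.

# Quad connectivity of an ni x nj structured node grid (node index
# (i, j) -> (j - 1) * ni + i), counter-clockwise when the first grid direction
# increases the first coordinate and the second decreases the second.
structured_quads <- function(ni, nj) {
  i <- rep(seq_len(ni - 1), nj - 1)
  j <- rep(seq_len(nj - 1), each = ni - 1)
  idx <- function(i, j) (j - 1L) * ni + i
  cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j), idx(i, j))
}

# Breaks over [from, to] with spacing h0 at `from`, growing geometrically to at
# most hmax.  The last interval is merged if shorter than half a step.
graded_breaks <- function(from, to, h0, hmax, growth = 1.3) {
  stopifnot(to > from, h0 > 0, hmax >= h0)
  b <- from
  h <- h0
  while (b[length(b)] < to) {
    nxt <- b[length(b)] + h
    b <- c(b, min(nxt, to))
    h <- min(h * growth, hmax)
  }
  if (length(b) > 2 && (b[length(b)] - b[length(b) - 1]) < 0.5 * h0) {
    b <- b[-(length(b) - 1)]
  }
  b
}

#' Skin layer specification
#'
#' @param name layer name (epidermis, dermis, subcutaneous, ...).
#' @param thickness depth extent (mm), positive.
#' @param material a [neo_hookean()] material.
#' @param divisions number of element rows through the layer.
#' @return A \code{layer_spec} list.
#' @export
layer_spec <- function(name, thickness, material, divisions = 2L) {
  if (!is.finite(thickness) || thickness <= 0) {
    stop("config error: layer thickness must be positive (layer '", name, "')")
  }
  stopifnot(inherits(material, "neo_hookean"), divisions >= 1)
  structure(list(name = name, thickness = thickness, material = material,
                 divisions = as.integer(divisions)),
            class = "layer_spec")
}

#' Default fingertip layer stack
#'
#' Three soft layers over a rigid bone-proxy core (the core is represented as
#' the fixed inner boundary of the mesh).  The epidermis is 0.470 mm thick so
#' the epidermal-dermal interface, where the cue profiles are sampled, lies
#' 470 um beneath the skin surface.  Default shear moduli (45 / 22 / 9 kPa for
#' epidermis / dermis / subcutaneous) are anchored to published layered
#' fingertip models (Young's moduli 0.136 / 0.080 / 0.034 MPa at
#' near-incompressibility, G = E/3); see the methods vignette.  The bulk
#' modulus of every layer is \code{kappa_ratio} times its shear modulus
#' (near-incompressible tissue).
#'
#' @param moduli named or unnamed numeric vector of three shear moduli (kPa)
#'   for epidermis, dermis, subcutaneous.
#' @param thicknesses numeric vector of three layer thicknesses (mm).
#' @param divisions integer vector of element rows per layer.
#' @param kappa_ratio bulk-to-shear modulus ratio for all layers.
#' @return A list of three [layer_spec()] objects.
#' @export
default_layer_stack <- function(moduli = c(epidermis = 45, dermis = 22,
                                           subcutaneous = 9),
                                thicknesses = c(0.470, 1.2, 3.0),
                                divisions = c(2L, 3L, 4L),
                                kappa_ratio = 1e5) {
  nm <- c("epidermis", "dermis", "subcutaneous")
  mapply(function(name, G, th, dv) {
    layer_spec(name, th, neo_hookean(G = G, kappa_ratio = kappa_ratio), dv)
  }, nm, unname(moduli), unname(thicknesses), unname(divisions),
  SIMPLIFY = FALSE)
}

#' Fingertip geometry configuration
#'
#' Parameterised layered dome: a quarter-dome of soft tissue over a rigid core,
#' revolved about the finger-pad centreline (axisymmetric) or extruded
#' (plane strain).  The dome outer radius is derived from the requested
#' interface arc-length span so that the epidermal-dermal interface covers
#' \code{interface_span} mm of arc with \code{n_interface} equally spaced
#' nodes.
#'
#' @param formulation "axisymmetric" or "plane-strain".
#' @param layers list of [layer_spec()]; outermost first.
#' @param n_interface number of interface nodes (default 111).
#' @param interface_span interface arc length (mm, default 15.2).
#' @param phi_max angular extent of the dome (radians, default pi/2).
#' @param interface_depth depth of the cue-sampling interface (mm); defaults to
#'   the epidermis thickness and must coincide with a layer boundary.
#' @return A \code{fingertip_geometry} configuration list.
#' @export
fingertip_geometry <- function(formulation = c("axisymmetric", "plane-strain"),
                               layers = default_layer_stack(),
                               n_interface = 111L,
                               interface_span = 15.2,
                               phi_max = pi / 2,
                               interface_depth = NULL) {
  formulation <- match.arg(formulation)
  stopifnot(length(layers) >= 1, n_interface >= 2, interface_span > 0,
            phi_max > 0, phi_max <= pi / 2 + 1e-9)
  for (ly in layers) {
    if (!inherits(ly, "layer_spec")) stop("layers must be layer_spec objects")
  }
  th <- vapply(layers, function(l) l$thickness, 0)
  if (is.null(interface_depth)) interface_depth <- th[1]
  total <- sum(th)
  if (interface_depth >= total) {
    stop("config error: interface depth (", interface_depth,
         " mm) exceeds total soft-tissue depth (", total, " mm)")
  }
  bounds <- cumsum(th)
  if (min(abs(bounds - interface_depth)) > 1e-9) {
    stop("config error: interface depth must coincide with a layer boundary")
  }
  structure(list(formulation = formulation, layers = layers,
                 n_interface = as.integer(n_interface),
                 interface_span = interface_span, phi_max = phi_max,
                 interface_depth = interface_depth),
            class = "fingertip_geometry")
}

node_elem_map <- function(elems, n_nodes) {
  df <- data.frame(node = as.vector(elems),
                   elem = rep(seq_len(nrow(elems)), times = ncol(elems)))
  split(df$elem, factor(df$node, levels = seq_len(n_nodes)))
}

#' Build the layered fingertip finite-element model
#'
#' Generates the structured quadrilateral mesh of the layered dome, labels
#' elements by layer, and extracts the ordered interface and surface node sets
#' with their arc-length coordinates.  With the default configuration the
#' interface carries exactly 111 nodes spanning 0 to 15.2 mm of arc.
#'
#' @param config a [fingertip_geometry()] configuration.
#' @return A \code{fingertip_model}: nodes (n x 2, mm), elems (m x 4),
#'   per-element material constants, \code{interface_nodes} and
#'   \code{surface_nodes} data frames (node id, arc length mm), fixed core and
#'   axis node sets.
#' @examples
#' m <- build_fingertip_model(fingertip_geometry())
#' nrow(m$interface_nodes)  # 111
#' @export
build_fingertip_model <- function(config = fingertip_geometry()) {
  stopifnot(inherits(config, "fingertip_geometry"))
  th <- vapply(config$layers, function(l) l$thickness, 0)
  R_int <- config$interface_span / config$phi_max
  R_out <- R_int + config$interface_depth
  total <- sum(th)
  if (total >= R_out) {
    stop("config error: soft-tissue depth must be smaller than the dome radius")
  }

  # depth breaks: layer boundaries subdivided by per-layer divisions
  depth_breaks <- 0
  for (ly in config$layers) {
    lo <- depth_breaks[length(depth_breaks)]
    depth_breaks <- c(depth_breaks,
                      lo + ly$thickness * seq_len(ly$divisions) / ly$divisions)
  }
  row_layer <- rep(seq_along(config$layers),
                   vapply(config$layers, function(l) l$divisions, 0L))

  ni <- config$n_interface
  phi <- seq(0, config$phi_max, length.out = ni)
  nj <- length(depth_breaks)
  rad <- R_out - depth_breaks
  nodes <- cbind(as.vector(outer(sin(phi), rad)),
                 as.vector(outer(cos(phi), rad)) - R_out)
  elems <- structured_quads(ni, nj)
  elem_layer <- rep(row_layer, each = ni - 1)

  c10 <- vapply(config$layers, function(l) l$material$c10, 0)[elem_layer]
  d1 <- vapply(config$layers, function(l) l$material$d1, 0)[elem_layer]

  j_int <- which(abs(depth_breaks - config$interface_depth) < 1e-9)
  idx <- function(i, j) (j - 1L) * ni + i
  interface_nodes <- data.frame(node = idx(seq_len(ni), j_int),
                                arc = phi * rad[j_int])
  surface_nodes <- data.frame(node = idx(seq_len(ni), 1L), arc = phi * R_out)
  core_nodes <- idx(seq_len(ni), nj)
  axis_nodes <- idx(1L, seq_len(nj))

  structure(list(nodes = nodes, elems = elems, c10 = c10, d1 = d1,
                 elem_layer = elem_layer, layers = config$layers,
                 formulation = config$formulation,
                 axisym = config$formulation == "axisymmetric",
                 interface_nodes = interface_nodes,
                 surface_nodes = surface_nodes,
                 core_nodes = core_nodes, axis_nodes = axis_nodes,
                 node2elem = node_elem_map(elems, nrow(nodes)),
                 outer_radius = R_out, config = config),
            class = c("fingertip_model", "fe_body"))
}

#' Stimulus tip specification
#'
#' Hemispherical compliant tip with the flat central section attached to a
#' rigid driver plate.  Near-incompressible rubber-like behaviour is modelled
#' with a Neo-Hookean material at the given shear modulus and a Poisson ratio
#' of 0.475 for the plate coupling.
#'
#' @param radius hemisphere radius (mm); study grid \{4, 6, 8\}.
#' @param shear_modulus tip shear modulus (kPa); study grid \{10, 50, 90\}.
#' @param plate_poisson Poisson ratio (default 0.475).
#' @param fine_edge max element edge in the contact-candidate region (mm).
#' @param coarse_edge max element edge elsewhere (mm).
#' @return A \code{stimulus_tip} list.
#' @export
stimulus_tip <- function(radius, shear_modulus, plate_poisson = 0.475,
                         fine_edge = 0.25, coarse_edge = 1.0) {
  if (!is.finite(radius) || radius <= 0) stop("config error: radius must be positive")
  if (!is.finite(shear_modulus) || shear_modulus <= 0) {
    stop("config error: shear modulus must be positive")
  }
  if (plate_poisson <= 0 || plate_poisson >= 0.5) {
    stop("config error: plate_poisson must lie in (0, 0.5)")
  }
  if (fine_edge > coarse_edge) stop("config error: fine_edge must be <= coarse_edge")
  if (radius <= fine_edge) {
    stop("config error: tip radius (", radius,
         " mm) must exceed the fine element edge (", fine_edge, " mm)")
  }
  structure(list(radius = radius, shear_modulus = shear_modulus,
                 plate_poisson = plate_poisson, fine_edge = fine_edge,
                 coarse_edge = coarse_edge,
                 id = sprintf("%gkPa-%gmm", shear_modulus, radius)),
            class = "stimulus_tip")
}

#' Build the stimulus tip finite-element model
#'
#' The hemisphere cross-section (a quarter disc in the half-plane) is meshed
#' with a smooth elliptic square-to-quarter-disc mapping, so no degenerate
#' elements appear at the pole.  The grid is sized so that every element edge
#' on the spherical contact surface is at most \code{fine_edge}, and interior
#' edges at most \code{coarse_edge}.  The flat face (through the sphere's
#' central section) is tied to a rigid driver plate.
#'
#' @param tip a [stimulus_tip()].
#' @param standoff initial clearance between the pole and z = 0 (mm).
#' @return A \code{stimulus_model}: mesh, material constants, ordered surface
#'   polyline from the pole to the equator, and the rigid plate node set.
#' @export
build_stimulus_model <- function(tip, standoff = 2e-3) {
  stopifnot(inherits(tip, "stimulus_tip"))
  R <- tip$radius
  n <- max(4L, as.integer(ceiling(R / tip$fine_edge)))
  s <- seq(0, 1, length.out = n + 1) # xi and eta share the grid
  xi <- rep(s, times = n + 1)
  eta <- rep(s, each = n + 1)
  x <- R * xi * sqrt(1 - eta^2 / 2)
  y <- R * eta * sqrt(1 - xi^2 / 2)
  # pole (xi = 0, eta = 1) sits at z = standoff; plate plane at z = standoff + R
  nodes <- cbind(x, standoff + R - y)
  ni <- n + 1L
  idx <- function(i, j) (j - 1L) * ni + i
  # grid direction j = eta index: z decreases with eta, so reuse the helper
  elems <- structured_quads(ni, ni)

  mat <- neo_hookean(G = tip$shear_modulus, nu = tip$plate_poisson)
  m <- nrow(elems)

  # ordered surface polyline pole -> equator: eta = 1 row (xi increasing), then
  # xi = 1 column (eta decreasing), dropping the shared 45-degree corner node
  surf <- c(idx(seq_len(ni), ni), idx(ni, rev(seq_len(ni - 1L))))
  ang <- asin(pmin(1, nodes[surf, 1] / R)) # polar angle from the pole
  surface_nodes <- data.frame(node = surf, arc = R * ang)

  structure(list(nodes = nodes, elems = elems,
                 c10 = rep(mat$c10, m), d1 = rep(mat$d1, m),
                 material = mat, tip = tip,
                 surface_nodes = surface_nodes,
                 plate_nodes = idx(seq_len(ni), 1L),
                 axis_nodes = idx(1L, seq_len(ni)),
                 node2elem = node_elem_map(elems, nrow(nodes)),
                 standoff = standoff),
            class = c("stimulus_model", "fe_body"))
}

#' Build a single-layer slab substrate (benchmark geometry)
#'
#' Rectangular block of one material, meshed finely near the contact axis and
#' the free surface, used for closed-form verification (Hertz contact) and
#' cheap solver tests.  The slab exposes the same node-set interface as the
#' fingertip model (its free surface doubles as the cue-sampling interface),
#' so it can stand in for the fingertip in [contact_problem()].
#'
#' @param width radial extent (mm).
#' @param depth slab thickness (mm).
#' @param material a [neo_hookean()] material.
#' @param fine_edge element size near the axis and surface (mm).
#' @param coarse_edge maximum element size away from the contact (mm).
#' @param fine_radius radial extent of the finely meshed zone (mm).
#' @param fine_depth depth extent of the finely meshed zone (mm).
#' @param formulation "axisymmetric" or "plane-strain".
#' @return A \code{slab_model} (subclass of \code{fingertip_model}).
#' @export
build_slab_model <- function(width, depth, material, fine_edge = 0.1,
                             coarse_edge = 1.0, fine_radius = width / 4,
                             fine_depth = depth / 5,
                             formulation = c("axisymmetric", "plane-strain")) {
  formulation <- match.arg(formulation)
  stopifnot(width > 0, depth > 0, inherits(material, "neo_hookean"))
  rb <- unique(c(seq(0, fine_radius,
                     length.out = ceiling(fine_radius / fine_edge) + 1),
                 graded_breaks(fine_radius, width, fine_edge, coarse_edge)))
  zb <- unique(c(seq(0, fine_depth,
                     length.out = ceiling(fine_depth / fine_edge) + 1),
                 graded_breaks(fine_depth, depth, fine_edge, coarse_edge)))
  ni <- length(rb)
  nj <- length(zb)
  nodes <- cbind(rep(rb, nj), rep(-zb, each = ni))
  elems <- structured_quads(ni, nj)
  m <- nrow(elems)
  idx <- function(i, j) (j - 1L) * ni + i
  surface_nodes <- data.frame(node = idx(seq_len(ni), 1L), arc = rb)
  structure(list(nodes = nodes, elems = elems,
                 c10 = rep(material$c10, m), d1 = rep(material$d1, m),
                 elem_layer = rep(1L, m),
                 layers = list(layer_spec("substrate", depth, material, 1L)),
                 formulation = formulation,
                 axisym = formulation == "axisymmetric",
                 interface_nodes = surface_nodes,
                 surface_nodes = surface_nodes,
                 core_nodes = idx(seq_len(ni), nj),
                 axis_nodes = idx(1L, seq_len(nj)),
                 node2elem = node_elem_map(elems, nrow(nodes)),
                 outer_radius = NA_real_, config = NULL),
            class = c("slab_model", "fingertip_model", "fe_body"))
}
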