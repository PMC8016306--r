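# Shared small fixtures.  Mechanics fixtures are deliberately coarse so the
# suite stays fast; the acceptance tests use the resolutions the checks call
# for.

soft_rubber <- function(G = 10, kappa = 100) neo_hookean(G = G, kappa_ratio = kappa)

tiny_slab <- function(G = 10, kappa = 100) {
  build_slab_model(4, 3, soft_rubber(G, kappa), fine_edge = 0.5, coarse_edge = 1)
}

# memoised coarse fingertip (several tests share it)
coarse_fingertip <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_fingertip_model(fingertip_geometry(
        layers = default_layer_stack(divisions = c(1L, 1L, 2L),
                                     kappa_ratio = 1e3),
        n_interface = 31L))
    }
    cache
  }
})

# a fabricated solved state carrying prescribed element fields, for testing
# the profile-averaging rules in isolation
fake_state <- function(model, fields = NULL, u = NULL, mode = "passive") {
  m <- nrow(model$elems)
  if (is.null(fields)) {
    fields <- matrix(0, m, 7,
                     dimnames = list(NULL, c("s_rr", "s_zz", "s_rz", "s_tt",
                                             "von_mises", "sed", "J")))
    fields[, "J"] <- 1
  }
  if (is.null(u)) u <- numeric(2 * nrow(model$nodes))
  structure(list(load = 0, target = 0, rigid_body_travel = 0, u = u,
                 element_fields = fields, strain_energy = 0,
                 penalty_energy = 0, external_work = 0,
                 contact = NULL, mode = mode, terminal = TRUE),
            class = "solution_state")
}

# independent brute-force two-sided Mann-Whitney p value: enumerate all group
# assignments and recompute U directly from the values (pair counting)
bf_mwu_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  u_of <- function(x, y) {
    ua <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    min(ua, n * m - ua)
  }
  obs <- u_of(a, b)
  pool <- c(a, b)
  sets <- utils::combn(n + m, n)
  us <- apply(sets, 2, function(ix) u_of(pool[ix], pool[-ix]))
  mean(us <= obs + 1e-9)
}
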