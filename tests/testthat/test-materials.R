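test_that("constructor resolves moduli and enforces invariants", {
  m <- neo_hookean(G = 10, kappa_ratio = 1e5)
  expect_equal(m$c10, 5)
  expect_equal(m$G, 2 * m$c10)
  expect_equal(m$K, 2 / m$d1)
  expect_equal(m$K, 1e6)
  m2 <- neo_hookean(G = 90, nu = 0.475)
  expect_equal(m2$K, 2 * 90 * 1.475 / (3 * 0.05))
  expect_error(neo_hookean(c10 = -1, d1 = 1), "positive")
  expect_error(neo_hookean(G = 10), "d1, K, nu or kappa_ratio")
})

test_that("strain energy: reference state, isochoric shear, invalid J", {
  m <- neo_hookean(c10 = 3.5, d1 = 1 / 500)
  expect_equal(strain_energy(m, diag(3)), 0)
  for (gam in c(0.1, 0.5, 1.3)) {
    F <- diag(3)
    F[1, 2] <- gam
    expect_equal(strain_energy(m, F), m$c10 * gam^2, tolerance = 1e-12)
  }
  Fbad <- diag(c(-1, 1, 1))
  expect_error(strain_energy(m, Fbad), "non-positive Jacobian")
})

test_that("strain energy matches the symbolic evaluation on frozen gradients", {
  # expected values computed independently with an arbitrary-precision CAS
  m <- neo_hookean(c10 = 3.5, d1 = 1 / 500)
  F1 <- matrix(c(1.20, -0.13, -0.19, -0.03, 0.95, -0.06,
                 -0.12, -0.14, 1.14), 3, 3, byrow = TRUE)
  F2 <- matrix(c(0.85, 0.17, 0.07, -0.18, 0.81, -0.15,
                 -0.07, -0.06, 1.12), 3, 3, byrow = TRUE)
  F3 <- matrix(c(1.18, -0.19, 0.15, -0.08, 1.14, 0.06,
                 -0.06, 0.08, 1.17), 3, 3, byrow = TRUE)
  expect_equal(strain_energy(m, F1), 34.929918749260273, tolerance = 1e-12)
  expect_equal(strain_energy(m, F2), 19.707930635513666, tolerance = 1e-12)
  expect_equal(strain_energy(m, F3), 157.30460764072747, tolerance = 1e-12)
})

test_that("Cauchy stress: reference, pure dilation, finite-difference oracle", {
  m <- neo_hookean(G = 8, kappa_ratio = 200)
  expect_equal(cauchy_stress(m, diag(3)), matrix(0, 3, 3))
  s <- cauchy_stress(m, diag(3) * 1.1)
  expect_equal(s[1, 1], s[2, 2])
  expect_equal(s[1, 1], s[3, 3])
  expect_equal(s[upper.tri(s)], rep(0, 3))
  expect_equal(s[lower.tri(s)], rep(0, 3))

  # stress power dPsi = P : dF, with P = J sigma F^{-T}
  set.seed(4)
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    if (det(F) <= 0.2) next
    P <- det(F) * cauchy_stress(m, F) %*% t(solve(F))
    h <- 1e-6
    for (k in sample(9, 3)) {
      dF <- matrix(0, 3, 3)
      dF[k] <- h
      num <- (strain_energy(m, F + dF) - strain_energy(m, F - dF)) / (2 * h)
      expect_equal(num, P[k], tolerance = 1e-4)
    }
  }
  expect_error(cauchy_stress(m, diag(c(1, -2, 1))), "non-positive Jacobian")
})
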