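#' Neo-Hookean material
#'
#' Compressible Neo-Hookean hyperelastic material with strain energy
#' \deqn{\Psi = C_{10}(\bar I_1 - 3) + \frac{1}{D_1}(J - 1)^2,}
#' where \eqn{\bar I_1 = J^{-2/3}\,\mathrm{tr}(F^T F)} is the isochoric first
#' invariant and \eqn{J = \det F} the volume ratio.  The initial shear modulus
#' is \eqn{G = 2 C_{10}} and the initial bulk modulus \eqn{K = 2/D_1}.
#'
#' The material can be specified either by the constants \code{c10} and
#' \code{d1}, or by moduli: \code{G} together with one of \code{K},
#' \code{kappa_ratio} (\eqn{K = \kappa G}) or a Poisson ratio \code{nu}
#' (\eqn{K = 2G(1+\nu) / (3(1-2\nu))}).
#'
#' @param c10 shear-like constant (kPa).
#' @param d1 compressibility constant (1/kPa).
#' @param G initial shear modulus (kPa); alternative to \code{c10}.
#' @param K initial bulk modulus (kPa); alternative to \code{d1}.
#' @param nu Poisson ratio used to derive \code{K} from \code{G}.
#' @param kappa_ratio ratio \code{K/G} used to derive \code{K} from \code{G}.
#' @return An object of class \code{neo_hookean} with fields \code{c10},
#'   \code{d1}, \code{G}, \code{K}.
#' @examples
#' m <- neo_hookean(G = 10, kappa_ratio = 1e5)
#' m$c10  # 5 kPa
#' @export
neo_hookean <- function(c10 = NULL, d1 = NULL, G = NULL, K = NULL,
                        nu = NULL, kappa_ratio = NULL) {
  if (is.null(c10)) {
    if (is.null(G)) stop("supply either c10 or G")
    c10 <- G / 2
  }
  if (is.null(d1)) {
    if (is.null(K)) {
      G0 <- 2 * c10
      if (!is.null(nu)) {
        if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)")
        K <- 2 * G0 * (1 + nu) / (3 * (1 - 2 * nu))
      } else if (!is.null(kappa_ratio)) {
        K <- kappa_ratio * G0
      } else {
        stop("supply d1, K, nu or kappa_ratio")
      }
    }
    d1 <- 2 / K
  }
  if (!is.finite(c10) || c10 <= 0) stop("c10 must be positive")
  if (!is.finite(d1) || d1 <= 0) stop("d1 must be positive")
  structure(list(c10 = c10, d1 = d1, G = 2 * c10, K = 2 / d1),
            class = "neo_hookean")
}

#' @exportS3Method base::print
print.neo_hookean <- function(x, ...) {
  cat(sprintf("Neo-Hookean material: C10 = %g kPa, D1 = %g 1/kPa (G = %g kPa, K = %g kPa)\n",
              x$c10, x$d1, x$G, x$K))
  invisible(x)
}

as_F3 <- function(F) {
  if (!is.matrix(F) || !is.numeric(F)) stop("deformation gradient must be a numeric matrix")
  if (all(dim(F) == c(2L, 2L))) {
    F3 <- diag(3)
    F3[1:2, 1:2] <- F
    F3
  } else if (all(dim(F) == c(3L, 3L))) {
    F
  } else {
    stop("deformation gradient must be 2x2 or 3x3")
  }
}

#' Strain energy density
#'
#' Evaluates the Neo-Hookean strain energy density at a deformation gradient.
#' A 2x2 gradient is interpreted as plane strain (unit out-of-plane stretch).
#'
#' @param material a [neo_hookean()] material.
#' @param F deformation gradient, 2x2 or 3x3 numeric matrix with positive
#'   determinant.
#' @return Energy density in kPa (equivalently mJ/mm^3 times 1e-3).
#' @examples
#' m <- neo_hookean(G = 10, kappa_ratio = 100)
#' strain_energy(m, diag(3))  # 0 in the reference state
#' @export
strain_energy <- function(material, F) {
  stopifnot(inherits(material, "neo_hookean"))
  F3 <- as_F3(F)
  J <- det(F3)
  if (!is.finite(J) || J <= 0) {
    stop("invalid deformation: non-positive Jacobian J")
  }
  I1 <- sum(F3 * F3)
  material$c10 * (J^(-2 / 3) * I1 - 3) + (1 / material$d1) * (J - 1)^2
}

#' Cauchy stress
#'
#' Analytic Cauchy stress of the Neo-Hookean law,
#' \deqn{\sigma = 2 C_{10} J^{-5/3}\,\mathrm{dev}(B) + \frac{2}{D_1}(J-1) I,}
#' with \eqn{B = F F^T}.  Consistent with [strain_energy()]: the stress power
#' \eqn{J^{-1} P : \delta F} matches the first-order perturbation of the
#' energy.
#'
#' @inheritParams strain_energy
#' @return 3x3 Cauchy stress tensor (kPa).
#' @export
cauchy_stress <- function(material, F) {
  stopifnot(inherits(material, "neo_hookean"))
  F3 <- as_F3(F)
  J <- det(F3)
  if (!is.finite(J) || J <= 0) {
    stop("invalid deformation: non-positive Jacobian J")
  }
  B <- F3 %*% t(F3)
  devB <- B - diag(3) * (sum(diag(B)) / 3)
  2 * material$c10 * J^(-5 / 3) * devB + (2 / material$d1) * (J - 1) * diag(3)
}

#' First Piola-Kirchhoff stress (internal helper, exported for verification)
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola-Kirchhoff stress tensor (kPa).
#' @keywords internal
#' @export
first_piola <- function(material, F) {
  F3 <- as_F3(F)
  J <- det(F3)
  if (!is.finite(J) || J <= 0) stop("invalid deformation: non-positive Jacobian J")
  J * cauchy_stress(material, F3) %*% t(solve(F3))
}
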