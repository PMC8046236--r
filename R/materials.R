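#' Neo-Hookean material
#'
#' Compressible Neo-Hookean hyperelastic material in the two-parameter
#' volumetric/isochoric split
#' \deqn{\Psi = C_{10}(\bar I_1 - 3) + \frac{1}{D_1}(J - 1)^2,}
#' where \eqn{\bar I_1 = \mathrm{tr}(\bar b)} is the first invariant of the
#' modified left Cauchy--Green tensor \eqn{\bar b = J^{-2/3} b} and
#' \eqn{J = \det F} the volume ratio. The initial shear modulus is
#' \eqn{\mu = 2 C_{10}} and the initial bulk modulus \eqn{\kappa = 2/D_1}.
#'
#' Defaults describe a soft, nearly incompressible collagen-scale medium
#' (shear modulus 40 kPa, bulk modulus 400 kPa); the same constants are used
#' for the cell body and the matrix.
#'
#' @param C10 isochoric stiffness constant, kPa. Must be positive.
#' @param D1 inverse volumetric stiffness, 1/kPa. Must be positive.
#' @return An object of class `neo_hookean`.
#' @examples
#' mat <- neo_hookean()
#' strain_energy(def_state(diag(3)), mat) # 0 at the reference state
#' @export
neo_hookean <- function(C10 = 20, D1 = 0.005) {
  stopifnot(is.numeric(C10), length(C10) == 1, C10 > 0,
            is.numeric(D1), length(D1) == 1, D1 > 0)
  structure(list(C10 = C10, D1 = D1), class = "neo_hookean")
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf("Neo-Hookean material: C10 = %g kPa, D1 = %g 1/kPa (mu = %g, kappa = %g kPa)\n",
              x$C10, x$D1, 2 * x$C10, 2 / x$D1))
  invisible(x)
}

#' Kinematic state at a material point
#'
#' Derives the full set of finite-strain kinematic tensors from a deformation
#' gradient: left Cauchy--Green tensor \eqn{b = F F^T}, volume ratio
#' \eqn{J = \det F}, modified tensor \eqn{\bar b = J^{-2/3} b}, its first
#' invariant \eqn{\bar I_1}, and the logarithmic (Hencky) strain
#' \eqn{\ln V = \frac{1}{2}\ln b}.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return Object of class `def_state` with fields `F`, `b`, `bbar`, `J`,
#'   `I1_bar`, `logV`.
#' @export
def_state <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) stop("def_state: det(F) must be positive (element inversion)")
  b <- F %*% t(F)
  b <- (b + t(b)) / 2
  bbar <- J^(-2 / 3) * b
  eb <- eigen(b, symmetric = TRUE)
  logV <- eb$vectors %*% diag(log(eb$values) / 2) %*% t(eb$vectors)
  structure(list(F = F, b = b, bbar = bbar, J = J,
                 I1_bar = sum(diag(bbar)), logV = (logV + t(logV)) / 2),
            class = "def_state")
}

as_def_state <- function(x) {
  if (inherits(x, "def_state")) x else def_state(x)
}

#' Strain energy density
#'
#' Evaluates \eqn{\Psi = C_{10}(\bar I_1 - 3) + (1/D_1)(J-1)^2} at a
#' deformation state.
#'
#' @param state a [def_state()] or a 3x3 deformation gradient.
#' @param mat a [neo_hookean()] material.
#' @return Energy density in kPa.
#' @export
strain_energy <- function(state, mat) {
  s <- as_def_state(state)
  mat$C10 * (s$I1_bar - 3) + (1 / mat$D1) * (s$J - 1)^2
}

#' Cauchy stress
#'
#' Evaluates the Cauchy stress of the Neo-Hookean material,
#' \deqn{\sigma = \frac{2 C_{10}}{J}\left(\bar b - \frac{\bar I_1}{3} I\right)
#'   + \frac{2}{D_1}(J - 1) I,}
#' the push-forward of \eqn{2\,\partial\Psi/\partial C}. The isochoric part is
#' deviatoric (trace-free) by construction.
#'
#' @inheritParams strain_energy
#' @return 3x3 symmetric stress tensor, kPa.
#' @export
cauchy_stress <- function(state, mat) {
  s <- as_def_state(state)
  I3 <- diag(3)
  sig <- (2 * mat$C10 / s$J) * (s$bbar - (s$I1_bar / 3) * I3) +
    (2 / mat$D1) * (s$J - 1) * I3
  (sig + t(sig)) / 2
}
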