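#' Cell monolayer material description
#'
#' The monolayer is modeled as a homogeneous sheet of height `height_h`
#' whose in-plane stress is linear in the strain rate (viscous fluid) or
#' strain (elastic solid) with a bulk constant `K1` and shear constant `K2`:
#' \deqn{\sigma_{ij} = (K_1 - \tfrac{2}{3} K_2)\,\dot\varepsilon_{kk}\,
#'   \delta_{ij} + 2 K_2\, \dot\varepsilon_{ij}.}
#' Only the dimensionless ratio of the constants affects the recovered
#' stresses (see [solve_stress()]); the default pair maps to an effective
#' plane-stress Poisson-like ratio of 0.5 via [k_to_nu()].
#'
#' @param height_h Monolayer height in µm (> 0).
#' @param K1,K2 Bulk and shear constants; arbitrary consistent units.
#' @return An object of class `monolayer`.
#' @export
monolayer <- function(height_h = 5, K1 = 8 / 3, K2 = 1) {
  if (height_h <= 0) stop("height_h must be positive")
  if (K2 <= 0) stop("K2 must be positive")
  if (K1 + K2 / 3 <= 0)
    stop("K1 - 2/3*K2 + K2 must be positive (positive-definite response)")
  structure(list(height_h = height_h, K1 = K1, K2 = K2), class = "monolayer")
}

#' Effective Poisson-like ratio of a (K1, K2) pair
#'
#' Writing the constitutive law in Lamé-like form
#' \eqn{\sigma = \lambda^* \mathrm{tr}(\dot\varepsilon) I +
#' 2\mu \dot\varepsilon} with \eqn{\lambda^* = K_1 - 2K_2/3},
#' \eqn{\mu = K_2}, and matching the plane-stress elastic matrix gives
#' \deqn{\nu_m = \frac{K_1 - 2K_2/3}{K_1 + 4K_2/3}.}
#'
#' @param K1,K2 Constitutive constants (or a [monolayer()] via `mono`).
#' @param mono Optional monolayer; overrides `K1`, `K2`.
#' @return The dimensionless ratio `nu_m` in (-1, 1).
#' @export
k_to_nu <- function(K1, K2, mono = NULL) {
  if (!is.null(mono)) { K1 <- mono$K1; K2 <- mono$K2 }
  (K1 - 2 * K2 / 3) / (K1 + 4 * K2 / 3)
}

#' Elastic substrate for the traction inverse problem
#'
#' Parameters of the elastic half-space below the cells. The physical gel is
#' 100–120 µm thick, far thicker than the displacement decay length at the
#' traction wavelengths of a millimetric island, so the half-space kernel is
#' used; the nominal thickness is only recorded.
#'
#' @param youngs_modulus_E Young's modulus in Pa (experiments use 6000).
#' @param poisson_ratio Poisson ratio in \[0, 0.5\]; polyacrylamide is nearly
#'   incompressible, default 0.45. The value 0.5 is handled by the same
#'   kernel formula, which stays finite there.
#' @param thickness Nominal gel thickness in µm (metadata only).
#' @return An object of class `substrate`.
#' @export
substrate <- function(youngs_modulus_E = 6000, poisson_ratio = 0.45,
                      thickness = 110) {
  if (youngs_modulus_E <= 0) stop("youngs_modulus_E must be positive")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must be in [0, 0.5]")
  structure(list(youngs_modulus_E = youngs_modulus_E,
                 poisson_ratio = poisson_ratio, thickness = thickness),
            class = "substrate")
}
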