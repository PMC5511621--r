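# Mechanical constitutive relations on the infinitely thin (Y,Z) tissue slice.
#
# Symmetric in-plane tensors are stored as 3-column matrices (t22, t23, t33);
# the out-of-plane components are identically zero on the slice, so the trace
# is t22 + t33 and the identity acts on the in-plane components only.
# Velocity gradients L = grad v are stored as 4-column matrices
# (L22, L23, L32, L33) with L_ab = d v_a / d x_b.

#' Construct a plane symmetric tensor field
#'
#' @param t22,t23,t33 numeric vectors (recycled to a common length).
#' @return 3-column matrix with columns \code{t22}, \code{t23}, \code{t33}.
#' @export
plane_tensor <- function(t22 = 0, t23 = 0, t33 = 0) {
  n <- max(length(t22), length(t23), length(t33))
  m <- cbind(t22 = rep_len(t22, n), t23 = rep_len(t23, n),
             t33 = rep_len(t33, n))
  m
}

tensor_trace <- function(t) t[, 1] + t[, 3]

sym_part <- function(L) {
  plane_tensor(L[, 1], 0.5 * (L[, 2] + L[, 3]), L[, 4])
}

spin_part <- function(L) {
  0.5 * (L[, 2] - L[, 3])  # skw(L) = w * [[0, 1], [-1, 0]]
}

#' Collagen-dependent Young's modulus
#'
#' \code{E(rho) = E_I * sqrt(rho)}: stiffness grows with the square root of
#' the local collagen concentration.
#'
#' @param rho collagen concentration, g/cm^3 (vector).
#' @param params a \code{model_parameters} object.
#' @return Young's modulus, N/cm^2.
#' @export
youngs_modulus <- function(rho, params) {
  params$E_I * sqrt(pmax(rho, 0))
}

#' Visco-elastic Cauchy stress
#'
#' \code{sigma = mu_1 sym(L) + mu_2 tr(sym(L)) I
#'   + E(rho)/(1+nu) [eps + tr(eps) nu/(1-2 nu) I]}, traces taken over the
#' in-plane components (the out-of-plane strain entries vanish on the slice).
#'
#' @param eps effective strain, plane tensor (3-column matrix).
#' @param L velocity gradient, 4-column matrix; may be \code{NULL} for the
#'   elastic part alone.
#' @param rho collagen concentration vector.
#' @param params a \code{model_parameters} object; requires \code{nu < 1/2}.
#' @return Cauchy stress, plane tensor, N/cm^2.
#' @export
cauchy_stress <- function(eps, L, rho, params) {
  if (params$nu >= 0.5) stop("nu = 1/2 (incompressible limit) is not supported")
  E <- youngs_modulus(rho, params)
  ce <- E / (1 + params$nu)
  cv <- params$nu / (1 - 2 * params$nu)
  tre <- tensor_trace(eps)
  sig <- plane_tensor(ce * (eps[, 1] + cv * tre),
                      ce * eps[, 2],
                      ce * (eps[, 3] + cv * tre))
  if (!is.null(L)) {
    S <- sym_part(L)
    trS <- tensor_trace(S)
    sig <- sig + plane_tensor(params$mu_1 * S[, 1] + params$mu_2 * trS,
                              params$mu_1 * S[, 2],
                              params$mu_1 * S[, 3] + params$mu_2 * trS)
  }
  sig
}

#' Isotropic myofibroblast traction stress
#'
#' \code{psi = xi * M * rho / (R_const^2 + rho^2) * I}; the body force in the
#' momentum balance is \code{f = div psi}.  The collagen dependence is maximal
#' at \code{rho = R_const}.
#'
#' @param M myofibroblast density vector, cells/cm^3.
#' @param rho collagen concentration vector, g/cm^3.
#' @param params a \code{model_parameters} object.
#' @return Scalar traction magnitude per node (the tensor is this scalar times
#'   the in-plane identity), N/cm^2.
#' @export
traction_stress <- function(M, rho, params) {
  params$xi * M * rho / (params$R_const^2 + rho^2)
}

#' Morphoelastic growth tensor
#'
#' Rate of active (plastic-like) change of the effective strain:
#' \code{G = zeta * (N + eta_II M) c / (1 + a_c_III c) * eps} -- the MMP level
#' times signal concentration over collagen, with the collagen factor
#' cancelling against the MMP proxy, acting along the current strain.
#'
#' @param eps effective strain, plane tensor.
#' @param p list with vectors \code{N}, \code{M}, \code{c}.
#' @param params a \code{model_parameters} object.
#' @return plane tensor, 1/day.
#' @export
growth_tensor <- function(eps, p, params) {
  k <- params$zeta * (p$N + params$eta_II * p$M) * p$c /
    (1 + params$a_c_III * p$c)
  plane_tensor(k * eps[, 1], k * eps[, 2], k * eps[, 3])
}

#' Material rate of the effective strain
#'
#' Evolution of the infinitesimal effective strain with the Jaumann
#' (corotational) correction moved to the right-hand side:
#' \code{D eps / D t = -[tr(eps) - 1] sym(L) - G - eps skw(L) + skw(L) eps}.
#' The output is symmetric whenever \code{eps} is.
#'
#' @param eps effective strain, plane tensor.
#' @param L velocity gradient, 4-column matrix.
#' @param G growth tensor, plane tensor.
#' @return plane tensor, 1/day.
#' @export
strain_rate <- function(eps, L, G) {
  S <- sym_part(L)
  w <- spin_part(L)
  a <- tensor_trace(eps) - 1
  plane_tensor(
    -a * S[, 1] - G[, 1] + 2 * w * eps[, 2],
    -a * S[, 2] - G[, 2] - w * (eps[, 1] - eps[, 3]),
    -a * S[, 3] - G[, 3] - 2 * w * eps[, 2]
  )
}
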