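# Pointwise biochemical kinetics and flux laws for the four constituents:
# fibroblasts N, myofibroblasts M, generic signalling molecule c (e.g.
# TGF-beta), collagen rho.  All functions are vectorised over nodes.

# saturating fraction c/(a + c) with the continuous extension 0/0 -> 0
hill_frac <- function(c, a) {
  den <- a + c
  out <- ifelse(den > 0, c / den, 0)
  out
}

# z^(1+q) for z >= 0; clip FP noise below zero before powering
pow1q <- function(z, q) {
  pmax(z, 0)^(1 + q)
}

#' MMP concentration proxy
#'
#' The matrix-metalloproteinase level is a derived quantity
#' \code{g = (N + eta_II * M) * rho / (1 + a_c_III * c)}: MMPs are secreted by
#' (myo)fibroblasts in proportion to the collagen present, and their secretion
#' is inhibited by the signalling molecule.
#'
#' @param p list with numeric components \code{N}, \code{M}, \code{c},
#'   \code{rho} (vectors of equal length; cells/cm^3 and g/cm^3).
#' @param params a \code{model_parameters} object.
#' @return MMP level, units cells g/cm^6.
#' @export
mmp_level <- function(p, params) {
  (p$N + params$eta_II * p$M) * p$rho / (1 + params$a_c_III * p$c)
}

#' Fibroblast reaction term
#'
#' Signal-enhanced, crowding-limited division, differentiation loss into
#' myofibroblasts, and apoptosis:
#' \code{r_F [1 + r_F_max c/(a_c_I + c)] [1 - kappa_F F] N^(1+q)
#'   - k_F c N - delta_N N}, with \code{F = N + M}.
#'
#' @inheritParams mmp_level
#' @return dN/dt contribution, cells/(cm^3 day).
#' @export
reaction_fibroblasts <- function(p, params) {
  F_tot <- p$N + p$M
  params$r_F * (1 + params$r_F_max * hill_frac(p$c, params$a_c_I)) *
    (1 - params$kappa_F * F_tot) * pow1q(p$N, params$q) -
    params$k_F * p$c * p$N - params$delta_N * p$N
}

#' Myofibroblast reaction term
#'
#' Division (fully signal-dependent), differentiation gain from fibroblasts,
#' and apoptosis:
#' \code{r_F [(1 + r_F_max) c/(a_c_I + c)] [1 - kappa_F F] M^(1+q)
#'   + k_F c N - delta_M M}.
#'
#' @inheritParams mmp_level
#' @return dM/dt contribution, cells/(cm^3 day).
#' @export
reaction_myofibroblasts <- function(p, params) {
  F_tot <- p$N + p$M
  params$r_F * ((1 + params$r_F_max) * hill_frac(p$c, params$a_c_I)) *
    (1 - params$kappa_F * F_tot) * pow1q(p$M, params$q) +
    params$k_F * p$c * p$N - params$delta_M * p$M
}

#' Signalling-molecule reaction term
#'
#' Autocrine net secretion by (myo)fibroblasts and MMP-mediated proteolysis:
#' \code{k_c [c/(a_c_II + c)] (N + eta_I M) - delta_c g c} with
#' \code{g = \link{mmp_level}}.
#'
#' @inheritParams mmp_level
#' @return dc/dt contribution, g/(cm^3 day).
#' @export
reaction_signal <- function(p, params) {
  params$k_c * hill_frac(p$c, params$a_c_II) * (p$N + params$eta_I * p$M) -
    params$delta_c * mmp_level(p, params) * p$c
}

#' Collagen reaction term
#'
#' Signal-enhanced secretion by (myo)fibroblasts and MMP-mediated breakdown:
#' \code{k_rho [1 + k_rho_max c/(a_c_IV + c)] (N + eta_I M) - delta_rho g rho}.
#'
#' @inheritParams mmp_level
#' @return drho/dt contribution, g/(cm^3 day).
#' @export
reaction_collagen <- function(p, params) {
  params$k_rho * (1 + params$k_rho_max * hill_frac(p$c, params$a_c_IV)) *
    (p$N + params$eta_I * p$M) -
    params$delta_rho * mmp_level(p, params) * p$rho
}

#' Cell flux vectors
#'
#' Random dispersal with cell-density-dependent motility plus chemotaxis up
#' the signal gradient: \code{J_N = -D_F F grad N + chi_F N grad c} and the
#' analogous \code{J_M}.  Collagen is immobile (\code{J_rho = 0}).
#'
#' @param p list with \code{N}, \code{M} and gradient components
#'   \code{gN}, \code{gM}, \code{gc}, each a 2-column matrix (d/dY, d/dZ).
#' @param params a \code{model_parameters} object.
#' @return list with 2-column matrices \code{J_N} and \code{J_M},
#'   cells/(cm^2 day).
#' @export
flux_cells <- function(p, params) {
  F_tot <- p$N + p$M
  list(
    J_N = -params$D_F * F_tot * p$gN + params$chi_F * p$N * p$gc,
    J_M = -params$D_F * F_tot * p$gM + params$chi_F * p$M * p$gc
  )
}

#' Signal flux vector
#'
#' Fickian diffusion \code{J_c = -D_c grad c}.
#'
#' @param p list with gradient component \code{gc} (2-column matrix).
#' @param params a \code{model_parameters} object.
#' @return 2-column matrix, g/(cm^2 day).
#' @export
flux_signal <- function(p, params) {
  -params$D_c * p$gc
}

#' Patankar production/loss split of the reaction terms
#'
#' Splits each reaction term into a non-negative production part and a
#' non-negative linearised loss rate so that
#' \code{R_z = production - loss_rate * z} with \code{loss_rate >= 0}.
#' Treating the loss implicitly guarantees positivity of the reaction update
#' for any step size.
#'
#' @inheritParams mmp_level
#' @return list of lists; for each constituent (\code{N}, \code{M}, \code{c},
#'   \code{rho}) a \code{prod} (units of the balance) and a \code{loss}
#'   (1/day) vector.
#' @export
split_sources <- function(p, params) {
  F_tot <- p$N + p$M
  g <- mmp_level(p, params)
  div_N <- params$r_F * (1 + params$r_F_max * hill_frac(p$c, params$a_c_I)) *
    (1 - params$kappa_F * F_tot) * pow1q(p$N, params$q)
  div_M <- params$r_F * ((1 + params$r_F_max) * hill_frac(p$c, params$a_c_I)) *
    (1 - params$kappa_F * F_tot) * pow1q(p$M, params$q)
  # crowding can push the division term negative ([1 - kappa_F F] < 0); route
  # any negative part through the loss channel (per-capita, guarded at z = 0)
  neg_rate <- function(term, z) ifelse(term < 0 & z > 0, -term / z, 0)
  list(
    N = list(prod = pmax(div_N, 0),
             loss = neg_rate(div_N, p$N) + params$k_F * p$c + params$delta_N),
    M = list(prod = pmax(div_M, 0) + params$k_F * p$c * p$N,
             loss = neg_rate(div_M, p$M) + params$delta_M),
    c = list(prod = params$k_c * hill_frac(p$c, params$a_c_II) *
               (p$N + params$eta_I * p$M),
             loss = params$delta_c * g),
    rho = list(prod = params$k_rho *
                 (1 + params$k_rho_max * hill_frac(p$c, params$a_c_IV)) *
                 (p$N + params$eta_I * p$M),
               loss = params$delta_rho * (p$N + params$eta_II * p$M) /
                 (1 + params$a_c_III * p$c) * p$rho)
  )
}
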