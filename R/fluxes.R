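#' Energy fluxes of the standard DEB model
#'
#' Evaluates the assimilation, mobilization, maintenance, growth and
#' maturation/reproduction fluxes at a given organism state. The kappa-rule
#' holds exactly by construction: a fixed fraction `kap` of the mobilized flux
#' goes to soma (somatic maintenance plus growth), the remainder to maturity
#' maintenance and maturation or reproduction.
#'
#' Embryos (`E_H < E_Hb`) do not assimilate. During metabolic acceleration the
#' shape-correction factor `sM >= 1` multiplies both the surface-specific
#' assimilation rate and the energy conductance.
#'
#' @param state a data frame (or list) with columns/fields `E` (reserve, J),
#'   `L` (structural length, cm), `EH` (maturity, J). Vectorized over rows.
#' @param f scaled functional response in `[0, 1]`.
#' @param sM shape correction factor, `>= 1`.
#' @param p a [deb_params()] object (rates already at body temperature).
#' @return a tibble with columns `pA`, `pX`, `pC`, `pS`, `pJ`, `pG`, `pR`
#'   (J/d) and logical `starved` (`pG < 0`).
#' @export
#' @examples
#' p <- deb_params()
#' st <- list(E = 0.5^3 * p$p_Am / p$v, L = 0.5, EH = p$E_Hp)
#' deb_fluxes(st, f = 1, sM = 1, p = p)
#' Aging dynamics
#'
#' Derivatives of the aging states: aging acceleration `q` (1/d^2), hazard
#' rate `h` (1/d) and survival probability `S`. Damage induction scales with
#' the Weibull aging acceleration `h_a` and is amplified by the Gompertz
#' stress coefficient `s_G`; dilution by growth enters through the specific
#' growth rate `r`.
#'
#' @param state list/data frame with `E`, `L`, `q`, `h`, `S`.
#' @param r specific growth rate of structure (1/d), `3 (dL/dt) / L`.
#' @param sM shape correction factor.
#' @param p a [deb_params()] object (rates at body temperature).
#' @return tibble with `dq`, `dh`, `dS`.
#' @export
#' @examples
#' aging_dynamics(list(E = 140, L = 0.5, q = 0, h = 0, S = 1), r = 0, sM = 1,
#'   p = deb_params())
aging_dynamics <- function(state, r, sM, p) {
  E_m <- p$p_Am / p$v
  L_m <- p$kap * p$p_Am / p$p_M
  e <- state$E / (state$L^3 * E_m)
  dq <- (state$q * (state$L^3 / L_m^3) * p$s_G + p$h_a) * e *
    (p$v * sM / state$L - r) - r * state$q
  dh <- state$q - r * state$h
  dS <- -state$h * state$S
  tibble::tibble(dq = dq, dh = dh, dS = dS)
}

deb_fluxes <- function(state, f, sM, p) {
  if (any(f < 0 | f > 1)) stop("`f` must lie in [0, 1]", call. = FALSE)
  if (any(sM < 1)) stop("`sM` must be >= 1", call. = FALSE)
  E <- state$E
  L <- state$L
  EH <- state$EH
  if (any(L < 0) || any(E < 0)) stop("state must satisfy E, L >= 0", call. = FALSE)
  pA <- ifelse(EH >= p$E_Hb, p$p_Am * f * sM * L^2, 0)
  pS <- p$p_M * L^3 + p$p_T * sM * L^2
  pJ <- p$k_J * pmin(EH, p$E_Hp)
  # mobilization; written to remain finite as L -> 0 (multiply num/denom by L^3)
  pC <- E * (p$E_G * p$v * sM * L^2 + pS) / (p$E_G * L^3 + p$kap * E)
  pC[L == 0] <- 0
  pG <- p$kap * pC - pS
  pR <- (1 - p$kap) * pC - pJ
  tibble::tibble(
    pA = pA, pX = pA / p$kap_X, pC = pC, pS = pS, pJ = pJ,
    pG = pG, pR = pR, starved = pG < 0
  )
}
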