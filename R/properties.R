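#' Implied physiological properties of a parameter set
#'
#' Computes a core set of biologically relevant quantities implied by the
#' primary parameters at a given food level and temperature: ages, lengths and
#' wet weights at stage transitions, initial reserve, the von Bertalanffy
#' growth rate, ultimate size, maximum reproduction rate, mean lifespan
#' (the expectation of the survival distribution), the metabolic acceleration
#' factor and a respiration proxy (somatic plus maturity maintenance at
#' ultimate size). Quantities whose stage is not reached are reported `NA`
#' with a reason.
#'
#' @param p a [deb_params()] object.
#' @param model a [deb_model()].
#' @param f scaled functional response (constant), in `(0, 1]`.
#' @param T_K body temperature (K).
#' @param chem a [chemical_params()] object for weight conversions.
#' @param sim optionally, a precomputed trajectory from
#'   [integrate_life_cycle()] at the same `p`, `model`, `f`, `T_K`.
#' @return a tibble with columns `property`, `value`, `units`, `note`.
#' @export
#' @examples
#' implied_properties(deb_params(), deb_model("std"))
implied_properties <- function(p, model = deb_model("std"), f = 1,
                               T_K = p$T_ref, chem = chemical_params(),
                               sim = NULL) {
  validate_deb_params(p, model)
  pT <- params_at_temp(p, T_K)
  E_m <- pT$p_Am / pT$v
  cmp <- compound_parameters(p) # lengths are temperature-independent
  if (is.null(sim)) {
    sim <- integrate_life_cycle(p, model, f = f, T_K = T_K)
  }
  sched <- attr(sim, "schedule")
  ev <- function(code, col) {
    row <- sched[sched$event == code & sched$reached, , drop = FALSE]
    if (nrow(row) == 0) NA_real_ else row[[col]][[1]]
  }
  state_at <- function(age) {
    i <- which.min(abs(sim$t - age))
    sim[i, , drop = FALSE]
  }

  a_b <- ev("b", "age")
  L_b <- ev("b", "L")
  a_p <- ev("p", "age")
  L_p <- ev("p", "L")
  L_j <- ev("j", "L")
  acc <- acceleration_factor(sched, model)
  s_M <- if (is.na(acc$factor)) NA_real_ else acc$factor
  L_i <- if (is.na(s_M)) NA_real_ else s_M * (f * cmp$L_m - cmp$L_T)
  E0 <- attr(sim, "E0")
  if (is.na(E0) && model$label %in% c("stf", "stx")) {
    E0 <- fetal_birth(p, f = f, T_K = T_K)$E0
  }

  # mean lifespan: expectation of the survival distribution
  died <- any(sched$event == "death" & sched$reached)
  a_m <- if (died) max(sim$SC) else NA_real_

  # von Bertalanffy growth rate (post-acceleration, isomorphic limit)
  g <- cmp$g
  rB <- (cmp$k_M * temp_correction(T_K, p)) / 3 / (1 + f / g)

  # maximum reproduction rate at ultimate size
  R_i <- NA_real_
  if (!is.na(L_i) && model$family != "h" && !is.na(a_p)) {
    pS_i <- pT$p_M * L_i^3 + pT$p_T * s_M * L_i^2
    pC_i <- pS_i / pT$kap # no growth at ultimate size
    pR_i <- (1 - pT$kap) * pC_i - pT$k_J * pT$E_Hp
    if (model$label %in% c("sbp", "abp")) {
      pR_i <- pC_i - pS_i - pT$k_J * pT$E_Hp
    }
    if (!is.na(E0) && pR_i > 0) R_i <- pT$kap_R * pR_i / E0
  }

  # weights from simulated states at events
  Ww_at <- function(age) {
    if (is.na(age)) return(NA_real_)
    st <- state_at(age)
    wet_weight(st$L, st$E, chem)
  }
  Ww_b <- Ww_at(a_b)
  Ww_p <- Ww_at(a_p)
  Ww_i <- if (is.na(L_i)) NA_real_ else wet_weight(L_i, f * E_m * L_i^3, chem)

  # respiration proxy: maintenance power at ultimate size
  resp <- if (is.na(L_i)) NA_real_ else pT$p_M * L_i^3 + pT$p_T * (if (is.na(s_M)) 1 else s_M) * L_i^2 + pT$k_J * pT$E_Hp

  rows <- tibble::tribble(
    ~property, ~value, ~units,
    "E0", E0, "J",
    "a_b", a_b, "d",
    "a_j", ev("j", "age"), "d",
    "a_p", a_p, "d",
    "a_m", a_m, "d",
    "L_b", L_b, "cm",
    "L_j", L_j, "cm",
    "L_p", L_p, "cm",
    "L_i", L_i, "cm",
    "Ww_b", Ww_b, "g",
    "Ww_p", Ww_p, "g",
    "Ww_i", Ww_i, "g",
    "r_B", rB, "1/d",
    "R_i", R_i, "1/d",
    "s_M", s_M, "-",
    "p_resp_i", resp, "J/d"
  )
  rows$note <- ifelse(is.na(rows$value), "stage not reached or undefined", "")
  rows
}
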