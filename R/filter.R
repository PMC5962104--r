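#' Parameter feasibility filter
#'
#' Tests a candidate parameter set for physical and biological consistency
#' before any model prediction is attempted: no negative rates, costs or
#' maturity levels; fractions within bounds; maturity thresholds correctly
#' ordered; birth reachable (an egg with finite initial reserve can develop to
#' `E_Hb`); and puberty reachable (the maturity ceiling at ultimate size
#' exceeds `E_Hp`). Cheap algebraic checks run before the reachability checks.
#' The filter always returns a verdict and never raises an error on bad input.
#'
#' @param p a [deb_params()] object (or bare named list of parameter values).
#' @param model a [deb_model()].
#' @param f food level used for the reachability checks.
#' @return a list with `pass` (logical) and `reasons` (character vector of
#'   reason codes, empty when passing).
#' @export
#' @examples
#' filter_check(deb_params(), deb_model("std"))$pass # TRUE
#' filter_check(deb_params(kap = 0.999999), deb_model("std"))
filter_check <- function(p, model = deb_model("std"), f = 1) {
  reasons <- character(0)
  num_ok <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

  strict_pos <- c(
    "F_m", "kap_X", "p_Am", "v", "kap", "kap_R", "p_M", "k_J",
    "E_G", "E_Hb", "E_Hp"
  )
  for (nm in strict_pos) {
    if (!num_ok(p[[nm]]) || p[[nm]] <= 0) {
      reasons <- c(reasons, paste0("non-positive parameter: ", nm))
    }
  }
  for (nm in c("p_T", "s_G", "h_a")) {
    if (!num_ok(p[[nm]]) || p[[nm]] < 0) {
      reasons <- c(reasons, paste0("negative parameter: ", nm))
    }
  }
  if (length(reasons)) {
    return(list(pass = FALSE, reasons = reasons))
  }
  for (nm in c("kap", "kap_X", "kap_R")) {
    if (p[[nm]] > 1 || (nm == "kap" && p[[nm]] >= 1)) {
      reasons <- c(reasons, paste0("fraction out of bounds: ", nm))
    }
  }
  thr <- stage_thresholds(p, model)
  if (length(thr) && is.unsorted(thr, strictly = FALSE)) {
    reasons <- c(reasons, "maturity thresholds mis-ordered")
  }
  if (p$E_Hb >= p$E_Hp) reasons <- c(reasons, "E_Hb >= E_Hp")
  if (length(reasons)) {
    return(list(pass = FALSE, reasons = reasons))
  }

  # maturity ceiling: maturation flux must stay positive up to E_Hp at
  # ultimate size (isomorphic bound; acceleration only relaxes it)
  L_i <- f * p$kap * p$p_Am / p$p_M - p$p_T / p$p_M
  if (L_i <= 0) {
    return(list(pass = FALSE, reasons = "ultimate length non-positive at this food level"))
  }
  pS_i <- p$p_M * L_i^3 + p$p_T * L_i^2
  if ((1 - p$kap) * pS_i / p$kap <= p$k_J * p$E_Hp && model$family == "s") {
    return(list(pass = FALSE, reasons = "puberty unreachable: maturity ceiling below E_Hp"))
  }

  # birth reachability: embryo integration must attain E_Hb
  ok <- tryCatch(
    {
      initial_reserve(p, f = f, rtol = 1e-7, atol = 1e-9)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    return(list(pass = FALSE, reasons = "birth unreachable"))
  }
  list(pass = TRUE, reasons = character(0))
}
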