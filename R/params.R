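#' Primary DEB parameter set
#'
#' Constructs the set of primary parameters of the standard Dynamic Energy
#' Budget (DEB) model in a time-length-energy frame (days, cm, Joule, Kelvin),
#' together with the Arrhenius temperature-correction constants and optional
#' extensions used by the typified model family (maturity thresholds for
#' acceleration windows, gestation delay, reproduction-buffer density
#' thresholds, conversion efficiencies).
#'
#' Defaults are the typical generalized-animal values at 20 degrees C for a
#' maximum structural length of 1 cm (zoom factor z = 1). Extensive parameters
#' covary with the dimensionless zoom factor z: the maximum surface-specific
#' assimilation rate scales with z and the maturity thresholds with z^3, so
#' that the compound maximum structural length equals z cm (see
#' [scale_with_zoom()]).
#'
#' @param ... named parameter values overriding the generalized-animal
#'   defaults. Recognised names: `F_m` (specific searching rate, l/d.cm^2),
#'   `kap_X` (assimilation efficiency, -), `p_Am` (max surface-specific
#'   assimilation rate, J/d.cm^2), `v` (energy conductance, cm/d), `kap`
#'   (allocation fraction to soma, -), `kap_R` (reproduction efficiency, -),
#'   `p_M` (volume-specific somatic maintenance, J/d.cm^3), `p_T`
#'   (surface-specific somatic maintenance, J/d.cm^2), `k_J` (maturity
#'   maintenance rate coefficient, 1/d), `E_G` (specific cost for structure,
#'   J/cm^3), `E_Hb`, `E_Hp` (maturity at birth / puberty, J), `s_G` (Gompertz
#'   stress coefficient, -), `h_a` (Weibull aging acceleration, 1/d^2),
#'   `T_ref`, `T_A` (reference and Arrhenius temperatures, K), and the model
#'   extensions `E_Hs`, `E_Hj`, `E_Hx` (J), `t_0`, `t_sj` (d), `E_Rj`
#'   (J/cm^3), `kap_V`, `kap_shrink`, `f_milk` (-).
#' @param z dimensionless zoom factor applied to the defaults before the
#'   overrides in `...` (extensive parameters only).
#' @param free character vector of parameter names marked free (to be
#'   estimated); stored as an attribute and used by [estimate()].
#'
#' @return An object of class `deb_params`: a named list of numeric values
#'   with attributes `free` and `units`.
#' @seealso [compound_parameters()], [scale_with_zoom()], [tidy.deb_params()]
#' @export
#' @examples
#' p <- deb_params(z = 2)
#' compound_parameters(p)$L_m # 2 cm
deb_params <- function(..., z = 1, free = c("p_Am", "v", "kap", "p_M", "E_Hb", "E_Hp")) {
  base <- list(
    F_m = 6.5, kap_X = 0.8, p_Am = 22.5, v = 0.02, kap = 0.8, kap_R = 0.95,
    p_M = 18, p_T = 0, k_J = 0.002, E_G = 2800, E_Hb = 0.275, E_Hp = 166,
    s_G = 1e-4, h_a = 1e-10, T_ref = 293.15, T_A = 8000,
    E_Hs = NA_real_, E_Hj = NA_real_, E_Hx = NA_real_,
    t_0 = 0, t_sj = 0, E_Rj = NA_real_,
    kap_V = 0.8, kap_shrink = 0.8, f_milk = 1
  )
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0) {
    stop("`z` must be a single positive number", call. = FALSE)
  }
  base$p_Am <- base$p_Am * z
  base$E_Hb <- base$E_Hb * z^3
  base$E_Hp <- base$E_Hp * z^3
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    base[names(over)] <- over
  }
  structure(base,
    class = "deb_params",
    free = intersect(free, names(base)),
    units = deb_param_units()[names(base)]
  )
}

deb_param_units <- function() {
  c(
    F_m = "l/d.cm^2", kap_X = "-", p_Am = "J/d.cm^2", v = "cm/d", kap = "-",
    kap_R = "-", p_M = "J/d.cm^3", p_T = "J/d.cm^2", k_J = "1/d",
    E_G = "J/cm^3", E_Hb = "J", E_Hp = "J", s_G = "-", h_a = "1/d^2",
    T_ref = "K", T_A = "K", E_Hs = "J", E_Hj = "J", E_Hx = "J", t_0 = "d",
    t_sj = "d", E_Rj = "J/cm^3", kap_V = "-", kap_shrink = "-", f_milk = "-"
  )
}

# parameter names carrying a per-time dimension (corrected by the Arrhenius
# factor); h_a is per-time-squared and is corrected by the squared factor
rate_param_names <- function() c("F_m", "p_Am", "v", "p_M", "p_T", "k_J")

#' Validate a primary parameter set
#'
#' Checks the structural invariants of a [deb_params()] object: positivity of
#' rates, costs and maturity thresholds (surface-specific maintenance, the
#' Gompertz stress coefficient and the Weibull aging acceleration may be
#' zero), fraction bounds, and the ordering of maturity thresholds. The first
#' violated invariant is reported by field name.
#'
#' @param p a `deb_params` object.
#' @param model optional [deb_model()] used to check extension thresholds.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_deb_params <- function(p, model = NULL) {
  strict_pos <- c("F_m", "kap_X", "p_Am", "v", "kap", "kap_R", "p_M", "k_J",
                  "E_G", "E_Hb", "E_Hp", "T_ref", "T_A")
  for (nm in strict_pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("parameter `", nm, "` must be strictly positive", call. = FALSE)
    }
  }
  for (nm in c("p_T", "s_G", "h_a")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("parameter `", nm, "` must be non-negative", call. = FALSE)
    }
  }
  for (nm in c("kap", "kap_X", "kap_R")) {
    if (p[[nm]] > 1 || (nm == "kap" && p[[nm]] >= 1)) {
      stop("fraction `", nm, "` out of bounds (0, 1]", call. = FALSE)
    }
  }
  if (p$E_Hb >= p$E_Hp) stop("`E_Hb` must be smaller than `E_Hp`", call. = FALSE)
  if (!is.null(model)) {
    thr <- stage_thresholds(p, model)
    if (is.unsorted(thr, strictly = FALSE)) {
      stop("maturity thresholds mis-ordered for model ", model$label, call. = FALSE)
    }
    if (model$label %in% c("ssj") && (!is.finite(p$t_sj) || p$t_sj < 0)) {
      stop("`t_sj` must be non-negative", call. = FALSE)
    }
    if (model$label %in% c("stx") && (!is.finite(p$t_0) || p$t_0 < 0)) {
      stop("`t_0` must be non-negative", call. = FALSE)
    }
  }
  invisible(p)
}

# ordered maturity thresholds relevant to a model (used for ordering checks)
stage_thresholds <- function(p, model) {
  out <- p$E_Hb
  if (model$label == "ssj") out <- c(out, p$E_Hs)
  if (model$label == "asj") out <- c(out, p$E_Hs, p$E_Hj)
  if (model$label %in% c("abj", "abp")) out <- c(out, p$E_Hj)
  if (model$label == "stx") out <- c(out, p$E_Hx)
  out <- c(out, p$E_Hp)
  out[is.finite(out)]
}

#' Compound DEB parameters
#'
#' Computes the standard compound quantities implied by a primary parameter
#' set: maximum reserve density `E_m = {p_Am}/v` (J/cm^3), energy investment
#' ratio `g = [E_G]/(kap E_m)` (-), somatic maintenance rate coefficient
#' `k_M = [p_M]/[E_G]` (1/d), maximum structural length
#' `L_m = kap {p_Am}/[p_M]` (cm), heating length `L_T = {p_T}/[p_M]` (cm) and
#' half-saturation food density `K = {p_Am}/(kap_X {F_m})`.
#'
#' @param p a validated [deb_params()] object.
#' @return A one-row tibble with columns `E_m`, `g`, `k_M`, `k`, `L_m`, `L_T`,
#'   `K`.
#' @export
#' @examples
#' compound_parameters(deb_params())
compound_parameters <- function(p) {
  validate_deb_params(p)
  E_m <- p$p_Am / p$v
  tibble::tibble(
    E_m = E_m,
    g = p$E_G / (p$kap * E_m),
    k_M = p$p_M / p$E_G,
    k = p$k_J / (p$p_M / p$E_G),
    L_m = p$kap * p$p_Am / p$p_M,
    L_T = p$p_T / p$p_M,
    K = p$p_Am / (p$kap_X * p$F_m)
  )
}

#' Arrhenius temperature correction
#'
#' Correction factor `exp(T_A/T_ref - T_A/T)` applied multiplicatively to all
#' rate-dimension parameters before simulation; equals 1 at the reference
#' temperature.
#'
#' @param T_K body temperature (K).
#' @param p a [deb_params()] object supplying `T_ref` and `T_A`.
#' @return the dimensionless correction factor.
#' @export
#' @examples
#' temp_correction(303.15, deb_params()) # > 1: warmer than reference
temp_correction <- function(T_K, p) {
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be strictly positive (K)", call. = FALSE)
  }
  exp(p$T_A / p$T_ref - p$T_A / T_K)
}

# parameters with all rates corrected to body temperature T_K
params_at_temp <- function(p, T_K) {
  tc <- temp_correction(T_K, p)
  for (nm in rate_param_names()) p[[nm]] <- p[[nm]] * tc
  p$h_a <- p$h_a * tc^2
  p
}

#' Scaled functional response
#'
#' Hyperbolic (Holling type II) functional response `f = X/(X + K)` with
#' half-saturation food density `K = {p_Am}/(kap_X {F_m})`.
#'
#' @param X food density (same units as `K`), non-negative.
#' @param p a [deb_params()] object.
#' @return `f` in `[0, 1]`.
#' @export
functional_response <- function(X, p) {
  if (any(!is.finite(X)) || any(X < 0)) stop("food density must be non-negative", call. = FALSE)
  K <- p$p_Am / (p$kap_X * p$F_m)
  X / (X + K)
}

#' Zoom-factor covariation scaling
#'
#' Applies the parameter covariation rules to a reference parameter set at
#' z = 1: the surface-specific assimilation rate scales with z (extensive per
#' area) and the maturity thresholds at birth and puberty with z^3 (extensive
#' per volume); all other primary parameters are intensive and unchanged. The
#' compound maximum structural length of the result equals z times that of the
#' reference.
#'
#' @param reference a [deb_params()] object (taken as the z = 1 reference).
#' @param z zoom factor, > 0.
#' @return a `deb_params` object.
#' @export
scale_with_zoom <- function(reference, z) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0) {
    stop("`z` must be a single positive number", call. = FALSE)
  }
  p <- reference
  p$p_Am <- p$p_Am * z
  p$E_Hb <- p$E_Hb * z^3
  p$E_Hp <- p$E_Hp * z^3
  for (nm in c("E_Hs", "E_Hj", "E_Hx")) {
    if (is.finite(p[[nm]])) p[[nm]] <- p[[nm]] * z^3
  }
  p
}

#' Remove the size dependence from a parameter set
#'
#' Inverse of [scale_with_zoom()]: divides the z-dependent parameters by the
#' set's own zoom factor z = L_m / 1 cm, yielding a size-independent vector
#' that can be compared across species of very different maximum size.
#'
#' @param p a [deb_params()] object.
#' @return a `deb_params` object with `p_Am/z`, maturities divided by `z^3`,
#'   and attribute `z` recording the zoom factor removed.
#' @export
scale_out_size <- function(p) {
  validate_deb_params(p)
  z <- p$kap * p$p_Am / p$p_M # L_m in cm, reference length 1 cm
  out <- scale_with_zoom(p, 1 / z)
  attr(out, "z") <- z
  out
}

#' @export
print.deb_params <- function(x, ...) {
  cat("<deb_params>\n")
  print(tidy.deb_params(x), n = Inf)
  invisible(x)
}

#' Tidy a DEB parameter set
#'
#' @param x a `deb_params` object.
#' @param ... unused.
#' @return a tibble with columns `parameter`, `value`, `units`, `free`.
#' @export
tidy.deb_params <- function(x, ...) {
  tibble::tibble(
    parameter = names(x),
    value = unlist(x, use.names = FALSE),
    units = unname(attr(x, "units")),
    free = names(x) %in% attr(x, "free")
  )
}
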