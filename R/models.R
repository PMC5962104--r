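#' Typified DEB model specification
#'
#' The family of typified DEB models, classified by the mode of metabolic
#' acceleration: s-models are isomorphic over all life stages (`std` egg
#' development, `stf` fetal development, `stx` fetal development with a
#' gestation delay and a weaning diet switch, `ssj` a non-feeding shrinking
#' stage during the juvenile period, `sbp` growth ceasing at puberty);
#' a-models insert a V1-morphic acceleration window (`abj` birth to
#' metamorphosis, `asj` delayed onset at maturity `E_Hs`, `abp` birth to
#' puberty with no adult growth); h-models extend acceleration into the adult
#' stage as in insects (`hep` emergence of a non-growing imago when the
#' reproduction buffer density hits a threshold, `hex` holometabolous
#' development with a pupal stage).
#'
#' @param label one of `"std"`, `"stf"`, `"stx"`, `"ssj"`, `"sbp"`, `"abj"`,
#'   `"asj"`, `"abp"`, `"hep"`, `"hex"`.
#' @return an object of class `deb_model` with fields `label` and `family`
#'   (`"s"`, `"a"` or `"h"`).
#' @export
#' @examples
#' deb_model("abj")
deb_model <- function(label = "std") {
  fam <- c(
    std = "s", stf = "s", stx = "s", ssj = "s", sbp = "s",
    abj = "a", asj = "a", abp = "a", hep = "h", hex = "h"
  )
  if (!is.character(label) || length(label) != 1L || !label %in% names(fam)) {
    stop("unknown model label; must be one of ", paste(names(fam), collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(label = label, family = unname(fam[label])), class = "deb_model")
}

#' @export
print.deb_model <- function(x, ...) {
  cat("<deb_model> ", x$label, " (", x$family, "-family)\n", sep = "")
  invisible(x)
}

#' Shape correction factor
#'
#' V1-morphic shape correction `sM` multiplying both the surface-specific
#' assimilation rate and the energy conductance. s-models are isomorphic
#' (`sM = 1` throughout); a- and h-models accelerate between the start of the
#' window (birth, or `E_Hs` for `asj`) and its end (metamorphosis `E_Hj`,
#' puberty for `abp`/`hep`, pupation for `hex`), after which `sM` is frozen at
#' the ratio of lengths at the end and start of acceleration.
#'
#' @param model a [deb_model()].
#' @param EH current maturity (J).
#' @param L current structural length (cm).
#' @param p a [deb_params()] object (for thresholds).
#' @param L_b,L_s,L_j lengths at birth, acceleration start (`asj`), and
#'   acceleration end, for phases already realized (`NA` otherwise).
#' @return `sM >= 1`.
#' @export
shape_correction <- function(model, EH, L, p, L_b = NA, L_s = NA, L_j = NA) {
  if (model$family == "s") {
    return(rep(1, length(L)))
  }
  L_start <- if (model$label == "asj") L_s else L_b
  EH_start <- if (model$label == "asj") p$E_Hs else p$E_Hb
  EH_end <- switch(model$label,
    abj = p$E_Hj, asj = p$E_Hj, abp = p$E_Hp, hep = p$E_Hp, hex = NA_real_
  )
  sM <- rep(1, length(L))
  during <- EH >= EH_start & (is.na(EH_end) | EH < EH_end)
  after <- !is.na(EH_end) & EH >= EH_end
  if (any(during)) {
    if (is.na(L_start)) stop("acceleration start length not yet realized", call. = FALSE)
    sM[during] <- pmax(1, L[during] / L_start)
  }
  if (any(after)) {
    if (is.na(L_j) || is.na(L_start)) stop("acceleration end length not yet realized", call. = FALSE)
    sM[after] <- max(1, L_j / L_start)
  }
  sM
}

#' Metabolic acceleration factor
#'
#' The ratio of structural lengths at the end and the start of the metabolic
#' acceleration window. Isomorphic s-models have factor 1 by definition.
#'
#' @param schedule a stage schedule tibble as returned by
#'   [integrate_life_cycle()] (attribute `schedule`) or the trajectory itself.
#' @param model a [deb_model()].
#' @return a list with `factor` (numeric or `NA`) and `reason` (`NULL` or a
#'   string explaining an absent value).
#' @export
acceleration_factor <- function(schedule, model) {
  if (inherits(schedule, "deb_trajectory")) schedule <- attr(schedule, "schedule")
  if (model$family == "s") {
    return(list(factor = 1, reason = NULL))
  }
  ev_start <- if (model$label == "asj") "s" else "b"
  ev_end <- switch(model$label, abj = "j", asj = "j", abp = "p", hep = "p", hex = "j")
  L_of <- function(code) {
    row <- schedule[schedule$event == code & schedule$reached, , drop = FALSE]
    if (nrow(row) == 0) NA_real_ else row$L[[1]]
  }
  L0 <- L_of(ev_start)
  L1 <- L_of(ev_end)
  if (is.na(L0) || is.na(L1)) {
    return(list(
      factor = NA_real_,
      reason = paste0("event '", if (is.na(L0)) ev_start else ev_end, "' not realized")
    ))
  }
  list(factor = L1 / L0, reason = NULL)
}

# --- stage plans ------------------------------------------------------------
#
# Each stage is a list:
#   name      stage label
#   event     event code recorded when the stage's end condition fires
#   end       list(type = "maturity" | "duration" | "repro_density" | "none",
#                  value = threshold (J), duration (d) or density (J/cm^3))
#   assim     does the stage feed?
#   f_name    "f" (ambient) or "f_milk" (stx baby stage)
#   sM        "iso" (frozen at entry value), "accel" (grows as L/L_ref)
#   growth    "normal", "none", "shrink", "fetal", "frozen_state" (prep stage)
#   maturing  does EH increase (capped at E_Hp)?
#   repro     "none", "buffer" (pR -> ER), "excess" (pC - pS - pJ -> ER)
#   at_entry  optional function(ctx, y) -> list(ctx, y) state adjustment

stage_plan <- function(model, p) {
  lbl <- model$label
  st <- function(name, event, end, assim = TRUE, f_name = "f", sM = "iso",
                 growth = "normal", maturing = TRUE, repro = "none",
                 at_entry = NULL) {
    list(
      name = name, event = event, end = end, assim = assim, f_name = f_name,
      sM = sM, growth = growth, maturing = maturing, repro = repro,
      at_entry = at_entry
    )
  }
  mat <- function(v) list(type = "maturity", value = v)
  dur <- function(v) list(type = "duration", value = v)
  rjd <- function(v) list(type = "repro_density", value = v)
  none <- list(type = "none")

  embryo <- st("embryo", "b", mat(p$E_Hb), assim = FALSE)
  fetus <- st("fetus", "b", mat(p$E_Hb), assim = FALSE, growth = "fetal")
  adult <- st("adult", NA, none, repro = "buffer", maturing = FALSE)
  adult_ng <- st("adult", NA, none, repro = "excess", maturing = FALSE, growth = "none")
  juvenile <- function(to = p$E_Hp, event = "p", sM = "iso") {
    st("juvenile", event, mat(to), sM = sM)
  }

  switch(lbl,
    std = list(embryo, juvenile(), adult),
    stf = list(fetus, juvenile(), adult),
    stx = list(
      st("preparation", "g", dur(p$t_0), assim = FALSE, growth = "frozen_state", maturing = FALSE),
      fetus,
      st("baby", "x", mat(p$E_Hx), f_name = "f_milk"),
      juvenile(), adult
    ),
    ssj = list(
      embryo,
      st("juvenile", "s", mat(p$E_Hs)),
      st("shrink", "j", dur(p$t_sj), assim = FALSE, growth = "shrink"),
      juvenile(), adult
    ),
    sbp = list(embryo, juvenile(), adult_ng),
    abj = list(
      embryo,
      st("juvenile_acc", "j", mat(p$E_Hj), sM = "accel"),
      juvenile(), adult
    ),
    asj = list(
      embryo,
      st("juvenile", "s", mat(p$E_Hs)),
      st("juvenile_acc", "j", mat(p$E_Hj), sM = "accel"),
      juvenile(), adult
    ),
    abp = list(
      embryo,
      st("juvenile_acc", "p", mat(p$E_Hp), sM = "accel"),
      adult_ng
    ),
    hep = list(
      embryo,
      st("larva", "p", mat(p$E_Hp), sM = "accel"),
      st("larva_adult", "e", rjd(p$E_Rj), repro = "buffer", maturing = FALSE),
      st("imago", NA, none, assim = FALSE, growth = "none", maturing = FALSE)
    ),
    hex = list(
      embryo,
      st("larva", "j", rjd(p$E_Rj), sM = "accel", maturing = FALSE, repro = "buffer"),
      st("pupa", "e", mat(p$E_Hp), assim = FALSE, at_entry = pupate),
      st("imago", NA, none, assim = FALSE, growth = "none", maturing = FALSE)
    )
  )
}

# hex pupation: larval structure converts to pupal reserve at efficiency
# kap_V (of the [E_G]-energy held in structure); the reproduction buffer is
# carried over unchanged; maturity resets and re-develops
pupate <- function(ctx, y, p) {
  y["E"] <- y["E"] + p$kap_V * p$E_G * y["L"]^3
  y["L"] <- ctx$L0
  y["EH"] <- 0
  ctx$sM_base <- ctx$sM_base # frozen at the larval ratio
  list(ctx = ctx, y = y)
}

# model-specific validity checks for thresholds used by the plan
validate_model_params <- function(p, model) {
  need <- switch(model$label,
    stx = c("E_Hx"), ssj = c("E_Hs"), abj = c("E_Hj"), asj = c("E_Hs", "E_Hj"),
    hep = c("E_Rj"), hex = c("E_Rj"),
    character(0)
  )
  for (nm in need) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("model ", model$label, " requires positive `", nm, "`", call. = FALSE)
    }
  }
  invisible(p)
}
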