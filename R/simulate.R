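# Life-cycle integration: a stage machine over the typified model family.
# States: E (reserve, J), L (structural length, cm), EH (maturity, J),
# ER (reproduction buffer, J), q (aging acceleration, 1/d^2), h (hazard, 1/d),
# S (survival, -), SC (integral of S, d; expected lifespan at death).

#' Initial reserve of an egg
#'
#' Solves the initial-value problem of embryo development: the reserve energy
#' `E0` an egg must start with so that, when maturity reaches the birth
#' threshold `E_Hb`, the scaled reserve density `e = E/(L^3 E_m)` equals the
#' target `f` (the food level experienced by the mother). Found by bisection
#' on `E0` over repeated embryo integrations; the result is deterministic.
#'
#' @param p a [deb_params()] object.
#' @param f target scaled reserve density at birth, in `(0, 1]`.
#' @param T_K body temperature (K); affects the age at birth, not `E0`.
#' @param rtol,atol integration tolerances.
#' @return a list with `E0` (J), `a_b` (age at birth, d), `L_b` (length at
#'   birth, cm).
#' @export
#' @examples
#' initial_reserve(deb_params(), f = 1)
initial_reserve <- function(p, f = 1, T_K = p$T_ref, rtol = 1e-8, atol = 1e-10) {
  validate_deb_params(p)
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
    stop("`f` must lie in (0, 1]", call. = FALSE)
  }
  pT <- params_at_temp(p, T_K)
  E_m <- pT$p_Am / pT$v
  L_m <- pT$kap * pT$p_Am / pT$p_M
  k_M <- pT$p_M / pT$E_G
  L0 <- 1e-5 * L_m
  horizon <- 500 / k_M

  shoot <- function(E0) {
    out <- embryo_ode(E0, L0, pT, rtol, atol, horizon)
    if (!out$reached) {
      return(list(gap = -f, out = out))
    }
    e_b <- out$E / (out$L^3 * E_m)
    list(gap = e_b - f, out = out)
  }

  # bracket E0: scaled reserve density at birth increases with E0
  E_lo <- max(p$E_Hb / (1 - p$kap), 1e-8)
  E_hi <- E_lo
  s_hi <- shoot(E_hi)
  n <- 0
  while (s_hi$gap < 0 && n < 80) {
    E_hi <- E_hi * 2
    s_hi <- shoot(E_hi)
    n <- n + 1
  }
  if (s_hi$gap < 0) {
    stop("birth unreachable: maintenance exceeds mobilization before E_Hb", call. = FALSE)
  }
  s_lo <- shoot(E_lo)
  n <- 0
  while (s_lo$gap > 0 && n < 80) {
    E_lo <- E_lo / 2
    s_lo <- shoot(E_lo)
    n <- n + 1
  }
  root <- stats::uniroot(function(x) shoot(x)$gap,
    lower = E_lo, upper = E_hi,
    f.lower = s_lo$gap, f.upper = s_hi$gap,
    tol = max(1e-12, 1e-9 * E_hi)
  )
  fin <- shoot(root$root)
  list(E0 = root$root, a_b = fin$out$t, L_b = fin$out$L)
}

# integrate the embryo system (E, L, EH) until EH = E_Hb, or until maturation
# stalls (birth unreachable); compiled dynamics
embryo_ode <- function(E0, L0, pT, rtol, atol, horizon) {
  E_Hb <- pT$E_Hb
  parms <- c(pT$p_Am, pT$v, pT$kap, pT$p_M, pT$p_T, pT$k_J, pT$E_G, pT$E_Hb)
  out <- deSolve::lsodar(
    y = c(E0, L0, 0), times = c(0, horizon),
    func = "embryo_deriv", parms = parms, dllname = "debfit",
    initfunc = "embryo_init", rootfunc = "embryo_root", nroot = 2L,
    rtol = rtol, atol = atol
  )
  last <- out[nrow(out), ]
  reached <- last[[4]] >= E_Hb * (1 - 1e-6)
  list(reached = reached, t = last[[1]], E = last[[2]], L = last[[3]], EH = last[[4]])
}

# fetal embryo (stf/stx): structural growth unconstrained by reserve,
# dL/dt = v/3; maturation driven by fluxes evaluated at e = 1
fetal_birth <- function(p, f = 1, T_K = p$T_ref, rtol = 1e-8, atol = 1e-10) {
  pT <- params_at_temp(p, T_K)
  E_m <- pT$p_Am / pT$v
  derivs <- function(t, y, parms) {
    L <- y[1]
    EH <- y[2]
    pS <- pT$p_M * L^3 + pT$p_T * L^2
    pC <- E_m * (pT$E_G * pT$v * L^2 + pS) / (pT$E_G + pT$kap * E_m)
    list(c(pT$v / 3, max(0, (1 - pT$kap) * pC - pT$k_J * EH)))
  }
  root <- function(t, y, parms) y[2] - pT$E_Hb
  k_M <- pT$p_M / pT$E_G
  out <- deSolve::lsodar(
    y = c(1e-9, 0), times = c(0, 500 / k_M), func = derivs, parms = NULL,
    rootfunc = root, rtol = rtol, atol = atol
  )
  last <- out[nrow(out), ]
  if (last[[3]] < pT$E_Hb * (1 - 1e-6)) stop("fetal birth unreachable", call. = FALSE)
  L_b <- last[[2]]
  E_b <- f * E_m * L_b^3
  list(
    a_b = last[[1]], L_b = L_b, E_b = E_b,
    E0 = E_b + pT$E_G * L_b^3 + pT$E_Hb
  )
}

#' Integrate a DEB life cycle
#'
#' Integrates the coupled reserve-structure-maturity-reproduction-aging system
#' from the start of embryo development to death (or a horizon), switching
#' stage dynamics at maturity thresholds, stage durations and
#' reproduction-buffer density thresholds according to the typified model.
#' Events are located by root-finding during integration.
#'
#' @param p a [deb_params()] object.
#' @param model a [deb_model()]; defaults to the standard model.
#' @param f scaled functional response: a scalar in `[0, 1]` or a function of
#'   time (d).
#' @param T_K body temperature (K); all rate parameters are Arrhenius-corrected
#'   before integration.
#' @param horizon maximum age (d); default `1e5` days divided by the
#'   temperature correction factor.
#' @param times optional extra output times (d) merged into the output grid.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param S_floor survival probability at which the simulation stops and death
#'   by aging is recorded.
#' @return A tibble of class `deb_trajectory` with columns `t`, `E`, `L`,
#'   `EH`, `ER`, `q`, `h`, `S`, `SC`, `stage`, `sM`, `f` and the energy fluxes
#'   (`pA`, `pX`, `pC`, `pS`, `pJ`, `pG`, `pR`). Attributes: `schedule` (the
#'   stage-event tibble: `event`, `age`, `L`, `EH`, `reached`), `params`,
#'   `model`, `E0`, `starved`.
#' @export
#' @examples
#' tr <- integrate_life_cycle(deb_params(), deb_model("std"), f = 1)
#' attr(tr, "schedule")
integrate_life_cycle <- function(p, model = deb_model("std"), f = 1,
                                 T_K = p$T_ref, horizon = NULL, times = NULL,
                                 rtol = 1e-8, atol = 1e-10, S_floor = 1e-6) {
  validate_deb_params(p, model)
  validate_model_params(p, model)
  tc <- temp_correction(T_K, p)
  pT <- params_at_temp(p, T_K)
  E_m <- pT$p_Am / pT$v
  L_m <- pT$kap * pT$p_Am / pT$p_M
  if (is.null(horizon)) horizon <- 1e5 / tc
  f_fun <- if (is.function(f)) f else function(t) f
  f0 <- f_fun(0)
  if (!is.finite(f0) || f0 < 0 || f0 > 1) stop("`f` must lie in [0, 1]", call. = FALSE)

  plan <- stage_plan(model, pT)
  L0 <- 1e-5 * L_m

  # initial state
  if (plan[[1]]$name %in% c("fetus", "preparation")) {
    E0 <- NA_real_ # maternal supply; embryo cost accounted at birth
    y <- c(E = E_m * L0^3, L = L0, EH = 0, ER = 0, q = 0, h = 0, S = 1, SC = 0)
  } else {
    ir <- initial_reserve(p, f = min(1, max(f0, 1e-3)), T_K = T_K, rtol = rtol, atol = atol)
    E0 <- ir$E0
    y <- c(E = E0, L = L0, EH = 0, ER = 0, q = 0, h = 0, S = 1, SC = 0)
  }

  grid <- sort(unique(c(
    seq(0, horizon, length.out = 300),
    exp(seq(log(max(horizon * 1e-7, 1e-4)), log(horizon), length.out = 250)),
    times[times >= 0 & times <= horizon]
  )))

  ctx <- list(sM_base = 1, L_ref = NA_real_, t_entry = 0, L0 = L0)
  t_cur <- 0
  rows <- list()
  events <- list()
  died <- FALSE
  death_age <- NA_real_

  for (k in seq_along(plan)) {
    stg <- plan[[k]]

    # stage-entry bookkeeping
    if (!is.null(stg$at_entry)) {
      adj <- stg$at_entry(ctx, y, pT)
      ctx <- adj$ctx
      y <- adj$y
    }
    if (stg$sM == "accel") ctx$L_ref <- unname(y["L"])
    ctx$t_entry <- t_cur

    fd <- make_stage_derivs(stg, ctx, pT, E_m, L_m, f_fun, S_floor,
      f_const = if (is.function(f)) NULL else f
    )

    # end condition already satisfied at entry -> zero-length stage
    end_now <- switch(stg$end$type,
      maturity = y["EH"] >= stg$end$value - 1e-12,
      duration = stg$end$value <= 0,
      repro_density = y["ER"] >= stg$end$value * y["L"]^3,
      none = FALSE
    )
    if (isTRUE(end_now)) {
      events[[length(events) + 1]] <- list(
        event = stg$event, age = t_cur,
        L = unname(y["L"]), EH = unname(y["EH"]), reached = TRUE
      )
      if (stg$sM == "accel") { # degenerate window: ratio 1
        ctx$sM_base <- max(1, unname(y["L"]) / ctx$L_ref)
      }
      next
    }

    tt <- c(t_cur, grid[grid > t_cur + 1e-12 & grid <= horizon])
    if (length(tt) < 2) tt <- c(t_cur, horizon)
    if (tt[length(tt)] < horizon) tt <- c(tt, horizon)

    out <- if (is.null(fd$parms)) {
      deSolve::lsodar(
        y = y, times = tt, func = fd$derivs, parms = NULL,
        rootfunc = fd$root, rtol = rtol, atol = atol, maxsteps = 1e5
      )
    } else {
      deSolve::lsodar(
        y = y, times = tt, func = "stage_deriv", parms = fd$parms,
        dllname = "debfit", initfunc = "stage_init",
        rootfunc = "stage_root", nroot = 3L,
        rtol = rtol, atol = atol, maxsteps = 1e5
      )
    }
    out <- as.data.frame(out)
    names(out) <- c("t", "E", "L", "EH", "ER", "q", "h", "S", "SC")
    n <- nrow(out)
    yend <- unlist(out[n, -1])
    t_end <- out$t[n]

    out$stage <- stg$name
    out$sM <- fd$sM_of(out$L, out$EH)
    out$f <- ifelse(rep(stg$assim, n), vapply(out$t, fd$f_eff, numeric(1)), 0)
    rows[[length(rows) + 1]] <- out

    y <- c(
      E = yend[["E"]], L = yend[["L"]], EH = yend[["EH"]], ER = yend[["ER"]],
      q = yend[["q"]], h = yend[["h"]], S = yend[["S"]], SC = yend[["SC"]]
    )
    t_cur <- t_end

    # identify why integration stopped
    ended <- switch(stg$end$type,
      maturity = y["EH"] >= stg$end$value * (1 - 1e-8),
      duration = t_end >= ctx$t_entry + stg$end$value - 1e-9,
      repro_density = y["ER"] >= stg$end$value * y["L"]^3 * (1 - 1e-8),
      none = FALSE
    )
    # reserve exhaustion judged relative to body size (imago/non-feeding stages)
    dead <- (y["S"] <= S_floor * (1 + 1e-6)) ||
      (y["E"] <= 1.01e-9 * E_m * y["L"]^3)

    if (isTRUE(ended)) {
      events[[length(events) + 1]] <- list(
        event = stg$event, age = t_end,
        L = unname(y["L"]), EH = unname(y["EH"]), reached = TRUE
      )
      if (!is.null(stg$at_exit)) y <- stg$at_exit(y)
      if (stg$name == "fetus") { # reserve density at birth set to f
        y["E"] <- f_fun(t_end) * E_m * y["L"]^3
      }
      if (stg$sM == "accel") ctx$sM_base <- max(1, unname(y["L"]) / ctx$L_ref)
      if (dead) {
        died <- TRUE
        death_age <- t_end
        break
      }
    } else if (dead || t_end >= horizon * (1 - 1e-12)) {
      if (dead) {
        died <- TRUE
        death_age <- t_end
      }
      # remaining events unreached
      for (kk in k:length(plan)) {
        ev <- plan[[kk]]$event
        if (!is.na(ev)) {
          events[[length(events) + 1]] <- list(
            event = ev, age = NA_real_, L = NA_real_, EH = NA_real_, reached = FALSE
          )
        }
      }
      break
    } else {
      stop("integration stalled in stage ", stg$name, " (non-finite state?)", call. = FALSE)
    }
  }

  events[[length(events) + 1]] <- list(
    event = "death", age = death_age, L = unname(y["L"]),
    EH = unname(y["EH"]), reached = died
  )

  traj <- dplyr::bind_rows(rows)
  traj <- traj[!duplicated(traj[c("t", "E", "L", "EH", "ER")]), , drop = FALSE]
  fl <- deb_fluxes(traj, f = traj$f, sM = traj$sM, p = pT)
  # starvation: growth flux negative (or mobilization short of maintenance)
  # outside the stages where that is part of the stage's own rule
  ok_neg <- traj$stage %in% c("shrink", "imago", "preparation", "fetus")
  starved <- any((fl$pG < -1e-12 | fl$pG + fl$pR < -1e-12) & !ok_neg)
  traj <- dplyr::bind_cols(traj, fl[, c("pA", "pX", "pC", "pS", "pJ", "pG", "pR")])
  # the imago mobilizes reserve to match constant maintenance (no kappa-rule)
  im <- traj$stage == "imago"
  if (any(im)) {
    traj$pC[im] <- traj$pS[im] + traj$pJ[im]
    traj$pG[im] <- 0
    traj$pR[im] <- 0
  }
  schedule <- dplyr::bind_rows(lapply(events, tibble::as_tibble))

  structure(
    tibble::as_tibble(traj),
    class = c("deb_trajectory", class(tibble::tibble())),
    schedule = schedule, params = p, model = model, T_K = T_K,
    E0 = E0, starved = starved
  )
}

# closure factory: stage dynamics + root function + sM accessor; when the
# functional response is constant the compiled dynamics are used instead of
# the R closures (identical formulation, see src/debfit.c)
make_stage_derivs <- function(stg, ctx, pT, E_m, L_m, f_fun, S_floor = 1e-6,
                              f_const = NULL) {
  imago <- identical(stg$name, "imago")
  sM_of <- function(L, EH) {
    if (stg$sM == "accel") pmax(1, ctx$sM_base * L / ctx$L_ref) else rep(ctx$sM_base, length(L))
  }
  f_eff <- function(t) if (stg$assim) {
    if (stg$f_name == "f_milk") pT$f_milk else f_fun(t)
  } else 0

  parms <- NULL
  if (!is.null(f_const)) {
    fv <- if (stg$f_name == "f_milk") pT$f_milk else f_const
    parms <- c(
      as.numeric(stg$assim), fv,
      as.numeric(stg$sM == "accel"), ctx$sM_base,
      if (is.na(ctx$L_ref)) 1 else ctx$L_ref,
      match(stg$growth, c("normal", "none", "shrink", "fetal", "frozen_state")) - 1,
      as.numeric(stg$maturing),
      match(stg$repro, c("none", "buffer", "excess")) - 1,
      as.numeric(imago), ctx$t_entry,
      match(stg$end$type, c("maturity", "duration", "repro_density", "none")) - 1,
      if (stg$end$type == "none") 0 else stg$end$value,
      S_floor,
      pT$p_Am, pT$v, pT$kap, pT$p_M, pT$p_T, pT$k_J, pT$E_G, pT$E_Hb,
      pT$E_Hp, pT$s_G, pT$h_a, pT$kap_shrink, E_m, L_m
    )
  }

  derivs <- function(t, y, parms) {
    E <- y[1]; L <- y[2]; EH <- y[3]; ER <- y[4]
    q <- y[5]; h <- y[6]; S <- y[7]
    sM <- if (stg$sM == "accel") max(1, ctx$sM_base * L / ctx$L_ref) else ctx$sM_base
    fv <- f_eff(t)
    pA <- if (stg$assim) pT$p_Am * fv * sM * L^2 else 0
    pS <- pT$p_M * L^3 + pT$p_T * sM * L^2
    pJ <- pT$k_J * min(EH, pT$E_Hp)
    pC <- E * (pT$E_G * pT$v * sM * L^2 + pS) / (pT$E_G * L^3 + pT$kap * E)
    pG <- pT$kap * pC - pS
    pR <- (1 - pT$kap) * pC - pJ

    if (imago) { # mobilization matches constant (somatic + maturity) maintenance
      dE <- -(pS + pJ)
      dL <- 0; r <- 0
      dEH <- 0; dER <- 0
    } else {
      dE <- switch(stg$growth,
        fetal = 3 * E_m * L^2 * (pT$v * sM / 3),
        frozen_state = 0,
        pA - pC
      )
      gr <- switch(stg$growth,
        normal = pG / (3 * pT$E_G * L^2),
        fetal = pT$v * sM / 3,
        none = 0,
        frozen_state = 0,
        shrink = if (pG >= 0) 0 else pG / (3 * pT$kap_shrink * pT$E_G * L^2)
      )
      dL <- gr
      r <- 3 * dL / L
      dEH <- if (stg$maturing && EH < pT$E_Hp) max(0, pR) else 0
      dER <- switch(stg$repro,
        none = 0,
        buffer = max(0, pR),
        excess = max(0, pC - pS - pJ)
      )
    }
    if (stg$growth == "frozen_state") {
      dq <- 0; dh <- 0; dS <- 0
    } else {
      e <- E / (L^3 * E_m)
      sMq <- if (stg$sM == "accel") max(1, ctx$sM_base * L / ctx$L_ref) else ctx$sM_base
      dq <- (q * (L^3 / L_m^3) * pT$s_G + pT$h_a) * e * (pT$v * sMq / L - r) - r * q
      dh <- q - r * h
      dS <- -h * S
    }
    list(c(dE, dL, dEH, dER, dq, dh, dS, S))
  }

  root <- function(t, y, parms) {
    end <- switch(stg$end$type,
      maturity = y[3] - stg$end$value,
      duration = t - (ctx$t_entry + stg$end$value),
      repro_density = y[4] - stg$end$value * y[2]^3,
      none = 1
    )
    c(end, y[7] - S_floor, y[1] - 1e-9 * E_m * y[2]^3)
  }

  list(derivs = derivs, root = root, sM_of = sM_of, f_eff = f_eff, parms = parms)
}

#' @export
print.deb_trajectory <- function(x, ...) {
  sched <- attr(x, "schedule")
  cat("<deb_trajectory> model", attr(x, "model")$label,
      "|", nrow(x), "time points\n")
  NextMethod()
  invisible(x)
}
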