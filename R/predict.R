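# Prediction rules: map each standardized dataset label to model predictions.
# Zero-variate predictions come from the implied properties at the datum's
# temperature; uni-variate predictions from the life-cycle trajectory under
# the dataset's food level, with times Arrhenius-scaled to the reference
# temperature. Additional rules can be registered for bespoke labels.

.prediction_registry <- new.env(parent = emptyenv())

#' Register a prediction rule for a dataset label
#'
#' Extension point for data types beyond the built-in vocabulary. The rule
#' receives the entry, the parameter set, the dataset (a one-row zero-variate
#' tibble or a uni-variate list) and a simulation cache, and must return a
#' numeric vector congruent with the dataset values.
#'
#' @param label base dataset label.
#' @param fn function `(entry, params, dataset, cache) -> numeric`.
#' @export
register_prediction <- function(label, fn) {
  assign(label, fn, envir = .prediction_registry)
  invisible(label)
}

# zero-variate label -> implied property and its time dimension
# (times divide by the Arrhenius factor, rates multiply)
zero_variate_map <- function() {
  tibble::tribble(
    ~label, ~property, ~dim,
    "ab", "a_b", "time",
    "aj", "a_j", "time",
    "ap", "a_p", "time",
    "am", "a_m", "time",
    "Lb", "L_b", "none",
    "Lj", "L_j", "none",
    "Lp", "L_p", "none",
    "Li", "L_i", "none",
    "Wwb", "Ww_b", "none",
    "Wwp", "Ww_p", "none",
    "Wwi", "Ww_i", "none",
    "Ri", "R_i", "rate",
    "E0", "E0", "none"
  )
}

# per-food-level simulation cache: sims are run at the reference temperature
# and shared between all datasets with the same food level
sim_cache <- function(p, model, chem) {
  cache <- new.env(parent = emptyenv())
  cache$p <- p
  cache$model <- model
  cache$chem <- chem
  cache$sims <- list()
  cache$times <- list()
  cache
}

cache_request_times <- function(cache, f, times) {
  key <- sprintf("%.12g", f)
  cache$times[[key]] <- c(cache$times[[key]], times)
  invisible(cache)
}

cache_sim <- function(cache, f) {
  key <- sprintf("%.12g", f)
  if (is.null(cache$sims[[key]])) {
    sim <- integrate_life_cycle(
      cache$p, cache$model,
      f = f, T_K = cache$p$T_ref,
      times = sort(unique(cache$times[[key]]))
    )
    props <- implied_properties(
      cache$p, cache$model,
      f = f, T_K = cache$p$T_ref,
      chem = cache$chem, sim = sim
    )
    cache$sims[[key]] <- list(sim = sim, props = props)
  }
  cache$sims[[key]]
}

#' Predict every dataset of an entry
#'
#' Computes model predictions aligned with all of the entry's datasets at the
#' given parameter values: zero-variate predictions from the implied
#' properties evaluated at each datum's temperature, uni-variate predictions
#' from the life-cycle trajectory under the dataset's constant food level.
#' Predictions requiring an unreached life stage are `NA` (the estimation
#' objective converts these into a large penalty).
#'
#' @param entry a [deb_entry()].
#' @param p a [deb_params()] object; defaults to the entry's parameters.
#' @param chem a [chemical_params()] object.
#' @return a long tibble with columns `set`, `type`, `j`, `x`, `data`, `pred`,
#'   `weight` (automatic `1/n_i` weights times the entry multipliers).
#' @export
predict_entry <- function(entry, p = entry$params, chem = chemical_params()) {
  validate_deb_params(p, entry$model)
  cache <- sim_cache(p, entry$model, chem)
  zmap <- zero_variate_map()
  pT_ref <- p # properties computed at reference temperature

  # pre-register output times needed by time-series datasets
  ab_at <- function(f) {
    if (entry$model$label %in% c("stf", "stx")) {
      fetal_birth(p, f = f)$a_b
    } else {
      initial_reserve(p, f = f)$a_b
    }
  }
  ab_cache <- list()
  for (ds in entry$uni_variate) {
    base <- sub("_.*$", "", ds$label)
    if (base %in% c("tL", "tW")) {
      key <- sprintf("%.12g", ds$f)
      if (is.null(ab_cache[[key]])) ab_cache[[key]] <- ab_at(ds$f)
      tc <- temp_correction(ds$temp_K, p)
      cache_request_times(cache, ds$f, ab_cache[[key]] + ds$x * tc)
    }
  }

  out <- list()
  zv <- entry$zero_variate
  if (nrow(zv)) {
    preds <- numeric(nrow(zv))
    for (i in seq_len(nrow(zv))) {
      lab <- zv$label[i]
      cs <- cache_sim(cache, zv$f[i])
      m <- zmap[zmap$label == lab, ]
      val <- cs$props$value[cs$props$property == m$property]
      tc <- temp_correction(zv$temp_K[i], p)
      preds[i] <- switch(m$dim,
        time = val / tc,
        rate = val * tc,
        none = val
      )
    }
    out[[1]] <- tibble::tibble(
      set = zv$label, type = "zero", j = 1L, x = NA_real_,
      data = zv$value, pred = preds, weight = zv$weight
    )
  }

  for (ds in entry$uni_variate) {
    base <- sub("_.*$", "", ds$label)
    tc <- temp_correction(ds$temp_K, p)
    n <- length(ds$x)
    pred <- if (!is.null(.prediction_registry[[base]])) {
      .prediction_registry[[base]](entry, p, ds, cache)
    } else if (base %in% c("tL", "tW")) {
      cs <- cache_sim(cache, ds$f)
      key <- sprintf("%.12g", ds$f)
      tt <- ab_cache[[key]] + ds$x * tc
      sim <- cs$sim
      idx <- vapply(tt, function(t0) which.min(abs(sim$t - t0)), integer(1))
      miss <- abs(sim$t[idx] - tt) > pmax(1e-6 * pmax(tt, 1), 1e-8)
      if (base == "tL") {
        v <- sim$L[idx]
      } else {
        v <- wet_weight(sim$L[idx], sim$E[idx], chem)
      }
      v[miss] <- NA_real_ # beyond death or horizon
      v
    } else if (base == "LN") {
      cs <- cache_sim(cache, ds$f)
      repro_rate_at_length(ds$x, p, entry$model, ds$f, cs) * tc
    } else {
      stop("no prediction rule for dataset label '", ds$label, "'", call. = FALSE)
    }
    out[[length(out) + 1]] <- tibble::tibble(
      set = ds$label, type = "uni", j = seq_len(n), x = ds$x,
      data = ds$y, pred = pred, weight = ds$weight / n
    )
  }
  dplyr::bind_rows(out)
}

# reproduction rate (offspring per day) as a function of structural length,
# at constant scaled reserve density e = f
repro_rate_at_length <- function(L, p, model, f, cs) {
  sched <- attr(cs$sim, "schedule")
  if (!any(sched$event == "p" & sched$reached)) {
    return(rep(NA_real_, length(L)))
  }
  s_M <- acceleration_factor(sched, model)$factor
  if (is.na(s_M)) s_M <- 1
  E0 <- cs$props$value[cs$props$property == "E0"]
  if (is.na(E0)) {
    return(rep(NA_real_, length(L)))
  }
  E_m <- p$p_Am / p$v
  E <- f * E_m * L^3
  pS <- p$p_M * L^3 + p$p_T * s_M * L^2
  pC <- E * (p$E_G * p$v * s_M * L^2 + pS) / (p$E_G * L^3 + p$kap * E)
  if (model$label %in% c("sbp", "abp")) {
    pR <- pC - pS - p$k_J * p$E_Hp
  } else {
    pR <- (1 - p$kap) * pC - p$k_J * p$E_Hp
  }
  pmax(0, p$kap_R * pR / E0)
}
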