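# Estimation in context: filtered simplex over transformed free parameters,
# with pseudo-data priors and continuation rounds.

# free parameters are searched on a log scale, fractions on a logit scale,
# which keeps positivity and fraction bounds by construction (the filter is
# still enforced for the remaining constraints)
fraction_params <- function() c("kap", "kap_R", "kap_X", "kap_V", "kap_shrink")

par_transform <- function(p, free) {
  vapply(free, function(nm) {
    v <- p[[nm]]
    if (nm %in% fraction_params()) log(v / (1 - v)) else log(v)
  }, numeric(1))
}

par_untransform <- function(x, free, template) {
  p <- template
  x <- unname(x)
  for (i in seq_along(free)) {
    nm <- free[i]
    p[[nm]] <- if (nm %in% fraction_params()) 1 / (1 + exp(-x[i])) else exp(x[i])
  }
  p
}

# objective over the transformed free-parameter vector; unreachable-stage
# predictions are replaced by a penalty of 10x the worst feasible loss seen
make_objective <- function(entry, template, free, loss_kind, chem, state) {
  pseudo_tbl <- if (entry$pseudo) pseudo_data(loss_kind) else NULL
  function(x) {
    p <- par_untransform(x, free, template)
    df <- tryCatch(
      predict_entry(entry, p, chem = chem),
      error = function(e) NULL
    )
    if (is.null(df)) {
      return(10 * state$worst)
    }
    if (!is.null(pseudo_tbl)) {
      pp <- pseudo_predictions(p, chem)
      df <- dplyr::bind_rows(
        df[, c("set", "data", "pred", "weight")],
        tibble::tibble(
          set = paste0("psd_", pseudo_tbl$label),
          data = pseudo_tbl$value,
          pred = unname(pp[pseudo_tbl$label]),
          weight = pseudo_tbl$weight
        )
      )
    }
    if (anyNA(df$pred)) {
      return(10 * state$worst * (1 + mean(is.na(df$pred))))
    }
    val <- deb_loss_core(df, loss_kind)
    if (is.finite(val) && val > state$worst) state$worst <- val
    val
  }
}

# loss evaluation without the deprecation warning (used in the hot loop)
deb_loss_core <- function(df, kind) {
  withCallingHandlers(
    deb_loss(df, kind),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Estimate DEB parameters for an entry
#'
#' Minimizes the selected loss function over the entry's free parameters with
#' the feasibility-filtered Nelder-Mead simplex, run in continuation rounds:
#' each round restarts from the current best point with a re-inflated simplex,
#' which converges much faster than one long run and reduces the risk of
#' stalling in a prematurely shrunken simplex. Pseudo-data (generalized-animal
#' priors) are included unless the entry disables them. The loss trace is
#' non-increasing across rounds since the best vertex is carried over.
#'
#' @param entry a [deb_entry()].
#' @param init initial [deb_params()]; defaults to the entry's parameters.
#'   Must pass [filter_check()]. The `free` attribute selects what is
#'   estimated.
#' @param options an [estimation_options()] list; defaults to the entry's.
#' @param chem a [chemical_params()] object.
#' @return an object of class `deb_fit`: list with `params` (estimates),
#'   `init`, `loss` (final value), `trace` (per-round tibble), `report` (a
#'   [fit_metrics()] report on the real data), `entry`, `options`,
#'   `diagnostics` (objective/filter call counts).
#' @export
estimate <- function(entry, init = entry$params, options = entry$options,
                     chem = chemical_params()) {
  model <- entry$model
  free <- attr(init, "free")
  if (!length(free)) stop("no free parameters to estimate", call. = FALSE)
  if (options$loss == "re") {
    warning("loss 're' is deprecated and retained for historical context; 'sb' is recommended",
      call. = FALSE
    )
  }
  flt <- filter_check(init, model)
  if (!flt$pass) {
    stop("initial parameters fail the filter: ", paste(flt$reasons, collapse = "; "),
      call. = FALSE
    )
  }
  # every dataset label must have a prediction rule
  base_labs <- unique(sub("_.*$", "", vapply(entry$uni_variate, function(d) d$label, character(1))))
  known <- c(names(uni_units()), ls(.prediction_registry))
  bad <- setdiff(base_labs, known)
  if (length(bad)) {
    stop("no prediction rule for dataset label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  state <- new.env(parent = emptyenv())
  state$worst <- 1
  obj <- make_objective(entry, init, free, options$loss, chem, state)
  filt <- function(x) filter_check(par_untransform(x, free, init), model)

  x <- par_transform(init, free)
  trace <- list()
  total_obj <- 0L
  total_rej <- 0L
  res <- NULL
  for (round in seq_len(options$continuations)) {
    res <- nelder_mead_filtered(
      obj, x,
      filter = filt, max_steps = options$steps,
      tol_f = options$tol_f, tol_x = options$tol_x
    )
    x <- res$par
    total_obj <- total_obj + res$n_obj
    total_rej <- total_rej + res$n_filter_fail
    trace[[round]] <- tibble::tibble(
      round = round, loss = res$value, steps = res$steps,
      converged = res$converged
    )
  }
  best <- par_untransform(x, free, init)
  attr(best, "free") <- free

  df <- predict_entry(entry, best, chem = chem)
  report <- fit_metrics(df[, c("set", "data", "pred", "weight")])

  structure(
    list(
      params = best, init = init, loss = res$value,
      trace = dplyr::bind_rows(trace), report = report,
      entry = entry, options = options,
      diagnostics = list(n_obj = total_obj, n_filter_fail = total_rej)
    ),
    class = "deb_fit"
  )
}

#' @export
print.deb_fit <- function(x, ...) {
  cat(
    "<deb_fit>", x$entry$species, "| model", x$entry$model$label,
    "| loss", signif(x$loss, 5),
    "| MRE", signif(attr(x$report, "MRE"), 4),
    "| SMSE", signif(attr(x$report, "SMSE"), 4), "\n"
  )
  invisible(x)
}

#' Tidy a fitted DEB estimation
#'
#' @param x a `deb_fit` object.
#' @param ... unused.
#' @return tibble with `parameter`, `units`, `init`, `estimate`, `free`.
#' @export
tidy.deb_fit <- function(x, ...) {
  units <- deb_param_units()
  nm <- names(unclass(x$params))
  tibble::tibble(
    parameter = nm,
    units = unname(units[nm]),
    init = unlist(unclass(x$init), use.names = FALSE),
    estimate = unlist(unclass(x$params), use.names = FALSE),
    free = nm %in% attr(x$params, "free")
  )
}

#' Glance at a fitted DEB estimation
#' @param x a `deb_fit` object.
#' @param ... unused.
#' @return one-row tibble: `loss`, `MRE`, `SMSE`, `n_sets`, `rounds`,
#'   `n_obj`, `converged`.
#' @export
glance.deb_fit <- function(x, ...) {
  tibble::tibble(
    loss = x$loss,
    MRE = attr(x$report, "MRE"),
    SMSE = attr(x$report, "SMSE"),
    n_sets = attr(x$report, "n_sets"),
    rounds = nrow(x$trace),
    n_obj = x$diagnostics$n_obj,
    converged = x$trace$converged[nrow(x$trace)]
  )
}

#' Persist / restore estimation results
#'
#' Saves the estimated parameters (with units and free flags) and the loss
#' trace as a YAML file; reading returns a parameter set usable as a new seed
#' for [estimate()].
#'
#' @param fit a `deb_fit`.
#' @param path file path.
#' @return `write_fit()` the path, invisibly; `read_fit_params()` a
#'   [deb_params()] object.
#' @export
write_fit <- function(fit, path) {
  units <- deb_param_units()
  nm <- names(unclass(fit$params))
  pars <- lapply(nm, function(n) {
    v <- fit$params[[n]]
    list(
      value = if (is.na(v)) NULL else v, units = unname(units[[n]]),
      free = n %in% attr(fit$params, "free")
    )
  })
  names(pars) <- nm
  yaml::write_yaml(list(
    species = fit$entry$species,
    loss_kind = fit$options$loss,
    loss = fit$loss,
    MRE = attr(fit$report, "MRE"),
    SMSE = attr(fit$report, "SMSE"),
    trace = lapply(seq_len(nrow(fit$trace)), function(i) as.list(fit$trace[i, ])),
    parameters = pars
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit_params <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- lapply(raw$parameters, function(x) if (is.null(x$value)) NA_real_ else x$value)
  free <- names(raw$parameters)[vapply(raw$parameters, function(x) isTRUE(x$free), logical(1))]
  do.call(deb_params, c(vals, list(free = free)))
}

#' Automatic initial parameters from nine zero-variate observations
#'
#' Derives a filter-passing initial parameter set from the nine standard
#' zero-variate data (`ab`, `ap`, `am`, `Lb`, `Lp`, `Li`, `Wwb`, `Wwi`,
#' `Ri`), exploiting the near-bijection between these nine observations and
#' nine primary parameters. The generalized-animal set is first scaled to the
#' observed ultimate length (zoom factor `z = Li/f`), then the free
#' parameters are adjusted by a short filtered-simplex run matching the
#' implied properties to the nine observations. If labels are missing, the
#' zoom-scaled generalized set is returned directly.
#'
#' @param zero_variate tibble as in [deb_entry()] (values at the reference
#'   temperature, or with a `temp_K` column for correction).
#' @param model a [deb_model()].
#' @param steps simplex steps for the matching run.
#' @return a [deb_params()] object passing [filter_check()].
#' @export
auto_init_9 <- function(zero_variate, model = deb_model("std"), steps = 300) {
  need <- c("ab", "ap", "am", "Lb", "Lp", "Li", "Wwb", "Wwi", "Ri")
  zv <- zero_variate
  Li <- zv$value[zv$label == "Li"]
  z <- if (length(Li) == 1 && is.finite(Li) && Li > 0) Li else 1
  base <- deb_params(z = z)
  # extension thresholds needed by the model family, placed within (E_Hb, E_Hp)
  if (model$label %in% c("abj", "asj")) base$E_Hj <- base$E_Hb * 10
  if (model$label %in% c("ssj", "asj")) base$E_Hs <- base$E_Hb * 2
  if (model$label == "stx") base$E_Hx <- base$E_Hb * 5
  if (model$family == "h") base$E_Rj <- 100

  if (!all(need %in% zv$label)) {
    return(base)
  }
  entry <- deb_entry(
    species = "init", model = model, params = base,
    zero_variate = zv[zv$label %in% need, , drop = FALSE]
  )
  free <- c("p_Am", "v", "kap", "p_M", "E_Hb", "E_Hp", "h_a")
  attr(base, "free") <- free
  opts <- estimation_options(loss = "sb", steps = steps, continuations = 1)
  entry$pseudo <- FALSE
  fit <- tryCatch(
    estimate(entry, init = base, options = opts),
    error = function(e) NULL
  )
  out <- if (is.null(fit)) base else fit$params
  if (!filter_check(out, model)$pass) out <- base
  out
}
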