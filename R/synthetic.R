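#' Generate a synthetic species entry from known parameters
#'
#' Builds an entry whose data are the model's own predictions under a known
#' ("true") parameter set, perturbed by multiplicative lognormal noise with a
#' given coefficient of variation. This emulates a typical species entry: the
#' nine standard zero-variate observations (age at birth/puberty, lifespan,
#' lengths at birth/puberty/ultimate, wet weights at birth/ultimate, maximum
#' reproduction rate) plus configurable uni-variate series (time-length,
#' time-weight, length-fecundity). Deterministic for a given seed.
#'
#' The noise multipliers have mean one: `exp(rnorm(0, sdlog) - sdlog^2/2)`
#' with `sdlog^2 = log(1 + cv^2)`.
#'
#' @param true_params the generating [deb_params()] set (must pass the
#'   filter).
#' @param model a [deb_model()].
#' @param design list describing the datasets: `zero_variate` (character
#'   vector of labels), `tL`, `tW`, `LN` (each `NULL` or a list with `n`,
#'   `t_max` (d) or `L_range` (cm), `f`, `temp_K`).
#' @param cv coefficient of variation of the multiplicative noise (0 = exact).
#' @param cv_zero noise level for the zero-variate data; defaults to `cv`.
#'   Zero-variate observations are often known life-history constants, so a
#'   design may hold them exact (`cv_zero = 0`) while the series carry noise.
#' @param seed integer seed.
#' @param species name given to the synthetic species.
#' @param temp_K temperature assigned to the zero-variate data.
#' @return a [deb_entry()] whose `params` are the true values.
#' @export
#' @examples
#' e <- generate_synthetic_entry(deb_params(), cv = 0, seed = 1)
generate_synthetic_entry <- function(true_params, model = deb_model("std"),
                                     design = synthetic_design(), cv = 0.05,
                                     cv_zero = cv,
                                     seed = 1, species = "Synthetica exemplaris",
                                     temp_K = true_params$T_ref) {
  flt <- filter_check(true_params, model)
  if (!flt$pass) {
    stop("true parameters fail the filter: ", paste(flt$reasons, collapse = "; "),
      call. = FALSE
    )
  }
  lu <- label_units()
  zv_labels <- design$zero_variate
  zv <- tibble::tibble(
    label = zv_labels, value = 1, units = unname(lu[zv_labels]),
    temp_K = temp_K, weight = 1, f = 1
  )

  cmp <- compound_parameters(true_params)
  g <- cmp$g
  rB <- cmp$k_M / 3 / (1 + 1 / g)
  uv <- list()
  mk_series <- function(spec, label, units_x, units_y, x) {
    list(
      label = label, x = x, y = rep(1, length(x)),
      units_x = units_x, units_y = units_y,
      temp_K = spec$temp_K %||% temp_K, f = spec$f %||% 1,
      weight = spec$weight %||% 1
    )
  }
  if (!is.null(design$tL)) {
    t_max <- design$tL$t_max %||% (3 / rB)
    uv[[length(uv) + 1]] <- mk_series(
      design$tL, "tL", "d", "cm",
      seq(0, t_max, length.out = design$tL$n %||% 30)
    )
  }
  if (!is.null(design$tW)) {
    t_max <- design$tW$t_max %||% (3 / rB)
    uv[[length(uv) + 1]] <- mk_series(
      design$tW, "tW", "d", "g",
      seq(0, t_max, length.out = design$tW$n %||% 30)
    )
  }
  if (!is.null(design$LN)) {
    Lr <- design$LN$L_range %||% c(0.5, 0.95) * (design$LN$f %||% 1) * cmp$L_m
    uv[[length(uv) + 1]] <- mk_series(
      design$LN, "LN", "cm", "1/d",
      seq(Lr[1], Lr[2], length.out = design$LN$n %||% 10)
    )
  }

  entry <- deb_entry(
    species = species, model = model, params = true_params,
    zero_variate = zv, uni_variate = uv,
    classification = list(phylum = "Synthetica", class = "Simulata"),
    metadata = list(note = "synthetic entry generated from known parameters")
  )
  preds <- predict_entry(entry, true_params)
  if (anyNA(preds$pred)) {
    bad <- unique(preds$set[is.na(preds$pred)])
    stop(
      "design requests stages the model cannot reach (NA predictions): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }

  set.seed(seed)
  cvs <- ifelse(preds$type == "zero", cv_zero, cv)
  sdlog <- sqrt(log(1 + cvs^2))
  noise <- exp(stats::rnorm(nrow(preds), 0, sdlog) - sdlog^2 / 2)
  preds$data <- preds$pred * noise

  # write noisy data back into the entry
  zvi <- preds$type == "zero"
  entry$zero_variate$value <- preds$data[zvi][match(entry$zero_variate$label, preds$set[zvi])]
  for (k in seq_along(entry$uni_variate)) {
    lab <- entry$uni_variate[[k]]$label
    entry$uni_variate[[k]]$y <- preds$data[preds$set == lab]
  }
  validate_entry(entry)
  entry
}

#' Default synthetic design
#'
#' The nine standard zero-variate observations plus a 30-point growth curve,
#' all at the reference temperature and abundant food.
#'
#' @param tL,tW,LN uni-variate dataset specs (lists) or `NULL` to omit.
#' @param zero_variate labels of the zero-variate data to generate.
#' @return a design list for [generate_synthetic_entry()].
#' @export
synthetic_design <- function(tL = list(n = 30), tW = NULL, LN = NULL,
                             zero_variate = c(
                               "ab", "ap", "am", "Lb", "Lp", "Li",
                               "Wwb", "Wwi", "Ri"
                             )) {
  list(zero_variate = zero_variate, tL = tL, tW = tW, LN = LN)
}
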