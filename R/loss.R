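#' Loss functions for multi-dataset estimation
#'
#' Evaluates the weighted loss over a collection of datasets, given data,
#' predictions and weights in long format. Three kinds are supported:
#'
#' * `"sb"` — symmetric bounded (default):
#'   `sum_ij w_ij (d_ij - p_ij)^2 / (dbar_i^2 + pbar_i^2)`;
#' * `"su"` — symmetric unbounded:
#'   `sum_ij w_ij (d_ij - p_ij)^2 (1/dbar_i^2 + 1/pbar_i^2)`;
#' * `"re"` — relative error:
#'   `sum_ij w_ij (d_ij - p_ij)^2 / dbar_i^2` (deprecated; it can drive the
#'   search in the wrong direction even near the optimum and cannot handle
#'   zero-mean datasets).
#'
#' `dbar_i`, `pbar_i` are per-dataset means. `sb` and `su` are symmetric in
#' the roles of data and predictions; `sb` additionally handles data that take
#' the value 0.
#'
#' @param df a data frame with columns `set` (dataset id), `data`, `pred`,
#'   `weight`.
#' @param kind `"sb"`, `"su"` or `"re"`.
#' @return a single non-negative number.
#' @export
#' @examples
#' df <- tibble::tibble(set = "a", data = c(1, 3), pred = c(2, 2), weight = 0.5)
#' deb_loss(df, "sb") # 1/8
deb_loss <- function(df, kind = c("sb", "su", "re")) {
  kind <- match.arg(kind)
  stopifnot(all(c("set", "data", "pred", "weight") %in% names(df)))
  if (any(df$weight < 0)) stop("weights must be non-negative", call. = FALSE)
  if (kind == "re") {
    warning("loss 're' is deprecated; prefer 'sb'", call. = FALSE)
  }
  parts <- split(df[, c("data", "pred", "weight")], df$set)
  total <- 0
  for (s in parts) {
    dbar <- mean(s$data)
    pbar <- mean(s$pred)
    names(s) <- c("d", "p", "w")
    denom_ok <- dbar^2 + pbar^2 > 0
    contrib <- switch(kind,
      sb = {
        if (!denom_ok) 0 else sum(s$w * (s$d - s$p)^2 / (dbar^2 + pbar^2))
      },
      su = {
        if (dbar == 0 || pbar == 0) {
          stop("loss 'su' undefined for zero-mean data or predictions; use 'sb'", call. = FALSE)
        }
        sum(s$w * (s$d - s$p)^2 * (1 / dbar^2 + 1 / pbar^2))
      },
      re = {
        if (dbar == 0) {
          stop("loss 're' undefined for a zero-mean dataset; use 'sb'", call. = FALSE)
        }
        sum(s$w * (s$d - s$p)^2 / dbar^2)
      }
    )
    total <- total + contrib
  }
  total
}

#' Default weight coefficients
#'
#' Sets the automatic weights `w_ij = 1/n_i` (each dataset contributes equally
#' to the loss, rather than each point), multiplied by the user's
#' dimensionless weight multipliers. Pseudo-data receive loss-function
#' dependent defaults (see [pseudo_data()]), an order of magnitude smaller
#' than data weights so that informative data dominate.
#'
#' @param entry a [deb_entry()] object.
#' @return a tibble with columns `set`, `j`, `weight`.
#' @export
default_weights <- function(entry) {
  zv <- entry$zero_variate
  rows <- list()
  if (!is.null(zv) && nrow(zv)) {
    if (any(zv$weight < 0)) stop("negative weight multiplier", call. = FALSE)
    rows[[1]] <- tibble::tibble(set = zv$label, j = 1L, weight = zv$weight * 1)
  }
  for (ds in entry$uni_variate) {
    if (ds$weight < 0) stop("negative weight multiplier", call. = FALSE)
    n <- length(ds$x)
    rows[[length(rows) + 1]] <- tibble::tibble(
      set = ds$label, j = seq_len(n), weight = ds$weight / n
    )
  }
  dplyr::bind_rows(rows)
}

#' Pseudo-data: generalized-animal priors
#'
#' The pseudo-data are fixed generalized-animal values of (functions of)
#' parameters, treated as weak data so that they act as priors when the real
#' data are uninformative: energy conductance `v = 0.02` cm/d, allocation
#' fraction `kap = 0.8`, reproduction efficiency `kap_R = 0.95`, specific
#' somatic maintenance `p_M = 18` J/d.cm^3, maturity maintenance rate
#' `k_J = 0.002` 1/d and growth efficiency `kap_G = 0.8`. Default weights
#' depend on the loss function: under `"sb"` all are 0.1 except `kap_G` (20);
#' under `"su"` the rate parameters drop to 1e-5. When `"re"` is selected the
#' `"sb"` column is applied (with a warning at estimation time).
#'
#' @param loss_kind `"sb"`, `"su"` or `"re"`.
#' @return a tibble with columns `label`, `value`, `units`, `weight`.
#' @export
pseudo_data <- function(loss_kind = "sb") {
  w_sb <- c(v = 0.1, kap = 0.1, kap_R = 0.1, p_M = 0.1, k_J = 0.1, kap_G = 20)
  w_su <- c(v = 1e-5, kap = 0.1, kap_R = 0.1, p_M = 1e-5, k_J = 1e-5, kap_G = 20)
  w <- if (identical(loss_kind, "su")) w_su else w_sb
  tibble::tibble(
    label = c("v", "kap", "kap_R", "p_M", "k_J", "kap_G"),
    value = c(0.02, 0.8, 0.95, 18, 0.002, 0.8),
    units = c("cm/d", "-", "-", "J/d.cm^3", "1/d", "-"),
    weight = unname(w[c("v", "kap", "kap_R", "p_M", "k_J", "kap_G")])
  )
}

# predicted values of the pseudo-data under a parameter set
pseudo_predictions <- function(p, chem = chemical_params()) {
  c(
    v = p$v, kap = p$kap, kap_R = p$kap_R, p_M = p$p_M, k_J = p$k_J,
    kap_G = kap_G_from_chemistry(p, chem)
  )
}
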