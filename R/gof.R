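#' Goodness-of-fit metrics: mean relative error and symmetric mean squared error
#'
#' For each dataset `i`, the relative error is
#' `RE_i = sum_j (w_ij/w_i) |p_ij - d_ij| / |dbar_i|` and the symmetric
#' squared error `SSE_i = sum_j (w_ij/w_i) (p_ij - d_ij)^2 / (dbar_i^2 +
#' pbar_i^2)`, with `w_i = sum_j w_ij`. The global measures average over the
#' `n'` datasets with positive total weight: `MRE = mean(RE_i)` (range
#' `[0, Inf]`, additive: +20% and -20% deviations contribute equally) and
#' `SMSE = mean(SSE_i)` (range `[0, 1]`, multiplicative: x2 and x1/2
#' deviations contribute equally). Both are 0 exactly when predictions match
#' the data. For a single-value dataset these reduce to `RE = |p/d - 1|` and
#' `SSE = (p/d - 1)^2 / (1 + (p/d)^2)`.
#'
#' The SSE denominator is the weighted per-point sum `sum_j w_ij (d_ij^2 +
#' p_ij^2)`: since `(p - d)^2 <= d^2 + p^2` for non-negative values, this
#' guarantees the `[0, 1]` range for every dataset shape, and it coincides
#' with the zero-variate form above when `n_i = 1`.
#'
#' @param df a data frame with columns `set`, `data`, `pred`, `weight`.
#' @return an object of class `deb_fit_report`: a tibble with one row per
#'   dataset (`set`, `RE`, `SSE`, `w_i`) and attributes `MRE`, `SMSE`, `n_sets`.
#' @export
#' @examples
#' df <- tibble::tibble(set = "Li", data = 1, pred = 1.2, weight = 1)
#' fit_metrics(df) # RE = 0.2
fit_metrics <- function(df) {
  stopifnot(all(c("set", "data", "pred", "weight") %in% names(df)))
  by_set <- df |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      w_i = sum(.data$weight),
      dbar = mean(.data$data),
      pbar = mean(.data$pred),
      RE = if (sum(.data$weight) > 0) {
        sum((.data$weight / sum(.data$weight)) * abs(.data$pred - .data$data)) /
          abs(mean(.data$data))
      } else NA_real_,
      SSE = if (sum(.data$weight) > 0) {
        sum(.data$weight * (.data$pred - .data$data)^2) /
          sum(.data$weight * (.data$data^2 + .data$pred^2))
      } else NA_real_,
      .groups = "drop"
    )
  used <- by_set[by_set$w_i > 0, , drop = FALSE]
  if (nrow(used) == 0) stop("all dataset weights are zero: MRE/SMSE undefined", call. = FALSE)
  if (any(used$dbar == 0)) stop("MRE undefined for a zero-mean dataset", call. = FALSE)
  out <- by_set[, c("set", "RE", "SSE", "w_i")]
  structure(out,
    class = c("deb_fit_report", class(out)),
    MRE = mean(used$RE), SMSE = mean(used$SSE), n_sets = nrow(used)
  )
}

#' @export
print.deb_fit_report <- function(x, ...) {
  cat(
    "<deb_fit_report> MRE =", signif(attr(x, "MRE"), 4),
    "| SMSE =", signif(attr(x, "SMSE"), 4),
    "| datasets:", attr(x, "n_sets"), "\n"
  )
  NextMethod()
  invisible(x)
}

#' Glance at a fit report
#' @param x a `deb_fit_report`.
#' @param ... unused.
#' @return one-row tibble with `MRE`, `SMSE`, `n_sets`.
#' @export
glance.deb_fit_report <- function(x, ...) {
  tibble::tibble(
    MRE = attr(x, "MRE"), SMSE = attr(x, "SMSE"), n_sets = attr(x, "n_sets")
  )
}

#' Data-completeness score
#'
#' Scores how many different aspects of metabolic performance an entry's data
#' cover, on a scale of 1 to 10. The rubric is additive and configurable:
#' each covered aspect contributes its rubric points on top of a base level of
#' 1, capped at 10. The default rubric rewards life-history ages, sizes at
#' stage transitions, reproduction, growth curves, reproduction-vs-size data
#' and feeding/respiration information.
#'
#' @param entry a [deb_entry()] object.
#' @param rubric a data frame with columns `aspect`, `labels`
#'   (comma-separated data labels counting towards the aspect) and `points`.
#' @return a number in `[1, 10]`.
#' @export
completeness_score <- function(entry, rubric = completeness_rubric()) {
  labs <- c(
    entry$zero_variate$label,
    vapply(entry$uni_variate, function(d) d$label, character(1))
  )
  known <- unlist(strsplit(rubric$labels, ",[ ]*"))
  unknown <- setdiff(labs, known)
  if (length(unknown)) {
    warning(
      "labels not in completeness rubric (ignored): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  pts <- 0
  for (i in seq_len(nrow(rubric))) {
    aspect_labels <- strsplit(rubric$labels[i], ",[ ]*")[[1]]
    if (any(labs %in% aspect_labels)) pts <- pts + rubric$points[i]
  }
  min(10, 1 + pts)
}

#' Default completeness rubric
#' @return tibble with columns `aspect`, `labels`, `points`.
#' @export
completeness_rubric <- function() {
  tibble::tribble(
    ~aspect, ~labels, ~points,
    "size at one life stage", "Li, Wwi, Lp, Wwp", 0.5,
    "life-history ages", "ab, ap, am", 1,
    "sizes at stage transitions", "Lb, Wwb, Lj, Lp, Wwp", 1,
    "reproduction rate", "Ri", 1,
    "growth curve", "tL, tW", 2,
    "reproduction vs size or time", "LN, tN", 1.5,
    "feeding or respiration", "JX, JO", 2,
    "multiple food levels", "tL_f, tW_f", 1
  )
}
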