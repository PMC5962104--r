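#' Plot a life-cycle trajectory
#'
#' Faceted view of structural length, reserve, maturity and survival against
#' age, with stage-transition events marked.
#'
#' @param object a `deb_trajectory` from [integrate_life_cycle()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.deb_trajectory <- function(object, ...) {
  sched <- attr(object, "schedule")
  long <- tidyr::pivot_longer(
    as.data.frame(object)[, c("t", "L", "E", "EH", "S")],
    cols = c("L", "E", "EH", "S"),
    names_to = "state", values_to = "value"
  )
  long$state <- factor(long$state,
    levels = c("L", "E", "EH", "S"),
    labels = c("structural length (cm)", "reserve (J)", "maturity (J)", "survival (-)")
  )
  gp <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "age (d)", y = NULL)
  ev <- sched[sched$reached & !is.na(sched$age), ]
  if (nrow(ev)) {
    gp <- gp + ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$age),
      linetype = "dashed", colour = "grey50"
    )
  }
  gp
}

#' Plot observed vs predicted data of a fit
#'
#' Uni-variate datasets are shown as points (observations) with the model
#' curve; zero-variate data as an observed-predicted scatter on log axes.
#'
#' @param object a `deb_fit` from [estimate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.deb_fit <- function(object, ...) {
  preds <- predict_entry(object$entry, object$params)
  uni <- preds[preds$type == "uni", ]
  if (nrow(uni)) {
    ggplot2::ggplot(uni, ggplot2::aes(x = .data$x)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$data), alpha = 0.7) +
      ggplot2::geom_line(ggplot2::aes(y = .data$pred), colour = "steelblue") +
      ggplot2::facet_wrap(~set, scales = "free") +
      ggplot2::labs(x = NULL, y = NULL, title = object$entry$species)
  } else {
    zv <- preds[preds$type == "zero", ]
    ggplot2::ggplot(zv, ggplot2::aes(x = .data$data, y = .data$pred)) +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "observed", y = "predicted", title = object$entry$species)
  }
}

#' Plot a survivor function
#'
#' @param object a `deb_survivor` from [survivor_function()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.deb_survivor <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object), ggplot2::aes(x = .data$x, y = .data$S)) +
    ggplot2::geom_step(direction = "hv", colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "median"), linetype = "dashed") +
    ggplot2::labs(x = "value", y = "fraction of entries above")
}
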