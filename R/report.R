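#' Render an entry report
#'
#' Produces a markdown report for an entry with four sections: (i) metadata
#' with references, (ii) predictions (zero-variate observations as a table of
#' numbers; uni-variate datasets as figures when `plot_dir` is given),
#' (iii) parameters and (iv) implied properties. The model label, data
#' completeness and the MRE/SMSE goodness-of-fit summary are included.
#' Pseudo-data are excluded from the fit summary: they are priors, not
#' observations.
#'
#' @param entry a [deb_entry()].
#' @param p parameter set to report; defaults to the entry's.
#' @param fit optional [fit_metrics()] report (computed if missing).
#' @param path optional output file; when `NULL` the markdown is returned as
#'   a character vector.
#' @param plot_dir optional directory for uni-variate prediction figures
#'   (PNG, one per dataset).
#' @param chem a [chemical_params()] object.
#' @return the markdown lines, invisibly if written to `path`.
#' @export
render_report <- function(entry, p = entry$params, fit = NULL, path = NULL,
                          plot_dir = NULL, chem = chemical_params()) {
  preds <- predict_entry(entry, p, chem = chem)
  if (is.null(fit)) {
    fit <- fit_metrics(preds[, c("set", "data", "pred", "weight")])
  }
  props <- implied_properties(p, entry$model, f = 1, chem = chem)
  fmt <- function(x) ifelse(is.na(x), "-", signif(x, 5))

  lines <- c(
    paste0("# ", entry$species),
    "",
    "## Metadata",
    "",
    paste0("- model: ", entry$model$label, " (", entry$model$family, "-family)"),
    paste0(
      "- classification: ",
      paste(names(entry$classification), unlist(entry$classification),
        sep = ": ", collapse = "; "
      )
    ),
    paste0("- data completeness: ", completeness_score(entry), " (scale 1-10)"),
    paste0(
      "- data: ", paste(c(
        entry$zero_variate$label,
        vapply(entry$uni_variate, function(d) d$label, character(1))
      ), collapse = ", ")
    ),
    if (length(entry$metadata)) {
      paste0("- ", names(entry$metadata), ": ", vapply(entry$metadata, paste, character(1), collapse = "; "))
    },
    "",
    "## Predictions",
    "",
    paste0(
      "Goodness of fit: MRE = ", signif(attr(fit, "MRE"), 4),
      ", SMSE = ", signif(attr(fit, "SMSE"), 4),
      " over ", attr(fit, "n_sets"), " datasets",
      " (pseudo-data excluded)."
    ),
    "",
    "| dataset | observed | predicted | units | RE |",
    "|---|---|---|---|---|"
  )
  zv <- preds[preds$type == "zero", ]
  for (i in seq_len(nrow(zv))) {
    re <- fit$RE[fit$set == zv$set[i]]
    u <- entry$zero_variate$units[entry$zero_variate$label == zv$set[i]]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s |",
      zv$set[i], fmt(zv$data[i]), fmt(zv$pred[i]), u, fmt(re)
    ))
  }
  for (ds in entry$uni_variate) {
    re <- fit$RE[fit$set == ds$label]
    lines <- c(lines, sprintf(
      "| %s (%d points) | - | figure | %s vs %s | %s |",
      ds$label, length(ds$x), ds$units_y, ds$units_x, fmt(re)
    ))
  }
  if (!is.null(plot_dir) && length(entry$uni_variate)) {
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (ds in entry$uni_variate) {
      sub <- preds[preds$set == ds$label, ]
      gp <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$x)) +
        ggplot2::geom_point(ggplot2::aes(y = .data$data)) +
        ggplot2::geom_line(ggplot2::aes(y = .data$pred), colour = "steelblue") +
        ggplot2::labs(
          x = ds$units_x, y = ds$units_y,
          title = paste(entry$species, "-", ds$label)
        )
      fp <- file.path(plot_dir, paste0(ds$label, ".png"))
      ggplot2::ggsave(fp, gp, width = 5, height = 4, dpi = 120)
      lines <- c(lines, "", paste0("![", ds$label, "](", fp, ")"))
    }
  }

  pt <- tidy(p)
  lines <- c(
    lines, "", "## Parameters", "",
    "| parameter | value | units | free |", "|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %s |",
      pt$parameter, fmt(pt$value), pt$units, ifelse(pt$free, "yes", "no")
    ),
    "", "## Implied properties", "",
    "(at the reference temperature and abundant food)", "",
    "| property | value | units |", "|---|---|---|",
    sprintf("| %s | %s | %s |", props$property, fmt(props$value), props$units)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export a trajectory as CSV
#'
#' Writes the state trajectory (t, E, L, EH, ER, S) and, alongside it, the
#' stage-event table (`<path>` with suffix `_events.csv`).
#'
#' @param traj a `deb_trajectory` from [integrate_life_cycle()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(
    as.data.frame(traj)[, c("t", "E", "L", "EH", "ER", "S")],
    path,
    row.names = FALSE
  )
  ev_path <- sub("(\\.csv)?$", "_events.csv", path, ignore.case = TRUE)
  utils::write.csv(as.data.frame(attr(traj, "schedule")), ev_path, row.names = FALSE)
  invisible(path)
}
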