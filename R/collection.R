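# Cross-species comparison over a directory ("collection") of entry files.

#' Empirical survivor function of parameter values
#'
#' Right-continuous survival curve `S(x) = fraction of values > x`, the form
#' used to compare frequency distributions of parameters across a collection,
#' with the median read off as the smallest observed value with `S(x) <= 0.5`
#' (the lower-of-middle convention for even counts).
#'
#' @param values numeric vector (at least one finite value).
#' @return an object of class `deb_survivor`: tibble with columns `x`, `S`,
#'   and attribute `median`.
#' @export
#' @examples
#' survivor_function(c(1, 2, 3))
survivor_function <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values", call. = FALSE)
  xs <- sort(unique(values))
  S <- vapply(xs, function(x) mean(values > x), numeric(1))
  med <- xs[which(S <= 0.5)[1]]
  structure(
    tibble::tibble(x = xs, S = S),
    class = c("deb_survivor", class(tibble::tibble())),
    median = med, n = length(values)
  )
}

#' @export
print.deb_survivor <- function(x, ...) {
  cat("<deb_survivor> n =", attr(x, "n"), "| median =", attr(x, "median"), "\n")
  NextMethod()
  invisible(x)
}

#' Summarise a collection of entries
#'
#' Assembles one row per entry file in a directory: species, model label,
#' primary and compound parameters, a core of implied properties, the
#' goodness-of-fit of the stored parameters (MRE/SMSE), the completeness
#' score and the metabolic acceleration factor. Aggregate statistics (median
#' MRE/SMSE via the survivor function, acceleration-factor bins at 2, 5 and
#' 10) accompany the table. Unreadable entries are skipped with a warning.
#'
#' @param dir directory containing `.yaml`/`.yml` entry files.
#' @param chem a [chemical_params()] object.
#' @return a list of class `deb_collection`: `table` (tibble), `aggregates`
#'   (list with `median_MRE`, `median_SMSE`, `acceleration_bins`, `n`,
#'   `n_skipped`).
#' @export
collection_summary <- function(dir, chem = chemical_params()) {
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  rows <- list()
  skipped <- 0L
  for (fp in files) {
    row <- tryCatch(
      {
        entry <- read_entry(fp)
        p <- entry$params
        cmp <- compound_parameters(p)
        sim <- integrate_life_cycle(p, entry$model, f = 1, T_K = p$T_ref)
        props <- implied_properties(p, entry$model, f = 1, chem = chem, sim = sim)
        acc <- acceleration_factor(attr(sim, "schedule"), entry$model)
        preds <- predict_entry(entry, p, chem = chem)
        rep <- fit_metrics(preds[, c("set", "data", "pred", "weight")])
        pv <- function(nm) props$value[props$property == nm]
        tibble::tibble(
          file = basename(fp), species = entry$species,
          model = entry$model$label,
          p_Am = p$p_Am, v = p$v, kap = p$kap, p_M = p$p_M,
          k_J = p$k_J, E_G = p$E_G, E_Hb = p$E_Hb, E_Hp = p$E_Hp,
          h_a = p$h_a, s_G = p$s_G,
          L_m = cmp$L_m, E_m = cmp$E_m, g = cmp$g, k_M = cmp$k_M,
          L_i = pv("L_i"), a_b = pv("a_b"), a_p = pv("a_p"), a_m = pv("a_m"),
          Ww_i = pv("Ww_i"), R_i = pv("R_i"),
          MRE = attr(rep, "MRE"), SMSE = attr(rep, "SMSE"),
          completeness = completeness_score(entry),
          acceleration = acc$factor
        )
      },
      error = function(e) {
        warning("skipping ", basename(fp), ": ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(row)) skipped <- skipped + 1L else rows[[length(rows) + 1]] <- row
  }
  tab <- dplyr::bind_rows(rows)
  aggregates <- list(n = nrow(tab), n_skipped = skipped)
  if (nrow(tab)) {
    aggregates$median_MRE <- attr(survivor_function(tab$MRE), "median")
    aggregates$median_SMSE <- attr(survivor_function(tab$SMSE), "median")
    acc <- tab$acceleration[is.finite(tab$acceleration)]
    aggregates$acceleration_bins <- list(
      "<2" = sum(acc < 2), "<5" = sum(acc >= 2 & acc < 5),
      "<10" = sum(acc >= 5 & acc < 10), ">=10" = sum(acc >= 10)
    )
  }
  structure(list(table = tab, aggregates = aggregates), class = "deb_collection")
}

#' @export
print.deb_collection <- function(x, ...) {
  a <- x$aggregates
  cat(
    "<deb_collection>", a$n, "entries (", a$n_skipped, "skipped ) | median MRE",
    signif(a$median_MRE %||% NA, 4), "| median SMSE", signif(a$median_SMSE %||% NA, 4), "\n"
  )
  if (!is.null(a$acceleration_bins)) {
    cat("acceleration factor bins:\n")
    print(unlist(a$acceleration_bins))
  }
  invisible(x)
}

#' Export a collection summary
#'
#' Writes the per-entry table as CSV and the aggregate statistics as JSON.
#'
#' @param x a `deb_collection` from [collection_summary()].
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_collection <- function(x, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(x$table, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(x$aggregates, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
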