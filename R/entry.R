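# An "entry" is one species' complete bundle: metadata, zero- and uni-variate
# data with units, temperatures and weight multipliers, the typified model
# label, the parameter set, and estimation options.

# expected units per standardized data label (d/cm/J/K/g system)
label_units <- function() {
  c(
    ab = "d", ap = "d", am = "d", aj = "d",
    Lb = "cm", Lj = "cm", Lp = "cm", Li = "cm",
    Wwb = "g", Wwp = "g", Wwi = "g", Ri = "1/d", E0 = "J"
  )
}
uni_units <- function() {
  list(
    tL = c(x = "d", y = "cm"),
    tW = c(x = "d", y = "g"),
    LN = c(x = "cm", y = "1/d")
  )
}

#' Construct a species entry
#'
#' Bundles everything needed to estimate DEB parameters for one species:
#' zero-variate data (single scalar observations such as age at birth or
#' ultimate length, each with units, temperature and a weight multiplier),
#' uni-variate datasets (paired series such as time-length), the typified
#' model label, the parameter set and estimation options.
#'
#' @param species species name.
#' @param model a [deb_model()] or model label string.
#' @param params a [deb_params()] object.
#' @param zero_variate tibble with columns `label`, `value`, `units`,
#'   `temp_K`, `weight` (multiplier, default 1) and optionally `f` (food
#'   level, default 1).
#' @param uni_variate list of uni-variate datasets; each a list with `label`
#'   (base label `tL`, `tW` or `LN`, optionally suffixed for uniqueness, e.g.
#'   `tL_female`), `x`, `y`, `units_x`, `units_y`, `temp_K`, `f` (scalar food
#'   level, default 1) and `weight` (multiplier, default 1).
#' @param classification named list of free-text taxonomy strings (e.g.
#'   `phylum`, `class`).
#' @param pseudo include the generalized-animal pseudo-data in estimation?
#' @param options estimation options, see [estimation_options()].
#' @param metadata named list: authors, dates, references (free text).
#' @return an object of class `deb_entry`.
#' @export
deb_entry <- function(species, model = deb_model("std"), params = deb_params(),
                      zero_variate = NULL, uni_variate = list(),
                      classification = list(), pseudo = TRUE,
                      options = estimation_options(), metadata = list()) {
  if (is.character(model)) model <- deb_model(model)
  if (is.null(zero_variate)) {
    zero_variate <- tibble::tibble(
      label = character(), value = numeric(), units = character(),
      temp_K = numeric(), weight = numeric(), f = numeric()
    )
  }
  zero_variate <- tibble::as_tibble(zero_variate)
  if (!"weight" %in% names(zero_variate)) zero_variate$weight <- 1
  if (!"f" %in% names(zero_variate)) zero_variate$f <- 1
  entry <- structure(
    list(
      species = species, model = model, params = params,
      zero_variate = zero_variate, uni_variate = uni_variate,
      classification = classification, pseudo = isTRUE(pseudo),
      options = options, metadata = metadata
    ),
    class = "deb_entry"
  )
  validate_entry(entry)
  entry
}

validate_entry <- function(entry) {
  zv <- entry$zero_variate
  lu <- label_units()
  if (nrow(zv)) {
    if (anyNA(zv$value) || any(zv$value < 0)) {
      stop("zero-variate values must be non-negative", call. = FALSE)
    }
    for (i in seq_len(nrow(zv))) {
      lab <- zv$label[i]
      if (!lab %in% names(lu)) {
        stop("unknown zero-variate label: ", lab, call. = FALSE)
      }
      if (is.na(zv$units[i]) || zv$units[i] != lu[[lab]]) {
        stop(
          "unit mismatch for '", lab, "': expected '", lu[[lab]],
          "', got '", zv$units[i], "'",
          call. = FALSE
        )
      }
    }
    if (anyNA(zv$temp_K) || any(zv$temp_K <= 0)) {
      stop("zero-variate data need positive temperatures (K)", call. = FALSE)
    }
  }
  uu <- uni_units()
  labs <- zv$label
  for (ds in entry$uni_variate) {
    base <- sub("_.*$", "", ds$label)
    if (!base %in% names(uu)) {
      stop("unknown uni-variate label: ", ds$label, call. = FALSE)
    }
    if (length(ds$x) != length(ds$y) || length(ds$x) < 1) {
      stop("dataset '", ds$label, "': x and y must be equal-length, non-empty", call. = FALSE)
    }
    if (!identical(ds$units_x, unname(uu[[base]]["x"])) ||
      !identical(ds$units_y, unname(uu[[base]]["y"]))) {
      stop(
        "unit mismatch in dataset '", ds$label, "': expected x '",
        uu[[base]]["x"], "', y '", uu[[base]]["y"], "'",
        call. = FALSE
      )
    }
    if (is.null(ds$temp_K) || !is.finite(ds$temp_K) || ds$temp_K <= 0) {
      stop("dataset '", ds$label, "' lacks an auxiliary temperature", call. = FALSE)
    }
    labs <- c(labs, ds$label)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate dataset label: ", labs[duplicated(labs)][1], call. = FALSE)
  }
  invisible(entry)
}

#' Estimation options
#'
#' @param loss loss-function kind: `"sb"` (default), `"su"` or `"re"`
#'   (deprecated).
#' @param steps maximum simplex steps per continuation round.
#' @param continuations number of continuation rounds (each restart re-inflates
#'   the simplex around the current best point).
#' @param tol_f,tol_x convergence tolerances (relative loss spread, relative
#'   simplex size).
#' @param seed optional random seed recorded with the options.
#' @return a list of class `deb_estimation_options`.
#' @export
estimation_options <- function(loss = "sb", steps = 500, continuations = 3,
                               tol_f = 1e-4, tol_x = 1e-3, seed = NULL) {
  if (!loss %in% c("sb", "su", "re")) stop("loss must be sb, su or re", call. = FALSE)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  structure(
    list(
      loss = loss, steps = steps, continuations = continuations,
      tol_f = tol_f, tol_x = tol_x, seed = seed
    ),
    class = "deb_estimation_options"
  )
}

#' @export
print.deb_entry <- function(x, ...) {
  cat(
    "<deb_entry>", x$species, "| model", x$model$label, "|",
    nrow(x$zero_variate), "zero-variate data,",
    length(x$uni_variate), "uni-variate dataset(s)\n"
  )
  invisible(x)
}

#' Read / write an entry file
#'
#' Entries are serialized as YAML (JSON, being a YAML subset, is also
#' accepted on reading). All quantities carry unit strings which are
#' validated against the d/cm/J/K/g system on reading; writing then reading
#' recovers the entry values exactly up to floating-point formatting.
#'
#' @param path file path.
#' @return `read_entry()` returns a `deb_entry`; `write_entry()` returns
#'   `path` invisibly.
#' @export
read_entry <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("species", "model", "parameters")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("entry file missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)

  pv <- raw$parameters
  vals <- lapply(pv, function(x) x$value)
  units <- vapply(pv, function(x) x$units %||% NA_character_, character(1))
  free <- names(pv)[vapply(pv, function(x) isTRUE(x$free), logical(1))]
  exp_units <- deb_param_units()
  for (nm in names(vals)) {
    if (!nm %in% names(exp_units)) stop("unknown parameter in file: ", nm, call. = FALSE)
    if (is.na(units[[nm]]) || units[[nm]] != exp_units[[nm]]) {
      stop(
        "unit mismatch for parameter '", nm, "': expected '",
        exp_units[[nm]], "'",
        call. = FALSE
      )
    }
  }
  params <- do.call(deb_params, c(
    lapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v)),
    list(free = free)
  ))

  zv <- NULL
  if (!is.null(raw$zero_variate)) {
    zv <- dplyr::bind_rows(lapply(names(raw$zero_variate), function(lab) {
      d <- raw$zero_variate[[lab]]
      tibble::tibble(
        label = lab, value = as.numeric(d$value),
        units = d$units %||% NA_character_,
        temp_K = as.numeric(d$temp_K %||% NA_real_),
        weight = as.numeric(d$weight %||% 1),
        f = as.numeric(d$f %||% 1)
      )
    }))
  }
  uv <- list()
  if (!is.null(raw$uni_variate)) {
    uv <- lapply(names(raw$uni_variate), function(lab) {
      d <- raw$uni_variate[[lab]]
      x <- d$x
      y <- d$y
      if (!is.null(d$csv)) { # series stored in a sibling CSV file
        ser <- utils::read.csv(file.path(dirname(path), d$csv))
        x <- ser[[1]]
        y <- ser[[2]]
      }
      list(
        label = lab, x = as.numeric(x), y = as.numeric(y),
        units_x = d$units_x, units_y = d$units_y,
        temp_K = as.numeric(d$temp_K %||% NA_real_),
        f = as.numeric(d$f %||% 1), weight = as.numeric(d$weight %||% 1)
      )
    })
  }
  deb_entry(
    species = raw$species, model = deb_model(raw$model), params = params,
    zero_variate = zv, uni_variate = uv,
    classification = raw$classification %||% list(),
    pseudo = raw$pseudo_data %||% TRUE,
    options = do.call(estimation_options, raw$estimation %||% list()),
    metadata = raw$metadata %||% list()
  )
}

#' @rdname read_entry
#' @param entry a [deb_entry()] object.
#' @export
write_entry <- function(entry, path) {
  pu <- deb_param_units()
  free <- attr(entry$params, "free")
  pars <- lapply(names(unclass(entry$params)), function(nm) {
    v <- entry$params[[nm]]
    list(
      value = if (is.na(v)) NULL else v, units = unname(pu[[nm]]),
      free = nm %in% free
    )
  })
  names(pars) <- names(unclass(entry$params))
  zv <- NULL
  if (nrow(entry$zero_variate)) {
    zv <- lapply(seq_len(nrow(entry$zero_variate)), function(i) {
      r <- entry$zero_variate[i, ]
      list(
        value = r$value, units = r$units, temp_K = r$temp_K,
        weight = r$weight, f = r$f
      )
    })
    names(zv) <- entry$zero_variate$label
  }
  uv <- NULL
  if (length(entry$uni_variate)) {
    uv <- lapply(entry$uni_variate, function(d) {
      list(
        x = d$x, y = d$y, units_x = d$units_x, units_y = d$units_y,
        temp_K = d$temp_K, f = d$f, weight = d$weight
      )
    })
    names(uv) <- vapply(entry$uni_variate, function(d) d$label, character(1))
  }
  doc <- list(
    species = entry$species,
    classification = entry$classification,
    model = entry$model$label,
    metadata = entry$metadata,
    zero_variate = zv,
    uni_variate = uv,
    pseudo_data = entry$pseudo,
    parameters = pars,
    estimation = unclass(entry$options)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
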