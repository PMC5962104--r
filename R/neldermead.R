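#' Filter-aware Nelder-Mead downhill simplex
#'
#' Minimizes an objective under a feasibility filter: the filter is called
#' before every objective evaluation, and the objective is never evaluated at
#' a point that fails it. Candidate points that fail the filter are replaced
#' by successive halving towards the current best vertex (up to
#' `max_halvings`; the move is skipped if the point still fails). Standard
#' simplex coefficients are used (reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5).
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param x0 feasible starting point.
#' @param filter function of a numeric vector returning `TRUE`/`FALSE` (or a
#'   list with element `pass`).
#' @param max_steps maximum simplex iterations.
#' @param tol_f relative spread of vertex losses below which the run converges.
#' @param tol_x relative simplex size below which the run converges.
#' @param step initial simplex edge as a fraction of each coordinate (with an
#'   absolute floor for zero coordinates).
#' @param max_halvings halvings toward the best vertex when a candidate fails
#'   the filter.
#' @return a list with `par`, `value`, `steps`, `converged`, `n_obj`,
#'   `n_filter_fail` (candidates rejected by the filter), and `eval_log` (a
#'   tibble of every objective evaluation: the point had passed the filter).
#' @export
#' @examples
#' r <- nelder_mead_filtered(function(x) sum((x - 2)^2), c(0, 0))
#' round(r$par, 3)
nelder_mead_filtered <- function(objective, x0, filter = function(x) TRUE,
                                 max_steps = 500, tol_f = 1e-4, tol_x = 1e-3,
                                 step = 0.05, max_halvings = 10) {
  passes <- function(x) {
    v <- filter(x)
    if (is.list(v)) v <- isTRUE(v$pass) else v <- isTRUE(v)
    v
  }
  n_obj <- 0L
  n_filter_fail <- 0L
  log_x <- list()
  f_checked <- function(x) {
    if (!passes(x)) stop("internal: objective called on filter-failing point")
    n_obj <<- n_obj + 1L
    log_x[[length(log_x) + 1L]] <<- x
    objective(x)
  }

  if (!passes(x0)) stop("starting point fails the filter", call. = FALSE)
  n <- length(x0)

  # feasible initial simplex: offsets tried in both directions, halving
  # toward x0 until they pass
  verts <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) {
    dx0 <- if (x0[i] != 0) step * abs(x0[i]) else step
    v <- x0
    found <- FALSE
    for (sgn in c(1, -1)) {
      dx <- sgn * dx0
      k <- 0
      v[i] <- x0[i] + dx
      while (!passes(v) && k < max_halvings) {
        dx <- dx / 2
        v[i] <- x0[i] + dx
        k <- k + 1
        n_filter_fail <- n_filter_fail + 1L
      }
      if (passes(v) && abs(dx) > .Machine$double.eps * abs(x0[i])) {
        found <- TRUE
        break
      }
    }
    if (!found) v <- x0
    verts[i + 1, ] <- v
  }
  fv <- apply(verts, 1, f_checked)

  toward_best <- function(x, best) {
    k <- 0
    while (!passes(x) && k < max_halvings) {
      n_filter_fail <<- n_filter_fail + 1L
      x <- best + (x - best) / 2
      k <- k + 1
    }
    if (!passes(x)) return(NULL)
    attr(x, "halved") <- k > 0
    x
  }

  steps <- 0L
  converged <- FALSE
  while (steps < max_steps) {
    steps <- steps + 1L
    ord <- order(fv)
    verts <- verts[ord, , drop = FALSE]
    fv <- fv[ord]
    best <- verts[1, ]
    worst <- verts[n + 1, ]

    spread <- abs(fv[n + 1] - fv[1]) / (abs(fv[1]) + 1e-12)
    size <- max(apply(verts, 2, function(c) diff(range(c)))) /
      (max(abs(best)) + 1e-12)
    if (spread < tol_f && size < tol_x) {
      converged <- TRUE
      break
    }

    centroid <- colMeans(verts[1:n, , drop = FALSE])
    # a candidate that had to be halved toward the best vertex is no longer a
    # genuine reflection: accept it only if it improves on the best, otherwise
    # fall through to the contraction step (prevents simplex collapse onto a
    # feasibility boundary)
    eval_candidate <- function(x) {
      if (is.null(x)) return(Inf)
      val <- f_checked(as.numeric(x))
      if (isTRUE(attr(x, "halved")) && val >= fv[1]) Inf else val
    }
    xr <- toward_best(centroid + (centroid - worst), best)
    fr <- eval_candidate(xr)

    if (fr < fv[1]) {
      xe <- toward_best(centroid + 2 * (centroid - worst), best)
      fe <- eval_candidate(xe)
      if (fe < fr) {
        verts[n + 1, ] <- as.numeric(xe)
        fv[n + 1] <- fe
      } else {
        verts[n + 1, ] <- as.numeric(xr)
        fv[n + 1] <- fr
      }
    } else if (fr < fv[n]) {
      verts[n + 1, ] <- as.numeric(xr)
      fv[n + 1] <- fr
    } else {
      xc <- if (is.finite(fr) && fr < fv[n + 1]) {
        centroid + 0.5 * (as.numeric(xr) - centroid) # outside contraction
      } else {
        centroid + 0.5 * (worst - centroid) # inside contraction
      }
      xc <- toward_best(xc, best)
      fc <- eval_candidate(xc)
      if (fc < min(fr, fv[n + 1])) {
        verts[n + 1, ] <- as.numeric(xc)
        fv[n + 1] <- fc
      } else {
        # shrink toward best; vertices are pulled further if infeasible
        for (i in 2:(n + 1)) {
          v <- toward_best(best + 0.5 * (verts[i, ] - best), best)
          v <- if (is.null(v)) best else as.numeric(v)
          verts[i, ] <- v
          fv[i] <- f_checked(v)
        }
      }
    }
  }
  ord <- order(fv)
  list(
    par = verts[ord[1], ], value = fv[ord[1]], steps = steps,
    converged = converged, n_obj = n_obj, n_filter_fail = n_filter_fail,
    eval_log = do.call(rbind, log_x)
  )
}
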