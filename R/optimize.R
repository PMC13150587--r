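#' Constrained optimum of a fitted response surface
#'
#' Locates the global maximum (or minimum) of the fitted quadratic over
#' a box of factor ranges. Because a quadratic over a box attains its
#' optimum either at the unconstrained stationary point or on the
#' boundary, the search is a deterministic multi-start quasi-Newton
#' refinement (L-BFGS-B with analytic gradient) seeded from the 8 box
#' vertices, the box center and the stationary point of the quadratic
#' (clamped into the box); ties within a relative tolerance of 1e-8 are
#' broken by the first-found start.
#'
#' @param object An `rsm_quad` fit.
#' @param bounds Per-factor ranges as a named list of `c(low, high)`;
#'   defaults to each factor's design range.
#' @param direction `"max"` (default) or `"min"`.
#' @return An object of class `rsm_optimum`: a list with `actual` and
#'   `coded` optimal levels, `predicted` response, per-factor `boundary`
#'   flags (`"interior"`, `"at-low"`, `"at-high"`), the stationary-point
#'   `classification` (`"maximum"`, `"minimum"`, `"saddle"` or
#'   `"boundary"` when the constrained optimum sits on the box edge) and
#'   the `stationary_point` itself (NULL if the quadratic part is
#'   singular).
#' @examples
#' fit <- rsm_quad(activity ~ cs + ga + time, amylase_bbd())
#' optimize_response(fit)
#' @export
optimize_response <- function(object, bounds = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(inherits(object, "rsm_quad"))
  nm <- factor_names(object$factors)
  if (is.null(bounds))
    bounds <- lapply(object$factors, function(f) c(f$low, f$high))
  if (is.matrix(bounds)) bounds <- apply(bounds, 2L, identity, simplify = FALSE)
  if (!is.null(names(bounds)) && all(nm %in% names(bounds)))
    bounds <- bounds[nm]
  lo <- vapply(bounds, `[[`, numeric(1L), 1L)
  hi <- vapply(bounds, `[[`, numeric(1L), 2L)
  if (!all(is.finite(c(lo, hi))) || any(hi <= lo))
    stop("bounds must be finite with low < high", call. = FALSE)

  b <- object$coefficients
  a <- b[2:4]
  Q <- diag(b[5:7])
  Q[lower.tri(Q)] <- c(b[8L], b[9L], b[10L]) / 2
  Q <- Q + t(Q) - diag(diag(Q))
  sgn <- if (direction == "max") -1 else 1
  fn <- function(x) sgn * (b[1L] + sum(a * x) + drop(x %*% Q %*% x))
  gr <- function(x) sgn * (a + 2 * drop(Q %*% x))

  verts <- as.matrix(expand.grid(bounds))
  starts <- rbind(verts, (lo + hi) / 2)
  stat_pt <- NULL
  if (rcond(Q) > 1e-12) {
    stat_pt <- drop(solve(2 * Q, -a))
    starts <- rbind(starts, pmin(pmax(stat_pt, lo), hi))
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                      lower = lo, upper = hi)
    if (is.null(best) ||
        o$value < best$value * (1 - sign(best$value) * 1e-8) - 1e-12)
      best <- o
  }
  x <- pmin(pmax(best$par, lo), hi)
  names(x) <- nm
  tol <- 1e-6 * (hi - lo)
  boundary <- ifelse(x <= lo + tol, "at-low",
                     ifelse(x >= hi - tol, "at-high", "interior"))
  names(boundary) <- nm

  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  stat_class <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
                else "saddle"
  classification <- if (any(boundary != "interior")) "boundary" else stat_class

  coded <- tryCatch(encode_levels(x, object$factors),
                    error = function(e) stats::setNames(rep(NA_real_, 3L), nm))
  structure(list(actual = x, coded = coded, predicted = sgn * best$value,
                 boundary = boundary, classification = classification,
                 stationary_point = stat_pt, stationary_class = stat_class,
                 direction = direction, bounds = cbind(low = lo, high = hi)),
            class = "rsm_optimum")
}

#' @export
print.rsm_optimum <- function(x, ...) {
  cat(sprintf("Constrained %simum of the fitted surface\n",
              x$direction))
  for (i in seq_along(x$actual))
    cat(sprintf("  %-8s = %.4g (%s)\n", names(x$actual)[i], x$actual[i],
                x$boundary[i]))
  cat(sprintf("predicted response = %.4g (%s)\n", x$predicted,
              x$classification))
  invisible(x)
}

#' Plot-ready response-surface grid
#'
#' Evaluates the fitted surface on a rectangular grid over two factors,
#' holding the third fixed, for contour or surface plots.
#'
#' @param object An `rsm_quad` fit.
#' @param vary Character vector of two factor names to vary over their
#'   design ranges.
#' @param fix Value at which to hold the remaining factor (default: its
#'   center level).
#' @param resolution Grid points per varied axis (scalar or length 2).
#' @return A data frame with the two varied factors and `response`, plus
#'   attribute `"fixed"` (named value of the held factor).
#' @examples
#' fit <- rsm_quad(activity ~ cs + ga + time, amylase_bbd())
#' g <- surface_grid(fit, c("cs", "ga"), fix = 16, resolution = 21)
#' @export
surface_grid <- function(object, vary, fix = NULL, resolution = 50) {
  nm <- factor_names(object$factors)
  if (length(vary) != 2L || !all(vary %in% nm))
    stop("'vary' must name two of: ", paste(nm, collapse = ", "),
         call. = FALSE)
  other <- setdiff(nm, vary)
  fo <- object$factors[[other]]
  if (is.null(fix)) fix <- fo$center
  if (fix < fo$low || fix > fo$high)
    stop("fixed level ", fix, " outside the range of factor '", other, "'",
         call. = FALSE)
  resolution <- rep_len(as.integer(resolution), 2L)
  if (any(resolution < 1L)) stop("resolution must be >= 1", call. = FALSE)
  ax <- lapply(seq_len(2L), function(i) {
    f <- object$factors[[vary[i]]]
    seq(f$low, f$high, length.out = resolution[i])
  })
  g <- expand.grid(ax[[1L]], ax[[2L]])
  names(g) <- vary
  g[[other]] <- fix
  g$response <- as.numeric(predict(object, g[nm]))
  g <- g[c(vary, "response")]
  attr(g, "fixed") <- stats::setNames(fix, other)
  g
}
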