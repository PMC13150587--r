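#' Define a three-level design factor
#'
#' A factor for a three-level Box-Behnken design, carrying its low
#' (coded -1), center (coded 0) and high (coded +1) physical levels.
#' The three levels need not be equidistant: coded/actual conversion is
#' piecewise linear about the center level, so the coded labels of a
#' design table are always reproduced exactly even when the center is
#' not the numeric midpoint (e.g. binding times 6, 16, 24 h).
#'
#' @param name Factor name (column name in design tables).
#' @param low,center,high Physical levels mapped to coded -1, 0, +1.
#'   Must be finite and strictly increasing.
#' @param unit Unit string, for printing only.
#' @return An object of class `bbd_factor`.
#' @examples
#' bbd_factor("cs", 2, 2.5, 3, unit = "% w/v")
#' @export
bbd_factor <- function(name, low, center, high, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lv <- c(low = low, center = center, high = high)
  if (!all(is.finite(lv)))
    stop("levels of factor '", name, "' must be finite", call. = FALSE)
  if (!(low < center && center < high))
    stop("levels of factor '", name,
         "' must be strictly increasing (low < center < high)", call. = FALSE)
  structure(list(name = name, unit = unit,
                 low = low, center = center, high = high),
            class = "bbd_factor")
}

#' @export
print.bbd_factor <- function(x, ...) {
  cat(sprintf("factor %s%s: -1 = %g, 0 = %g, +1 = %g\n", x$name,
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
              x$low, x$center, x$high))
  invisible(x)
}

#' Bundle factors into a factor set
#'
#' @param ... `bbd_factor` objects (or a single list of them).
#' @return A named list of class `bbd_factors`.
#' @examples
#' bbd_factors(bbd_factor("a", 0, 1, 2), bbd_factor("b", 0, 2, 3),
#'             bbd_factor("c", 1, 2, 4))
#' @export
bbd_factors <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "bbd_factor")) fs <- fs[[1L]]
  if (!all(vapply(fs, inherits, logical(1L), "bbd_factor")))
    stop("all arguments must be bbd_factor objects", call. = FALSE)
  nm <- vapply(fs, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("duplicate factor names", call. = FALSE)
  names(fs) <- nm
  structure(fs, class = "bbd_factors")
}

#' @export
print.bbd_factors <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Factor set of the amylase immobilization study
#'
#' Chitosan concentration (% w/v), glutaraldehyde concentration (% v/v)
#' and enzyme binding time (h) at the levels of the 15-run
#' Box-Behnken immobilization experiment. Note the binding-time center
#' (16 h) is not the numeric midpoint of 6 and 24 h.
#'
#' @return A `bbd_factors` set with factors `cs`, `ga`, `time`.
#' @examples
#' amylase_factors()
#' @export
amylase_factors <- function() {
  bbd_factors(
    bbd_factor("cs",   2.0, 2.5, 3.0, unit = "% w/v"),
    bbd_factor("ga",   0.5, 1.0, 1.5, unit = "% v/v"),
    bbd_factor("time", 6,   16,  24,  unit = "h")
  )
}

factor_names <- function(factors) vapply(factors, `[[`, character(1L), "name")

#' Convert between coded and actual factor levels
#'
#' `decode_levels()` maps coded levels to actual units; `encode_levels()`
#' is its inverse. The map is piecewise linear about the center level:
#' coded c in [-1, 0] maps to `center + c * (center - low)`, c in [0, 1]
#' to `center + c * (high - center)`. This reproduces non-equidistant
#' level sets exactly and keeps the two functions mutual inverses.
#'
#' @param x A numeric vector of length 3, or a matrix/data.frame with one
#'   column per factor (columns matched by name when named).
#' @param factors A `bbd_factors` set.
#' @return Numeric vector or matrix of the same shape as `x`.
#' @examples
#' f <- amylase_factors()
#' decode_levels(c(1, 1, 0), f)        # c(3.0, 1.5, 16)
#' encode_levels(c(2.75, 1, 16), f)    # c(0.5, 0, 0)
#' @export
decode_levels <- function(x, factors) {
  map_levels(x, factors, decode = TRUE)
}

#' @rdname decode_levels
#' @export
encode_levels <- function(x, factors) {
  map_levels(x, factors, decode = FALSE)
}

map_levels <- function(x, factors, decode) {
  nm <- factor_names(factors)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L,
                       dimnames = list(NULL, if (!is.null(names(x))) names(x)))
       else as.matrix(x)
  if (ncol(m) != length(factors))
    stop("expected ", length(factors), " factor columns", call. = FALSE)
  if (!is.null(colnames(m)) && all(nm %in% colnames(m))) m <- m[, nm, drop = FALSE]
  out <- m
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    v <- m[, j]
    if (decode) {
      if (any(v < -1 - 1e-12 | v > 1 + 1e-12, na.rm = TRUE))
        stop("coded level out of [-1, 1] for factor '", f$name, "'",
             call. = FALSE)
      out[, j] <- ifelse(v < 0, f$center + v * (f$center - f$low),
                                f$center + v * (f$high - f$center))
    } else {
      if (any(v < f$low - 1e-9 | v > f$high + 1e-9, na.rm = TRUE))
        stop("actual value out of range [", f$low, ", ", f$high,
             "] for factor '", f$name, "'", call. = FALSE)
      out[, j] <- ifelse(v < f$center, (v - f$center) / (f$center - f$low),
                                       (v - f$center) / (f$high - f$center))
    }
  }
  colnames(out) <- nm
  if (vec) { out <- drop(out); names(out) <- nm }
  out
}

# Affine midrange coding: (x - (low+high)/2) / ((high-low)/2).  This is the
# coding conventional ANOVA software applies to a Box-Behnken design, and the
# space in which the adjusted (drop-term) sums of squares of the reference
# analysis are computed.  It differs from the piecewise label coding whenever
# the center level is off the midrange (binding time: (t - 15)/9).
midrange_code <- function(x, factors) {
  nm <- factor_names(factors)
  m <- as.matrix(x)
  if (!is.null(colnames(m)) && all(nm %in% colnames(m))) m <- m[, nm, drop = FALSE]
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    m[, j] <- (m[, j] - (f$low + f$high) / 2) / ((f$high - f$low) / 2)
  }
  colnames(m) <- nm
  m
}
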