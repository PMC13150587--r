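#' Generate a three-factor Box-Behnken design
#'
#' Builds the 12 edge-midpoint runs of the 3-factor Box-Behnken design
#' (all four +/-1 combinations over each factor pair with the third
#' factor at its center) followed by the requested number of center
#' runs. Run order is deterministic: factor pairs in lexicographic
#' order, (-1,-1), (-1,+1), (+1,-1), (+1,+1) within a pair, centers
#' last. No randomization is applied.
#'
#' @param factors A `bbd_factors` set of exactly 3 factors.
#' @param center_points Number of replicated center runs (>= 1).
#' @return A data frame of class `bbd_design` with columns `run`, one
#'   actual-unit column per factor, and one `<name>_coded` column per
#'   factor; the factor set is attached as attribute `"factors"`.
#' @examples
#' d <- bbd_design(amylase_factors(), center_points = 3)
#' nrow(d)  # 15
#' @export
bbd_design <- function(factors, center_points = 3) {
  if (!inherits(factors, "bbd_factors")) factors <- bbd_factors(factors)
  if (length(factors) != 3L)
    stop("only the 3-factor Box-Behnken design is supported (got ",
         length(factors), " factors)", call. = FALSE)
  if (center_points < 1 || center_points != round(center_points))
    stop("center_points must be a positive integer", call. = FALSE)

  pm <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  pm <- pm[order(pm[, 1], pm[, 2]), ]            # (-1,-1) (-1,1) (1,-1) (1,1)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L)) # lexicographic factor pairs
  coded <- matrix(0, nrow = 12L + center_points, ncol = 3L)
  r <- 0L
  for (p in pairs) for (i in 1:4) {
    r <- r + 1L
    coded[r, p] <- pm[i, ]
  }
  colnames(coded) <- factor_names(factors)
  actual <- decode_levels(coded, factors)
  new_bbd_design(coded, actual, factors)
}

new_bbd_design <- function(coded, actual, factors, response = NULL) {
  nm <- factor_names(factors)
  d <- data.frame(run = seq_len(nrow(coded)))
  d[nm] <- as.data.frame(actual)
  d[paste0(nm, "_coded")] <- as.data.frame(coded)
  if (!is.null(response)) d[names(response)] <- response
  attr(d, "factors") <- factors
  class(d) <- c("bbd_design", "data.frame")
  d
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("3-factor Box-Behnken design: %d runs (%d center)\n",
              nrow(x), sum(rowSums(abs(coded_matrix(x))) == 0)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

coded_matrix <- function(design) {
  factors <- design_factors(design)
  nm <- paste0(factor_names(factors), "_coded")
  if (all(nm %in% names(design)))
    return(as.matrix(design[nm]))
  encode_levels(design[factor_names(factors)], factors)
}

actual_matrix <- function(design, factors = design_factors(design)) {
  as.matrix(design[factor_names(factors)])
}

design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design carries no factor definitions; ",
                       "attach them with bbd_design()/read_design_csv()",
                       call. = FALSE)
  f
}

#' Validate the structure of a Box-Behnken design table
#'
#' Checks the defining invariants of a 3-factor Box-Behnken design:
#' coded entries in \{-1, 0, +1\}, each coded column sums to zero, every
#' non-center run has exactly one factor at its center, at least one
#' center run is present, and actual levels equal the decoded coded
#' labels.
#'
#' @param design A `bbd_design` data frame.
#' @return Invisibly `TRUE`; stops with a message on the first violated
#'   invariant.
#' @export
validate_bbd_design <- function(design) {
  factors <- design_factors(design)
  cm <- coded_matrix(design)
  if (!all(cm %in% c(-1, 0, 1)))
    stop("coded levels must be -1, 0 or +1", call. = FALSE)
  if (any(abs(colSums(cm)) > 1e-9))
    stop("coded columns must each sum to zero", call. = FALSE)
  nzero <- rowSums(cm == 0)
  center <- nzero == 3L
  if (!any(center)) stop("design must contain a center run", call. = FALSE)
  if (!all(nzero[!center] == 1L))
    stop("every non-center run of a 3-factor BBD must have exactly one ",
         "factor at its center level", call. = FALSE)
  am <- actual_matrix(design, factors)
  if (max(abs(am - decode_levels(cm, factors))) > 1e-9)
    stop("actual levels disagree with decoded coded labels", call. = FALSE)
  invisible(TRUE)
}

#' Read or write a design CSV
#'
#' The design CSV dialect has columns `run`, `<factor>_coded` and
#' `<factor>_actual` per factor, plus optional response columns
#' (UTF-8, header row, period decimal separator). In-memory designs
#' name the actual-unit column simply `<factor>`; the mapping is applied
#' on read/write.
#'
#' @param design A `bbd_design` data frame.
#' @param path File path.
#' @param factors Factor set; for `read_design_csv()`, when `NULL` the
#'   factor levels are inferred from each coded/actual column pair.
#' @return `read_design_csv()` returns a `bbd_design` data frame;
#'   `write_design_csv()` returns `path` invisibly.
#' @export
write_design_csv <- function(design, path) {
  factors <- design_factors(design)
  nm <- factor_names(factors)
  out <- design
  class(out) <- "data.frame"
  names(out)[match(nm, names(out))] <- paste0(nm, "_actual")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, factors = NULL) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"run" %in% names(d)) stop("design CSV must have a 'run' column",
                                 call. = FALSE)
  acts <- grep("_actual$", names(d), value = TRUE)
  if (is.null(factors)) {
    if (length(acts) == 0L)
      stop("cannot infer factors: no '<name>_actual' columns", call. = FALSE)
    fs <- lapply(acts, function(a) {
      nm <- sub("_actual$", "", a)
      cc <- d[[paste0(nm, "_coded")]]
      if (is.null(cc)) stop("missing coded column for factor '", nm, "'",
                            call. = FALSE)
      lv <- vapply(c(-1, 0, 1), function(k) {
        v <- unique(d[[a]][cc == k])
        if (length(v) != 1L)
          stop("inconsistent actual levels for factor '", nm, "'",
               call. = FALSE)
        v
      }, numeric(1L))
      bbd_factor(nm, lv[1L], lv[2L], lv[3L])
    })
    factors <- bbd_factors(fs)
  }
  nm <- factor_names(factors)
  names(d)[match(paste0(nm, "_actual"), names(d))] <- nm
  attr(d, "factors") <- factors
  class(d) <- c("bbd_design", "data.frame")
  d
}

#' The 15-run amylase immobilization design and responses
#'
#' The Box-Behnken design and measured specific activities (U/g) of the
#' alpha-amylase immobilization experiment on glutaraldehyde-activated
#' chitosan beads: three factors (chitosan % w/v, glutaraldehyde % v/v,
#' binding time h), 12 edge runs and 3 center replicates, in the
#' original run order. The `activity` column holds the measured
#' response; `predicted_reported` holds the study's reported model
#' predictions, which derive from the second-order equation with
#' coefficients rounded to printing precision — they are reproduced by
#' `round(eval_quadratic(truth_surface()$coefficients, d[c("cs", "ga",
#' "time")]))`, not by the exact OLS fit.
#'
#' The same table ships as a CSV fixture at
#' `system.file("extdata", "amylase_bbd.csv", package = "immobopt")`.
#'
#' @return A `bbd_design` data frame with 15 rows.
#' @examples
#' d <- amylase_bbd()
#' fit <- rsm_quad(activity ~ cs + ga + time, d)
#' @export
amylase_bbd <- function() {
  factors <- amylase_factors()
  coded <- matrix(c(
     1,  1,  0,
     1,  0,  1,
     0,  0,  0,
     0, -1,  1,
    -1,  0,  1,
    -1,  0, -1,
     1, -1,  0,
     0,  1,  1,
     0, -1, -1,
     0,  0,  0,
    -1, -1,  0,
     0,  1, -1,
    -1,  1,  0,
     0,  0,  0,
     1,  0, -1), ncol = 3L, byrow = TRUE,
    dimnames = list(NULL, factor_names(factors)))
  activity <- c(86, 308, 217, 480, 540, 477, 214, 473, 690, 222,
                366, 462, 329, 284, 483)
  predicted <- c(96, 275, 239, 482, 546, 502, 235, 488, 672, 239,
                 352, 454, 304, 239, 476)
  new_bbd_design(coded, decode_levels(coded, factors), factors,
                 response = list(activity = activity,
                                 predicted_reported = predicted))
}
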