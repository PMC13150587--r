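#' Immobilized enzyme load
#'
#' Mass of enzyme bound per gram of support, from the depletion of
#' protein in the coupling solution:
#' \eqn{IE = V (C_i - C_f) / m}.
#' With `V` in mL and concentrations in mg/mL the natural unit is mg of
#' enzyme per g of support; set `as_g_per_g = TRUE` to convert to g/g
#' (the unit used when dividing a bead activity by the load). The unit
#' is attached as attribute `"unit"`.
#'
#' @param V Volume of enzyme solution (mL).
#' @param Ci,Cf Initial and final protein concentration (mg/mL).
#' @param m Support mass (g), > 0.
#' @param as_g_per_g Report in g per g of support instead of mg/g.
#' @return Enzyme load with attribute `"unit"`; if `Cf > Ci` the value
#'   is negative and flagged with attribute `"negative_binding"` and a
#'   warning (not an error).
#' @examples
#' immobilized_amount(V = 10, Ci = 0.5, Cf = 0.05, m = 1)  # 4.5 mg/g
#' @export
immobilized_amount <- function(V, Ci, Cf, m, as_g_per_g = FALSE) {
  stopifnot_scalar(V, "V"); stopifnot_scalar(Ci, "Ci")
  stopifnot_scalar(Cf, "Cf"); stopifnot_scalar(m, "m", positive = TRUE)
  if (any(c(V, Ci, Cf) < 0))
    stop("V, Ci and Cf must be non-negative", call. = FALSE)
  ie <- V * (Ci - Cf) / m
  if (as_g_per_g) ie <- ie / 1000
  attr(ie, "unit") <- if (as_g_per_g) "g/g support" else "mg/g support"
  if (Cf > Ci) {
    attr(ie, "negative_binding") <- TRUE
    warning("final concentration exceeds initial: negative apparent binding")
  }
  ie
}

#' Specific activity of an immobilized preparation
#'
#' Bead activity per mass of bound enzyme: \eqn{EA / IE}. With EA in
#' U per g of beads and IE in g of enzyme per g of beads the result is
#' U per g of enzyme.
#'
#' @param EA Enzymatic activity of the beads (U/g beads), >= 0.
#' @param IE Immobilized enzyme load (g enzyme / g beads), > 0.
#' @return Specific activity (U per g of enzyme).
#' @examples
#' specific_activity(EA = 450, IE = 0.005)  # 90000
#' @export
specific_activity <- function(EA, IE) {
  stopifnot_scalar(EA, "EA"); stopifnot_scalar(IE, "IE", positive = TRUE)
  if (EA < 0) stop("EA must be non-negative", call. = FALSE)
  EA / IE
}

#' Immobilization yield
#'
#' Percentage of the initial solution activity removed from the
#' supernatant by binding: \eqn{IY = 100 (EA_0 - EA_f) / EA_0}.
#'
#' @param EA0 Initial solution activity (> 0).
#' @param EAf Final supernatant activity (same units).
#' @return Yield in percent; `EAf > EA0` gives a negative yield with a
#'   warning flag rather than an error.
#' @examples
#' immobilization_yield(100, 10)  # 90
#' @export
immobilization_yield <- function(EA0, EAf) {
  stopifnot_scalar(EA0, "EA0", positive = TRUE)
  stopifnot_scalar(EAf, "EAf")
  iy <- (EA0 - EAf) * 100 / EA0
  if (EAf > EA0) warning("final activity exceeds initial: negative yield")
  iy
}

#' Fit first-order thermal deactivation
#'
#' Single-exponential (first-order) deactivation
#' \eqn{A(t) = A_0 e^{-k_d t}} fitted by unweighted least squares on the
#' log scale: the slope of \eqn{\ln A} on \eqn{t} is \eqn{-k_d}, and the
#' half-life is \eqn{t_{1/2} = \ln 2 / k_d}. Non-positive activities are
#' excluded with a warning (their log is undefined).
#'
#' @param time Times (h), strictly increasing.
#' @param activity Activities (raw or percent), same length.
#' @return An object of class `deactivation_fit`: `k_d` (1/h),
#'   `half_life` (h; `Inf` for a non-decaying series), `intercept` (log
#'   initial activity), `r_squared` of the log-linear fit, `n_used`,
#'   `time_range`.
#' @examples
#' t <- 0:20
#' fit_deactivation(t, 100 * exp(-0.0429 * t))  # k_d = 0.0429, t1/2 = 16.2 h
#' @export
fit_deactivation <- function(time, activity) {
  stopifnot(length(time) == length(activity))
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  keep <- activity > 0
  if (!all(keep)) {
    warning(sum(!keep), " non-positive activity point(s) excluded ",
            "(log undefined)")
    time <- time[keep]; activity <- activity[keep]
  }
  if (length(time) < 3L)
    stop("need at least 3 usable (positive-activity) points", call. = FALSE)
  ly <- log(activity)
  fit <- stats::lm(ly ~ time)
  slope <- unname(stats::coef(fit)[2L])
  kd <- -slope
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  structure(list(k_d = kd,
                 half_life = if (kd > 0) log(2) / kd else Inf,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_used = length(time),
                 time_range = range(time)),
            class = "deactivation_fit")
}

#' @export
print.deactivation_fit <- function(x, ...) {
  cat(sprintf(
    "First-order deactivation: k_d = %.4g /h, t1/2 = %.3g h (R-sq %.3f, n = %d)\n",
    x$k_d, x$half_life, x$r_squared, x$n_used))
  invisible(x)
}

#' Stabilization factor of an immobilized enzyme
#'
#' Ratio of the immobilized to the free half-life,
#' \eqn{SF = t_{1/2}(immobilized) / t_{1/2}(free)}. Accepts
#' [fit_deactivation()] results or plain half-lives in hours.
#'
#' @param free,immobilized `deactivation_fit` objects or numeric
#'   half-lives (h).
#' @return A list of class `stability_comparison` with `free`,
#'   `immobilized` and `SF`.
#' @examples
#' stabilization_factor(16.2, 34.7)$SF  # 2.14
#' @export
stabilization_factor <- function(free, immobilized) {
  hl <- function(x) if (inherits(x, "deactivation_fit")) x$half_life
                    else stopifnot_scalar(x, "half-life")
  t_free <- hl(free); t_imm <- hl(immobilized)
  if (!is.finite(t_free) || t_free <= 0)
    stop("free half-life must be finite and > 0", call. = FALSE)
  structure(list(free = free, immobilized = immobilized,
                 SF = t_imm / t_free),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat(sprintf("stabilization factor SF = %.3g\n", x$SF))
  invisible(x)
}

#' Residual-activity profile over reuse cycles
#'
#' Expresses per-cycle activities as percentages of the first cycle
#' (defined as 100%), the standard reusability summary.
#'
#' @param activity Activities per cycle, cycle 1 first; `activity[1]`
#'   must be > 0.
#' @return A data frame of class `cycle_profile` with `cycle`,
#'   `activity`, `residual_pct`.
#' @examples
#' cycle_profile(c(200, 120, 100))$residual_pct  # 100 60 50
#' @export
cycle_profile <- function(activity) {
  if (length(activity) < 1L) stop("need at least one cycle", call. = FALSE)
  if (!is.finite(activity[1L]) || activity[1L] <= 0)
    stop("cycle-1 activity must be > 0", call. = FALSE)
  out <- data.frame(cycle = seq_along(activity), activity = activity,
                    residual_pct = 100 * activity / activity[1L])
  class(out) <- c("cycle_profile", "data.frame")
  out
}
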