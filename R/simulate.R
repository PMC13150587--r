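#' Quadratic truth surface for simulation
#'
#' The generating model of the synthetic-data module: a 10-coefficient
#' quadratic in actual units plus Gaussian replicate noise. The defaults
#' are the reported second-order equation of the amylase immobilization
#' study (coefficients at printing precision) and a replicate standard
#' deviation of sqrt(1393) = 37.3 U/g, the pooled pure-error mean square
#' of its ANOVA — the study's own estimate of replicate variability. The
#' generator models lab replicate error as Gaussian; the uniform noise
#' of [augment_replicates()] is a separate, downstream procedure.
#'
#' @param coefficients Length-10 coefficient vector (canonical order:
#'   intercept, linear, quadratic, interactions 1:2, 1:3, 2:3).
#' @param factors A `bbd_factors` set (default [amylase_factors()]).
#' @param noise_sd Replicate noise standard deviation (>= 0).
#' @return A list of class `truth_surface`.
#' @examples
#' truth_surface()
#' @export
truth_surface <- function(coefficients = c(238, 812, -393, -72.6, -133,
                                           164.0, 2.999, -91.0, -13.66,
                                           12.42),
                          factors = amylase_factors(),
                          noise_sd = sqrt(1393)) {
  stopifnot(length(coefficients) == 10L, all(is.finite(coefficients)))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!inherits(factors, "bbd_factors")) factors <- bbd_factors(factors)
  M <- quad_model_matrix(matrix(0, 1L, 3L,
                                dimnames = list(NULL, factor_names(factors))))
  coefficients <- stats::setNames(as.numeric(coefficients), colnames(M))
  structure(list(coefficients = coefficients, factors = factors,
                 noise_sd = noise_sd), class = "truth_surface")
}

#' @export
print.truth_surface <- function(x, ...) {
  cat("Quadratic truth surface, replicate noise sd =", x$noise_sd, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Simulate a replicated Box-Behnken dataset
#'
#' Generates the statistical structure the analysis assumes: for each
#' run of the 3-factor Box-Behnken design, `replicates` responses equal
#' to the truth-surface prediction plus independent zero-mean Gaussian
#' noise. Negative draws are floored at 0 and counted in the `"floored"`
#' attribute (kept auditable rather than resampled).
#'
#' @param truth A [truth_surface()].
#' @param replicates Replicates per run (>= 1).
#' @param seed Integer seed.
#' @param center_points Center runs in the design (default 3).
#' @return A data frame with columns `run`, the three factors (actual
#'   units), `rep` and `activity`; the factor set, truth and seed are
#'   attached as attributes.
#' @examples
#' reps <- simulate_bbd_dataset(truth_surface(), replicates = 3, seed = 1)
#' table(reps$run)
#' @export
simulate_bbd_dataset <- function(truth = truth_surface(), replicates = 3,
                                 seed = NULL, center_points = 3) {
  stopifnot(inherits(truth, "truth_surface"))
  if (replicates < 1 || replicates != round(replicates))
    stop("replicates must be a positive integer", call. = FALSE)
  des <- bbd_design(truth$factors, center_points = center_points)
  nm <- factor_names(truth$factors)
  mu <- eval_quadratic(truth$coefficients, des[nm])
  n <- nrow(des)
  out <- with_seed(seed, {
    d <- des[rep(seq_len(n), each = replicates), c("run", nm)]
    d$rep <- rep(seq_len(replicates), times = n)
    d$activity <- rep(mu, each = replicates) +
      stats::rnorm(n * replicates, sd = truth$noise_sd)
    d
  })
  floored <- out$activity < 0
  out$activity[floored] <- 0
  rownames(out) <- NULL
  attr(out, "factors") <- truth$factors
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  attr(out, "floored") <- sum(floored)
  out
}

#' Simulate a first-order decay series
#'
#' \eqn{A(t) = A_0 e^{-k_d t} e^{\epsilon}} with
#' \eqn{\epsilon \sim N(0, sd_{log}^2)}, emulating thermal-stability
#' time courses with multiplicative (log-normal) measurement noise.
#'
#' @param k_d Inactivation constant (1/h), >= 0.
#' @param A0 Initial activity, > 0.
#' @param times Time points (h), >= 0.
#' @param sd_log Log-scale noise sd (0 for an exact series).
#' @param seed Integer seed.
#' @return A data frame with `time_h` and `activity`.
#' @examples
#' simulate_decay(0.0429, 100, 0:5)
#' @export
simulate_decay <- function(k_d, A0 = 100, times = 0:20, sd_log = 0,
                           seed = NULL) {
  stopifnot_scalar(k_d, "k_d"); stopifnot_scalar(A0, "A0", positive = TRUE)
  if (k_d < 0) stop("k_d must be >= 0", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  a <- with_seed(seed,
    A0 * exp(-k_d * times) * exp(stats::rnorm(length(times), sd = sd_log)))
  data.frame(time_h = times, activity = a)
}

#' Simulate a reuse-cycle activity profile
#'
#' Geometric per-cycle retention with multiplicative log-normal noise:
#' cycle n has mean activity \eqn{A_0 \cdot retention^{n-1}}, so the
#' noise-free residual profile is exactly
#' \eqn{100 \cdot retention^{n-1}} percent.
#'
#' @param retention Per-cycle retained fraction, in (0, 1].
#' @param cycles Number of cycles (>= 1).
#' @param A0 First-cycle activity.
#' @param sd_log Log-scale noise sd.
#' @param seed Integer seed.
#' @return A data frame with `cycle` and `activity`.
#' @examples
#' cycle_profile(simulate_reuse_profile(0.933, 10)$activity)
#' @export
simulate_reuse_profile <- function(retention, cycles = 10, A0 = 100,
                                   sd_log = 0, seed = NULL) {
  stopifnot_scalar(retention, "retention")
  if (retention <= 0 || retention > 1)
    stop("retention must be in (0, 1]", call. = FALSE)
  if (cycles < 1 || cycles != round(cycles))
    stop("cycles must be a positive integer", call. = FALSE)
  a <- with_seed(seed,
    A0 * retention^(seq_len(cycles) - 1) *
      exp(stats::rnorm(cycles, sd = sd_log)))
  data.frame(cycle = seq_len(cycles), activity = a)
}
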