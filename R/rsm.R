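#' Fit a full second-order response-surface model
#'
#' Ordinary least squares fit of the 10-term quadratic
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'       \sum_{i<j} \beta_{ij} x_i x_j}
#' in actual (uncoded) factor units, the standard response-surface model
#' for a three-factor Box-Behnken experiment.
#'
#' @param formula A formula `response ~ f1 + f2 + f3` naming the response
#'   and the three factors; the quadratic and interaction expansion is
#'   implied.
#' @param data A data frame (typically a [bbd_design()] with a response
#'   column) holding the named columns in actual units.
#' @param factors Optional `bbd_factors` set. Defaults to the set
#'   attached to `data`, else levels are inferred per factor from its
#'   three distinct values (low/center/high in increasing order).
#' @return An object of class `rsm_quad` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted`, `anova`, `plot` and
#'   `simulate`, plus [fit_stats()], [optimize_response()] and
#'   [surface_grid()].
#' @examples
#' fit <- rsm_quad(activity ~ cs + ga + time, amylase_bbd())
#' coef(fit)
#' predict(fit, data.frame(cs = 2.5, ga = 0.5, time = 6))
#' @export
rsm_quad <- function(formula, data, factors = NULL) {
  tt <- stats::terms(formula, data = data)
  if (attr(tt, "response") != 1L)
    stop("formula must have a response", call. = FALSE)
  vars <- as.character(attr(tt, "variables"))[-1L]
  response <- vars[1L]
  preds <- vars[-1L]
  if (length(preds) != 3L)
    stop("exactly 3 factors are required on the right-hand side",
         call. = FALSE)
  if (!all(c(response, preds) %in% names(data)))
    stop("data is missing columns: ",
         paste(setdiff(c(response, preds), names(data)), collapse = ", "),
         call. = FALSE)
  y <- data[[response]]
  if (anyNA(y) || !is.numeric(y))
    stop("response must be numeric with no missing values", call. = FALSE)
  X <- as.matrix(data[preds])
  if (anyNA(X)) stop("factor columns contain missing values", call. = FALSE)
  n <- nrow(X)
  if (n < 10L) stop("at least 10 runs are needed to fit the 10-term ",
                    "quadratic model", call. = FALSE)

  if (is.null(factors)) factors <- attr(data, "factors")
  if (is.null(factors)) factors <- infer_factors(X)
  if (!setequal(unname(factor_names(factors)), preds))
    stop("factor definitions do not match the formula terms", call. = FALSE)
  factors <- factors[preds]
  class(factors) <- "bbd_factors"

  M <- quad_model_matrix(X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop("singular design: the second-order model matrix is rank deficient",
         call. = FALSE)
  beta <- qr.coef(qrM, y)
  res <- as.numeric(qr.resid(qrM, y))
  df_res <- n - ncol(M)
  sigma2 <- sum(res^2) / df_res

  structure(list(
    coefficients = beta,
    residuals = res,
    fitted.values = y - res,
    qr = qrM,
    sigma2 = sigma2,
    df.residual = df_res,
    X = X, y = y,
    response = response,
    factors = factors,
    call = match.call()
  ), class = "rsm_quad")
}

infer_factors <- function(X) {
  fs <- lapply(colnames(X), function(nm) {
    lv <- sort(unique(X[, nm]))
    if (length(lv) != 3L)
      stop("cannot infer levels of factor '", nm, "': expected exactly 3 ",
           "distinct values; pass `factors` explicitly", call. = FALSE)
    bbd_factor(nm, lv[1L], lv[2L], lv[3L])
  })
  bbd_factors(fs)
}

# Full second-order model matrix: intercept, 3 linear, 3 quadratic,
# 3 interaction columns, in that canonical order.
quad_model_matrix <- function(X) {
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  M <- cbind(1, X, X^2,
             X[, 1L] * X[, 2L], X[, 1L] * X[, 3L], X[, 2L] * X[, 3L])
  colnames(M) <- c("(Intercept)", nm, paste0(nm, "^2"),
                   paste(nm[c(1L, 1L, 2L)], nm[c(2L, 3L, 3L)], sep = ":"))
  M
}

#' Evaluate a 10-coefficient quadratic at actual-unit points
#'
#' Evaluates the full second-order polynomial given its coefficient
#' vector in canonical order (intercept; three linear; three quadratic;
#' interactions 1:2, 1:3, 2:3), e.g. a fitted or published coefficient
#' set.
#'
#' @param coefficients Numeric vector of length 10.
#' @param points Data frame or matrix of points (3 columns, actual units).
#' @return Numeric vector of predicted responses.
#' @examples
#' eval_quadratic(coef(rsm_quad(activity ~ cs + ga + time, amylase_bbd())),
#'                data.frame(cs = 2.5, ga = 1, time = 16))
#' @export
eval_quadratic <- function(coefficients, points) {
  stopifnot(length(coefficients) == 10L)
  P <- as.matrix(points)
  if (ncol(P) != 3L) stop("points must have 3 columns", call. = FALSE)
  drop(quad_model_matrix(P) %*% as.numeric(coefficients))
}

#' @export
coef.rsm_quad <- function(object, ...) object$coefficients

#' @export
residuals.rsm_quad <- function(object, ...) object$residuals

#' @export
fitted.rsm_quad <- function(object, ...) object$fitted.values

leverages <- function(object) {
  Q <- qr.Q(object$qr)
  rowSums(Q^2)
}

#' @export
vcov.rsm_quad <- function(object, ...) {
  R <- qr.R(object$qr)
  V <- chol2inv(R) * object$sigma2
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' Predict from a fitted response-surface model
#'
#' @param object An `rsm_quad` fit.
#' @param newdata Data frame or 3-column matrix of actual-unit points;
#'   omitted for fitted values. Points outside the design box are
#'   evaluated but flagged in the `"extrapolated"` attribute of the
#'   result.
#' @param ... Unused.
#' @return Numeric vector of predictions with attribute `"extrapolated"`
#'   (logical, per point).
#' @export
predict.rsm_quad <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fitted.values)
  nm <- factor_names(object$factors)
  P <- as.matrix(if (is.data.frame(newdata)) newdata[nm] else newdata)
  colnames(P) <- nm
  if (!all(is.finite(P))) stop("prediction points must be finite",
                               call. = FALSE)
  out <- eval_quadratic(object$coefficients, P)
  lo <- vapply(object$factors, `[[`, numeric(1L), "low")
  hi <- vapply(object$factors, `[[`, numeric(1L), "high")
  extra <- rowSums(sweep(P, 2L, lo, `<`) | sweep(P, 2L, hi, `>`)) > 0
  attr(out, "extrapolated") <- unname(extra)
  out
}

#' @export
print.rsm_quad <- function(x, digits = 4, ...) {
  b <- x$coefficients
  nm <- names(b)[-1L]
  eq <- paste0(signif(b[1L], digits),
               paste0(ifelse(b[-1L] >= 0, " + ", " - "),
                      signif(abs(b[-1L]), digits), "*", nm, collapse = ""))
  cat("Second-order response-surface model (actual units)\n")
  cat(x$response, "=", eq, "\n")
  cat(sprintf("n = %d, residual SD = %.4g on %d df\n",
              length(x$y), sqrt(x$sigma2), x$df.residual))
  invisible(x)
}

#' @export
summary.rsm_quad <- function(object, ...) {
  se <- sqrt(diag(vcov(object)))
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(abs(tval), object$df.residual, lower.tail = FALSE)
  ct <- cbind(Estimate = object$coefficients, `Std. Error` = se,
              `t value` = tval, `Pr(>|t|)` = pval)
  structure(list(call = object$call, coefficients = ct,
                 stats = fit_stats(object), df.residual = object$df.residual),
            class = "summary.rsm_quad")
}

#' @export
print.summary.rsm_quad <- function(x, ...) {
  cat("Call:\n"); print(x$call); cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  cat("\n"); print(x$stats)
  invisible(x)
}

#' Goodness-of-fit summary of a response-surface model
#'
#' R-squared, adjusted R-squared, the PRESS statistic (sum of squared
#' leave-one-out prediction residuals, computed from leverages as
#' \eqn{\sum_i (e_i/(1-h_{ii}))^2}) and the PRESS-based predicted
#' R-squared \eqn{1 - PRESS/SS_{total}}.
#'
#' @param object An `rsm_quad` fit.
#' @return A list of class `rsm_fit_stats` with elements `r_squared`,
#'   `adj_r_squared`, `pred_r_squared`, `press` and `root_mse`.
#' @examples
#' fit_stats(rsm_quad(activity ~ cs + ga + time, amylase_bbd()))
#' @export
fit_stats <- function(object) {
  stopifnot(inherits(object, "rsm_quad"))
  y <- object$y
  sst <- sum((y - mean(y))^2)
  sse <- sum(object$residuals^2)
  h <- leverages(object)
  if (any(h >= 1 - 1e-10))
    stop("PRESS undefined: a run has leverage 1 (its removal makes the ",
         "fit interpolate it)", call. = FALSE)
  press <- sum((object$residuals / (1 - h))^2)
  n <- length(y)
  structure(list(
    r_squared = 1 - sse / sst,
    adj_r_squared = 1 - (sse / object$df.residual) / (sst / (n - 1)),
    pred_r_squared = 1 - press / sst,
    press = press,
    root_mse = sqrt(sse / object$df.residual)
  ), class = "rsm_fit_stats")
}

#' @export
print.rsm_fit_stats <- function(x, ...) {
  cat(sprintf(
    "R-sq = %.4f, adj R-sq = %.4f, pred R-sq (PRESS) = %.4f\n",
    x$r_squared, x$adj_r_squared, x$pred_r_squared))
  cat(sprintf("PRESS = %.4g, root MSE = %.4g\n", x$press, x$root_mse))
  invisible(x)
}

#' @export
simulate.rsm_quad <- function(object, nsim = 1, seed = NULL, ...) {
  out <- with_seed(seed, {
    n <- length(object$y)
    matrix(object$fitted.values, n, nsim) +
      matrix(stats::rnorm(n * nsim, sd = sqrt(object$sigma2)), n, nsim)
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.rsm_quad <- function(x, vary = factor_names(x$factors)[1:2], fix = NULL,
                          resolution = 60, ...) {
  g <- surface_grid(x, vary = vary, fix = fix, resolution = resolution)
  z <- matrix(g$response, nrow = length(unique(g[[1L]])))
  graphics::filled.contour(
    unique(g[[1L]]), unique(g[[2L]]), z,
    xlab = vary[1L], ylab = vary[2L],
    main = sprintf("Predicted %s (%s = %g)", x$response,
                   names(attr(g, "fixed")), attr(g, "fixed")),
    color.palette = grDevices::hcl.colors, ...)
  invisible(g)
}
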