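#' ANOVA for a response-surface model
#'
#' Adjusted (drop-term) analysis of variance for the 10-term quadratic
#' fit, in the layout conventional for Box-Behnken analyses: the model
#' row, group rows for the linear, square and two-way interaction terms,
#' individual term rows, and the residual split into lack-of-fit
#' (between distinct design points) and pure error (within replicated
#' points).
#'
#' Term and group sums of squares are adjusted: the increase in residual
#' SS when the term (or the group's three terms) is dropped from the
#' full model, so within-group term SS need not add up to the group SS.
#' F for terms and groups is MS over the residual MS; the lack-of-fit F
#' is MS(lack-of-fit) over MS(pure error). Replicates are detected as
#' runs with exactly equal actual factor levels; without replicated runs
#' the lack-of-fit rows are omitted.
#'
#' @section Unit space:
#' The residual, model, lack-of-fit and pure-error rows (hence the model
#' F, R-squared family and lack-of-fit test) are identical in any
#' nondegenerate reparameterization of the 10-term model space. The
#' per-term adjusted SS are not: dropping a linear term from a quadratic
#' in actual units spans a different subspace than in coded units.
#' `space = "coded"` (default) computes the drop-term SS on affine
#' midrange-coded factors (\eqn{(x - (low+high)/2)/((high-low)/2)}), the
#' convention of standard response-surface software; `space = "actual"`
#' uses raw units.
#'
#' @param object An `rsm_quad` fit.
#' @param space `"coded"` (midrange-coded, default) or `"actual"`.
#' @param ... Unused.
#' @return A data frame of class `rsm_anova` with columns `Source`,
#'   `DF`, `SS`, `MS`, `F` and `p` (exact values; the print method
#'   displays p below 0.0005 as "0.000").
#' @examples
#' fit <- rsm_quad(activity ~ cs + ga + time, amylase_bbd())
#' anova(fit)
#' @export
anova.rsm_quad <- function(object, space = c("coded", "actual"), ...) {
  space <- match.arg(space)
  if (object$df.residual < 1L)
    stop("no residual degrees of freedom: ANOVA diagnostics unavailable",
         call. = FALSE)
  y <- object$y
  n <- length(y)
  Xs <- if (space == "coded") midrange_code(object$X, object$factors)
        else object$X
  M <- quad_model_matrix(Xs)
  sse <- sum(qr.resid(qr(M), y)^2)
  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  mse <- sse / object$df.residual

  drop_ss <- function(cols) sum(qr.resid(qr(M[, -cols, drop = FALSE]), y)^2) - sse
  nm <- colnames(M)
  groups <- list(Linear = 2:4, Square = 5:7, `2-way interaction` = 8:10)

  src <- "Model"; df <- 9L; ss <- ssm
  for (g in names(groups)) {
    cols <- groups[[g]]
    src <- c(src, g, nm[cols])
    df <- c(df, 3L, rep(1L, 3L))
    ss <- c(ss, drop_ss(cols), vapply(cols, drop_ss, numeric(1L)))
  }
  ms <- ss / df
  f <- ms / mse
  p <- stats::pf(f, df, object$df.residual, lower.tail = FALSE)

  tab <- data.frame(Source = src, DF = df, SS = ss, MS = ms, F = f, p = p,
                    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(Source = "Error", DF = object$df.residual,
                               SS = sse, MS = mse, F = NA, p = NA))

  grp <- interaction(as.data.frame(object$X), drop = TRUE)
  within_ss <- tapply(y, grp, function(v) sum((v - mean(v))^2))
  df_pe <- sum(tapply(y, grp, length) - 1L)
  if (df_pe > 0L) {
    sspe <- sum(within_ss)
    sslof <- sse - sspe
    df_lof <- object$df.residual - df_pe
    if (df_lof > 0L) {
      f_lof <- (sslof / df_lof) / (sspe / df_pe)
      tab <- rbind(tab, data.frame(
        Source = "Lack-of-fit", DF = df_lof, SS = sslof, MS = sslof / df_lof,
        F = f_lof, p = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)))
    }
    tab <- rbind(tab, data.frame(Source = "Pure error", DF = df_pe,
                                 SS = sspe, MS = sspe / df_pe, F = NA, p = NA))
  }
  tab <- rbind(tab, data.frame(Source = "Total", DF = n - 1L, SS = sst,
                               MS = NA, F = NA, p = NA))
  attr(tab, "space") <- space
  attr(tab, "replicated") <- df_pe > 0L
  class(tab) <- c("rsm_anova", "data.frame")
  tab
}

#' @export
print.rsm_anova <- function(x, ...) {
  fmt <- function(v, digits = NULL) vapply(v, function(z) {
    if (is.na(z)) return("")
    formatC(z, format = "f", big.mark = ",",
            digits = if (is.null(digits)) (if (abs(z) >= 100) 0 else 2)
                     else digits)
  }, character(1L))
  out <- data.frame(Source = x$Source, DF = x$DF, SS = fmt(x$SS),
                    MS = fmt(x$MS), `F` = fmt(x$F, 2), p = fmt(x$p, 3),
                    check.names = FALSE)
  out$p[!is.na(x$p) & x$p < 5e-4] <- "0.000"
  cat(sprintf("ANOVA for the second-order model (%s units)\n",
              attr(x, "space")))
  print(out, row.names = FALSE, right = TRUE)
  if (!attr(x, "replicated"))
    cat("(no replicated design points: lack-of-fit not separable)\n")
  invisible(x)
}
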