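#' Specify a benchmark regressor
#'
#' Model specification for the three regression families benchmarked on
#' augmented immobilization data: support vector regression with an RBF
#' kernel (`"svr"`), Gaussian process regression with a squared-
#' exponential kernel (`"gpr"`), and random forest regression (`"rfr"`).
#'
#' Defaults (all overridable through `...`):
#' \itemize{
#' \item svr: epsilon-insensitive regression on standardized features
#'   and target; seeded grid search with internal 5-fold CV over
#'   cost \{1, 10, 100\} x gamma (1/p scale heuristic x \{0.5, 1, 2\}) x
#'   epsilon \{0.01, 0.1, 1\} (in units of the standardized target sd).
#' \item gpr: squared-exponential kernel on standardized features;
#'   signal variance, length-scale and noise variance learned by
#'   marginal-likelihood optimization (length-scale init 1.0, 5 seeded
#'   restarts).
#' \item rfr: 100 bootstrapped regression trees on raw features, all
#'   features eligible at every split and trees grown to
#'   single-observation leaves (`ntree`, `mtry`, `nodesize`, `replace`,
#'   `maxnodes` pass through to [randomForest::randomForest()]).
#' }
#'
#' @param family `"svr"`, `"gpr"` or `"rfr"`.
#' @param ... Family-specific hyperparameter overrides (see Details).
#' @return A list of class `ml_spec`.
#' @examples
#' ml_spec("rfr", ntree = 200)
#' @export
ml_spec <- function(family = c("svr", "gpr", "rfr"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    svr = list(cost = c(1, 10, 100), gamma_mult = c(0.5, 1, 2),
               epsilon = c(0.01, 0.1, 1), folds = 5L),
    gpr = list(restarts = 5L),
    rfr = list(ntree = 100L, replace = TRUE, nodesize = 1L,
               mtry = NULL, maxnodes = NULL, sampsize = NULL))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown ", family, " hyperparameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(list(family = family, params = defaults), class = "ml_spec")
}

#' Train a benchmark regressor
#'
#' Trains the regressor described by an [ml_spec()] on the three factor
#' columns of a (typically augmented) dataset. Kernel models (svr, gpr)
#' standardize features (and svr the target) with scalers fitted on the
#' training data only; the forest uses raw features. Training is fully
#' reproducible from `seed`.
#'
#' @param spec An `ml_spec` (or family string).
#' @param data Training data frame with factor columns and response.
#' @param response Response column name.
#' @param factors Factor column names (default: attached factor set,
#'   else all columns except `response`, `source_run`, `sample_id`).
#' @param seed Integer seed; recorded on the handle even for
#'   deterministic families.
#' @return An object of class `ml_model` with a `predict` method.
#' @examples
#' reps <- simulate_bbd_dataset(truth_surface(), seed = 1)
#' aug <- augment_replicates(reps, 200, seed = 2)
#' m <- train_regressor("rfr", aug, seed = 3)
#' predict(m, data.frame(cs = 2.5, ga = 0.5, time = 6))
#' @export
train_regressor <- function(spec, data, response = "activity",
                            factors = NULL, seed = NULL) {
  if (is.character(spec)) spec <- ml_spec(spec)
  stopifnot(inherits(spec, "ml_spec"))
  if (is.null(factors)) {
    fs <- attr(data, "factors")
    factors <- if (!is.null(fs)) factor_names(fs)
               else setdiff(names(data), c(response, "source_run",
                                           "sample_id", "run", "rep"))
  }
  if (nrow(data) == 0L) stop("empty training set", call. = FALSE)
  X <- as.matrix(data[factors])
  y <- data[[response]]
  if (is.null(y)) stop("missing response column '", response, "'",
                       call. = FALSE)
  degenerate <- stats::sd(y) == 0
  if (degenerate) warning("constant training target: degenerate fit")

  fit <- switch(spec$family,
    svr = svr_train(X, y, spec$params, seed),
    gpr = gpr_fit(X, y, restarts = spec$params$restarts, seed = seed),
    rfr = with_seed(seed, {
      p <- spec$params
      randomForest::randomForest(
        X, y, ntree = p$ntree, replace = p$replace, nodesize = p$nodesize,
        mtry = if (is.null(p$mtry)) ncol(X) else p$mtry,
        maxnodes = p$maxnodes,
        sampsize = if (is.null(p$sampsize)) {
          if (p$replace) nrow(X) else ceiling(0.632 * nrow(X))
        } else p$sampsize)
    }))
  structure(list(family = spec$family, spec = spec, fit = fit,
                 factors = factors, response = response, seed = seed,
                 degenerate = degenerate,
                 train_fingerprint = c(n = nrow(X), y_sum = sum(y))),
            class = "ml_model")
}

# Seeded grid search with k-fold CV for the RBF-kernel SVR; features and
# target standardized with train-only scalers.
svr_train <- function(X, y, params, seed) {
  xc <- colMeans(X); xs <- apply(X, 2L, stats::sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2L, xc), 2L, xs, `/`)
  yc <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - yc) / ys
  gamma0 <- 1 / ncol(Xs)
  grid <- expand.grid(cost = params$cost,
                      gamma = gamma0 * params$gamma_mult,
                      epsilon = params$epsilon)
  n <- length(yz)
  k <- min(params$folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  cv_err <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    errs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- e1071::svm(Xs[tr, , drop = FALSE], yz[tr], type = "eps-regression",
                      kernel = "radial", cost = g$cost, gamma = g$gamma,
                      epsilon = g$epsilon, scale = FALSE)
      mean((yz[!tr] - stats::predict(m, Xs[!tr, , drop = FALSE]))^2)
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  best <- grid[which.min(cv_err), ]
  model <- e1071::svm(Xs, yz, type = "eps-regression", kernel = "radial",
                      cost = best$cost, gamma = best$gamma,
                      epsilon = best$epsilon, scale = FALSE)
  list(model = model, x_center = xc, x_scale = xs, y_center = yc,
       y_scale = ys, chosen = as.list(best), cv_rmse = sqrt(min(cv_err)))
}

#' @export
predict.ml_model <- function(object, newdata, se = FALSE, ...) {
  X <- as.matrix(if (is.data.frame(newdata)) newdata[object$factors]
                 else newdata)
  switch(object$family,
    svr = {
      f <- object$fit
      Zs <- sweep(sweep(X, 2L, f$x_center), 2L, f$x_scale, `/`)
      as.numeric(stats::predict(f$model, Zs)) * f$y_scale + f$y_center
    },
    gpr = gpr_predict(object$fit, X, se = se),
    rfr = as.numeric(stats::predict(object$fit, X)))
}

#' @export
print.ml_model <- function(x, ...) {
  cat(sprintf("%s regressor trained on %d samples (seed %s)\n",
              toupper(x$family), x$train_fingerprint["n"],
              if (is.null(x$seed)) "none" else x$seed))
  if (x$family == "svr")
    cat("  chosen hyperparameters:",
        paste(names(x$fit$chosen), unlist(x$fit$chosen), sep = "=",
              collapse = ", "), "\n")
  if (x$family == "gpr")
    cat(sprintf("  kernel: sf2=%.3g, length-scale=%.3g, noise var=%.3g\n",
                x$fit$sf2, x$fit$ell, x$fit$sn2))
  invisible(x)
}

#' Regression metrics on a dataset
#'
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2} and
#' \eqn{RMSE = \sqrt{mean((y-\hat y)^2)}}. With constant targets
#' R-squared is undefined and returned as `NA` (RMSE is still returned).
#'
#' @param model An `ml_model` (or any object with a `predict` method
#'   accepting the data).
#' @param data Evaluation data frame containing the response.
#' @param response Response column name.
#' @param label Dataset label carried into the result (e.g. "train").
#' @return A one-row data frame with `label`, `r_squared`, `rmse`.
#' @export
eval_metrics <- function(model, data, response = "activity",
                         label = "test") {
  if (nrow(data) == 0L) stop("empty evaluation set", call. = FALSE)
  y <- data[[response]]
  yhat <- as.numeric(predict(model, data))
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  data.frame(label = label,
             r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
             rmse = sqrt(sse / length(y)))
}

#' Taylor-diagram statistics
#'
#' Standard deviations (population convention, divisor n), Pearson
#' correlation and centered RMSE of a prediction series against a
#' reference series — the three quantities a Taylor diagram displays.
#' They satisfy the law-of-cosines identity
#' \eqn{cRMSE^2 = \sigma_p^2 + \sigma_r^2 - 2\sigma_p\sigma_r\rho}.
#'
#' @param predictions,references Equal-length numeric vectors (n >= 2).
#' @return A list of class `taylor_stats`: `sd_ref`, `sd_pred`,
#'   `correlation` (`NA` for zero-variance predictions), `crmse`.
#' @examples
#' taylor_stats(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
taylor_stats <- function(predictions, references) {
  stopifnot(length(predictions) == length(references),
            length(references) >= 2L)
  n <- length(references)
  psd <- function(v) sqrt(sum((v - mean(v))^2) / n)
  sd_p <- psd(predictions); sd_r <- psd(references)
  rho <- if (sd_p == 0 || sd_r == 0) NA_real_
         else stats::cor(predictions, references)
  crmse <- sqrt(mean(((predictions - mean(predictions)) -
                        (references - mean(references)))^2))
  structure(list(sd_ref = sd_r, sd_pred = sd_p, correlation = rho,
                 crmse = crmse), class = "taylor_stats")
}

#' @export
print.taylor_stats <- function(x, ...) {
  cat(sprintf("sd(ref) = %.4g, sd(pred) = %.4g, rho = %.4f, cRMSE = %.4g\n",
              x$sd_ref, x$sd_pred, x$correlation, x$crmse))
  invisible(x)
}

#' Grid search for a trained model's predicted optimum
#'
#' Dense-grid argmax/argmin of a trained regressor over a factor box.
#' Grids are preferred to gradient methods here because forest and
#' kernel surfaces are piecewise-constant or expensive to differentiate.
#' Ties are broken toward the lexicographically lowest coordinates
#' (first factor most significant).
#'
#' @param model An `ml_model` (or `rsm_quad`).
#' @param bounds Named list of per-factor `c(low, high)`.
#' @param resolution Grid points per axis (>= 2), scalar or per-factor.
#' @param direction `"max"` or `"min"`.
#' @return An `rsm_optimum`-style list: `actual`, `predicted`,
#'   per-factor `boundary` flags, `resolution`.
#' @examples
#' reps <- simulate_bbd_dataset(truth_surface(), seed = 1)
#' m <- train_regressor("rfr", augment_replicates(reps, 200, seed = 2), seed = 3)
#' search_optimum(m, list(cs = c(2, 3), ga = c(0.5, 1.5), time = c(6, 24)),
#'                resolution = 11)
#' @export
search_optimum <- function(model, bounds, resolution = 101,
                           direction = c("max", "min")) {
  direction <- match.arg(direction)
  nm <- names(bounds)
  lo <- vapply(bounds, `[[`, numeric(1L), 1L)
  hi <- vapply(bounds, `[[`, numeric(1L), 2L)
  if (!all(is.finite(c(lo, hi))) || any(hi <= lo))
    stop("bounds must be finite with low < high", call. = FALSE)
  resolution <- rep_len(as.integer(resolution), length(bounds))
  if (any(resolution < 2L)) stop("resolution must be >= 2", call. = FALSE)
  axes <- Map(function(l, h, r) seq(l, h, length.out = r),
              as.list(lo), as.list(hi), as.list(resolution))
  # reversed expand.grid: last listed axis varies fastest, so the first
  # linear index among ties has the lexicographically lowest coordinates
  grid <- expand.grid(rev(axes))[, length(axes):1, drop = FALSE]
  names(grid) <- nm
  pred <- as.numeric(predict(model, grid))
  i <- if (direction == "max") which.max(pred) else which.min(pred)
  x <- unlist(grid[i, ])
  tol <- 1e-9 * (hi - lo)
  boundary <- ifelse(x <= lo + tol, "at-low",
                     ifelse(x >= hi - tol, "at-high", "interior"))
  names(boundary) <- names(x) <- nm
  structure(list(actual = x, predicted = pred[i], boundary = boundary,
                 classification = "grid", direction = direction,
                 resolution = resolution,
                 bounds = cbind(low = lo, high = hi)),
            class = "rsm_optimum")
}

#' Run the augmented-data regression benchmark
#'
#' One pass of the augmentation-to-benchmark route: resample-augment the
#' replicate dataset, split it, train the requested families, compute
#' train/test metrics and Taylor statistics, and locate each model's
#' predicted optimum on a grid. Per-stage seeds are derived from
#' `seed` by fixed offsets so a single integer reproduces the run.
#'
#' @param replicates Replicate data frame (see [simulate_bbd_dataset()]).
#' @param seed Master seed.
#' @param target_n Augmented sample count.
#' @param test_fraction Test-side fraction of the split.
#' @param families Model families to benchmark.
#' @param bounds Optimization box (default: the attached factor ranges).
#' @param resolution Optimum-search grid resolution per axis.
#' @param response Response column name.
#' @param split_mode Passed to [split_augmented()].
#' @return A list of class `ml_benchmark`: `metrics` (family x
#'   train/test rows of R-squared and RMSE), `taylor`, `optima`,
#'   `models`, `split` and provenance.
#' @examples
#' \donttest{
#' reps <- simulate_bbd_dataset(truth_surface(), seed = 1)
#' bm <- run_benchmark(reps, seed = 1, families = "rfr", resolution = 21)
#' bm$metrics
#' }
#' @export
run_benchmark <- function(replicates, seed, target_n = 750,
                          test_fraction = 0.2,
                          families = c("svr", "gpr", "rfr"),
                          bounds = NULL, resolution = 101,
                          response = "activity",
                          split_mode = "sample") {
  stopifnot_scalar(seed, "seed")
  aug <- augment_replicates(replicates, target_n = target_n,
                            seed = seed + 1L, response = response)
  sp <- split_augmented(aug, test_fraction = test_fraction,
                        mode = split_mode, seed = seed + 2L)
  if (is.null(bounds)) {
    fs <- attr(replicates, "factors")
    if (is.null(fs)) stop("no factor set on replicates; pass `bounds`",
                          call. = FALSE)
    bounds <- lapply(fs, function(f) c(f$low, f$high))
  }
  metrics <- list(); taylor <- list(); optima <- list(); models <- list()
  for (k in seq_along(families)) {
    fam <- families[k]
    m <- train_regressor(ml_spec(fam), sp$train, response = response,
                         seed = seed + 2L + k)
    models[[fam]] <- m
    for (lab in c("train", "test")) {
      d <- sp[[lab]]
      met <- eval_metrics(m, d, response, label = lab)
      metrics[[paste(fam, lab)]] <- cbind(family = fam, met)
      taylor[[fam]][[lab]] <-
        taylor_stats(as.numeric(predict(m, d)), d[[response]])
    }
    optima[[fam]] <- search_optimum(m, bounds, resolution = resolution,
                                    direction = "max")
  }
  structure(list(metrics = do.call(rbind, c(metrics,
                                            make.row.names = FALSE)),
                 taylor = taylor, optima = optima, models = models,
                 split = sp,
                 provenance = list(seed = seed, target_n = target_n,
                                   test_fraction = test_fraction,
                                   families = families,
                                   split_mode = split_mode,
                                   resolution = resolution,
                                   augmentation = attr(aug, "provenance"))),
            class = "ml_benchmark")
}

#' @export
print.ml_benchmark <- function(x, digits = 3, ...) {
  cat("Augmented-data regression benchmark (seed",
      x$provenance$seed, ")\n")
  m <- x$metrics
  m$r_squared <- round(m$r_squared, digits)
  m$rmse <- round(m$rmse, digits)
  print(m, row.names = FALSE)
  for (fam in names(x$optima)) {
    o <- x$optima[[fam]]
    cat(sprintf("%s optimum: %s -> %.1f\n", fam,
                paste(sprintf("%s=%.3g", names(o$actual), o$actual),
                      collapse = ", "), o$predicted))
  }
  invisible(x)
}
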