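smooth_fixture <- function(n = 40, noise = 0, seed = 21) {
  set.seed(seed)
  d <- data.frame(cs = runif(n, 2, 3), ga = runif(n, 0.5, 1.5),
                  time = runif(n, 6, 24))
  d$activity <- 300 + 150 * sin(d$cs * 2) - 80 * d$ga +
    40 * cos(d$time / 5) + rnorm(n, sd = noise)
  d
}

test_that("GPR nearly interpolates noise-free smooth data at training points", {
  d <- smooth_fixture(40, noise = 0)
  m <- train_regressor("gpr", d, seed = 1)
  yhat <- predict(m, d)
  # the learned noise floor absorbs residual kernel misfit, so exact
  # interpolation is not expected; a few percent of the target sd is
  expect_lt(max(abs(yhat - d$activity)), 0.03 * sd(d$activity))
  # predictive uncertainty is exposed and near zero at training points
  se <- attr(predict(m, d, se = TRUE), "se")
  expect_true(all(se < 0.05 * sd(d$activity)))
})

test_that("GPR posterior mean matches an independent GP implementation", {
  skip_if_not_installed("kernlab")
  d <- smooth_fixture(60, noise = 8)
  test <- smooth_fixture(40, noise = 0, seed = 22)
  m <- train_regressor("gpr", d, seed = 1)
  mine <- predict(m, test)
  f <- m$fit
  # same kernel and noise-to-signal ratio handed to kernlab: its
  # posterior-mean algebra is an independent route to the same surface
  skip_if(f$sn2 / f$sf2 <= 1e-3)  # kernlab's lower bound on var
  kp <- kernlab::gausspr(x = as.matrix(d[c("cs", "ga", "time")]),
                         y = d$activity, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * f$ell^2)),
                         var = f$sn2 / f$sf2, scaled = TRUE)
  theirs <- as.numeric(kernlab::predict(kp, as.matrix(test[c("cs", "ga",
                                                             "time")])))
  expect_equal(mine, theirs, tolerance = 1e-6)
  # and the learned surface itself generalizes to the noise-free truth
  expect_lt(sqrt(mean((mine - test$activity)^2)), 0.2 * sd(test$activity))
})

test_that("a single full-sample tree memorizes a lookup table", {
  d <- smooth_fixture(25, noise = 0, seed = 30)
  m <- train_regressor(ml_spec("rfr", ntree = 1, replace = FALSE,
                               sampsize = 25),
                       d, seed = 2)
  expect_equal(as.numeric(predict(m, d)), d$activity, tolerance = 1e-8)
})

test_that("training is reproducible from spec + seed + data", {
  d <- smooth_fixture(50, noise = 5)
  grid <- smooth_fixture(30, noise = 0, seed = 23)
  for (fam in c("svr", "gpr", "rfr")) {
    m1 <- train_regressor(fam, d, seed = 7)
    m2 <- train_regressor(fam, d, seed = 7)
    expect_identical(predict(m1, grid), predict(m2, grid))
  }
})

test_that("metrics match their definitions", {
  d <- data.frame(activity = c(1, 2, 3, 4, 6))
  # predict stubs: any object with a predict method can be evaluated
  stub <- function(cls, fun) {
    registerS3method("predict", cls, fun, envir = asNamespace("stats"))
    structure(list(), class = cls)
  }
  perfect <- stub("perfect_stub",
                  function(object, newdata, ...) newdata$activity)
  met <- eval_metrics(perfect, d)
  expect_equal(met$r_squared, 1)
  expect_equal(met$rmse, 0)
  mean_mod <- stub("mean_stub", function(object, newdata, ...)
    rep(mean(d$activity), nrow(newdata)))
  met2 <- eval_metrics(mean_mod, d)
  expect_equal(met2$r_squared, 0)
  # constant targets: R^2 undefined, RMSE still returned
  dc <- data.frame(activity = rep(2, 5))
  met3 <- eval_metrics(mean_mod, dc)
  expect_true(is.na(met3$r_squared))
  expect_equal(met3$rmse, sqrt(mean((2 - mean(d$activity))^2)))
})

test_that("metrics are invariant to sample order", {
  d <- smooth_fixture(50, noise = 5)
  m <- train_regressor("rfr", d, seed = 3)
  set.seed(8)
  dshuf <- d[sample(nrow(d)), ]
  expect_equal(eval_metrics(m, d)[-1], eval_metrics(m, dshuf)[-1])
})

test_that("Taylor statistics satisfy their defining identities", {
  x <- c(1, 2, 3, 4)
  ts <- taylor_stats(x, x)
  expect_equal(ts$correlation, 1)
  expect_equal(ts$crmse, 0)
  expect_equal(ts$sd_pred, ts$sd_ref)
  # antipodal zero-mean series
  r <- c(-2, -1, 1, 2)
  ta <- taylor_stats(-r, r)
  expect_equal(ta$correlation, -1)
  expect_equal(ta$crmse, 2 * ta$sd_ref)
  # law of cosines on random pairs
  set.seed(12)
  for (i in 1:20) {
    p <- rnorm(50); o <- rnorm(50)
    tt <- taylor_stats(p, o)
    rhs <- tt$sd_pred^2 + tt$sd_ref^2 -
      2 * tt$sd_pred * tt$sd_ref * tt$correlation
    expect_lt(abs(tt$crmse^2 - rhs) / max(rhs, 1e-12), 1e-9)
  }
  # zero-variance predictions: correlation undefined, sds returned
  tz <- taylor_stats(rep(1, 4), x)
  expect_true(is.na(tz$correlation))
  expect_equal(tz$sd_pred, 0)
})

test_that("grid optimum search matches the quadratic optimizer", {
  fit <- paper_fit()
  bounds <- list(cs = c(2, 3), ga = c(0.5, 1.5), time = c(6, 24))
  go <- search_optimum(fit, bounds, resolution = 51)
  qo <- optimize_response(fit, bounds)
  step <- c(1, 1, 18) / 50  # grid spacing per axis
  expect_true(all(abs(go$actual - qo$actual) <= step + 1e-9))
  expect_lt(abs(go$predicted - qo$predicted) / qo$predicted, 0.01)
  # resolution 2 can only return vertices
  v <- search_optimum(fit, bounds, resolution = 2)
  expect_true(all(v$actual %in% c(2, 3, 0.5, 1.5, 6, 24)))
  expect_true(all(v$boundary %in% c("at-low", "at-high")))
})

test_that("train/test metrics stay close on the standard pipeline", {
  truth <- truth_surface()
  for (seed in 1:5) {
    reps <- simulate_bbd_dataset(truth, replicates = 3, seed = seed)
    aug <- augment_replicates(reps, 750, seed = seed + 100)
    sp <- split_augmented(aug, 0.2, seed = seed + 200)
    for (fam in c("svr", "gpr", "rfr")) {
      m <- train_regressor(fam, sp$train, seed = seed + 300)
      r2_tr <- eval_metrics(m, sp$train, label = "train")$r_squared
      r2_te <- eval_metrics(m, sp$test, label = "test")$r_squared
      expect_lt(abs(r2_tr - r2_te), 0.05)
    }
  }
})

test_that("degenerate and invalid training inputs are handled", {
  d <- smooth_fixture(20, noise = 0)
  d$activity <- 5
  w <- capture_warnings(train_regressor("rfr", d, seed = 1))
  expect_match(w, "constant", all = FALSE)
  expect_error(ml_spec("boost"), "arg")
  expect_error(ml_spec("svr", banana = 1), "unknown")
  expect_error(train_regressor("gpr", d[0, ], seed = 1), "empty")
})
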