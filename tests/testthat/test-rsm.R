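test_that("OLS on the 15-run table reproduces the reported equation", {
  fit <- paper_fit()
  b <- unname(coef(fit))
  # each coefficient rounds to the value printed in the reported equation
  printed_digits <- c(0, 0, 0, 1, 0, 1, 3, 1, 2, 2)
  expect_equal(round(b, printed_digits), reported_coefs)
})

test_that("OLS is exact on noise-free data and shift-equivariant", {
  f <- amylase_factors()
  d <- bbd_design(f, center_points = 3)
  beta <- c(10, 2, -3, 0.5, 1, -1, 0.02, 0.3, -0.1, 0.05)
  d$y <- eval_quadratic(beta, d[names(f)])
  fit <- rsm_quad(y ~ cs + ga + time, d)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-9)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
  # adding a constant moves only the intercept, by exactly that constant
  d2 <- d; d2$y <- d$y + 123.5
  fit2 <- rsm_quad(y ~ cs + ga + time, d2)
  expect_equal(unname(coef(fit2) - coef(fit)),
               c(123.5, rep(0, 9)), tolerance = 1e-8)
})

test_that("fit validates its inputs", {
  d <- amylase_bbd()
  expect_error(rsm_quad(activity ~ cs + ga, d), "exactly 3 factors")
  d_bad <- d; d_bad$activity[3] <- NA
  expect_error(rsm_quad(activity ~ cs + ga + time, d_bad), "missing")
  expect_error(rsm_quad(activity ~ cs + ga + time, d[1:8, ]),
               "at least 10 runs")
  # collapsing a factor to one level makes the model matrix rank deficient
  d_sing <- as.data.frame(d); d_sing$ga <- 1
  expect_error(rsm_quad(activity ~ cs + ga + time, d_sing,
                        factors = amylase_factors()), "singular")
})

test_that("predictions evaluate the quadratic exactly and flag extrapolation", {
  fit <- paper_fit()
  pts <- data.frame(cs = c(2.5, 2.5, 3.0), ga = c(0.5, 1.0, 1.5),
                    time = c(6, 16, 16))
  p <- predict(fit, pts)
  expect_equal(as.numeric(p), eval_quadratic(coef(fit), pts))
  expect_equal(attr(p, "extrapolated"), c(FALSE, FALSE, FALSE))
  p2 <- predict(fit, data.frame(cs = 3.5, ga = 1, time = 16))
  expect_true(attr(p2, "extrapolated"))
  # the study's reported predicted column comes from the equation at
  # printing precision; the exact fit agrees with it within rounding drift
  d <- amylase_bbd()
  expect_equal(round(eval_quadratic(reported_coefs, d[c("cs", "ga", "time")])),
               d$predicted_reported)
  expect_true(max(abs(fitted(fit) - d$predicted_reported)) < 3)
})

test_that("ANOVA reproduces the reference table in coded space", {
  tab <- anova(paper_fit())
  row <- function(src) tab[tab$Source == src, ]
  m <- row("Model")
  expect_equal(m$DF, 9)
  expect_equal(round(m$F, 2), 29.25)
  expect_equal(round(m$SS), 342982)
  expect_equal(round(row("Linear")$SS), 78302)
  expect_equal(round(row("cs")$SS), 43788)
  expect_equal(round(row("ga")$SS), 22423)
  expect_equal(round(row("time")$SS), 12090)
  expect_equal(round(row("Square")$SS), 223829)
  expect_equal(round(row("time^2")$F, 2), 162.24)
  expect_equal(round(row("2-way interaction")$SS), 29843)
  expect_equal(round(row("cs:time")$SS), 15206)
  expect_equal(round(row("Pure error")$SS), 2786)
  expect_equal(row("Pure error")$DF, 2)
  expect_equal(round(row("Lack-of-fit")$F, 2), 0.89)
  expect_equal(round(row("Lack-of-fit")$p, 3), 0.567)
  expect_equal(round(row("Model")$p, 3), 0.001)
})

test_that("adjusted term SS equal a literal drop-term refit oracle", {
  fit <- paper_fit()
  for (space in c("coded", "actual")) {
    tab <- anova(fit, space = space)
    d <- amylase_bbd()
    X <- as.matrix(d[c("cs", "ga", "time")])
    if (space == "coded") {
      mid <- c(2.5, 1.0, 15); half <- c(0.5, 0.5, 9)
      X <- sweep(sweep(X, 2, mid), 2, half, `/`)
    }
    Q <- data.frame(y = d$activity, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
    full <- lm(y ~ x1 + x2 + x3 + I(x1^2) + I(x2^2) + I(x3^2) +
                 x1:x2 + x1:x3 + x2:x3, data = Q)
    sse <- sum(resid(full)^2)
    oracle <- function(f) sum(resid(update(full, f))^2) - sse
    drops <- list(cs = . ~ . - x1, ga = . ~ . - x2, time = . ~ . - x3,
                  `cs^2` = . ~ . - I(x1^2), `ga^2` = . ~ . - I(x2^2),
                  `time^2` = . ~ . - I(x3^2), `cs:ga` = . ~ . - x1:x2,
                  `cs:time` = . ~ . - x1:x3, `ga:time` = . ~ . - x2:x3,
                  Linear = . ~ . - x1 - x2 - x3,
                  Square = . ~ . - I(x1^2) - I(x2^2) - I(x3^2),
                  `2-way interaction` = . ~ . - x1:x2 - x1:x3 - x2:x3)
    for (src in names(drops))
      expect_equal(tab$SS[tab$Source == src], oracle(drops[[src]]),
                   tolerance = 1e-8, label = paste(space, src))
  }
})

test_that("SS decomposition closes and rank-invariant rows match across spaces", {
  fit <- paper_fit()
  for (space in c("coded", "actual")) {
    tab <- anova(fit, space = space)
    g <- function(src, col) tab[tab$Source == src, col]
    expect_lt(abs(g("Model", "SS") + g("Error", "SS") - g("Total", "SS")) /
                g("Total", "SS"), 1e-9)
    expect_lt(abs(g("Lack-of-fit", "SS") + g("Pure error", "SS") -
                    g("Error", "SS")), 1e-8)
    expect_equal(g("Model", "DF"), 9)
    expect_equal(g("Error", "DF"), 5)
    expect_equal(g("Total", "DF"), 14)
  }
  # model F, error SS, lack-of-fit are reparameterization invariant
  a1 <- anova(fit, "coded"); a2 <- anova(fit, "actual")
  for (src in c("Model", "Error", "Lack-of-fit", "Pure error"))
    expect_equal(a1$SS[a1$Source == src], a2$SS[a2$Source == src],
                 tolerance = 1e-9)
  expect_equal(a1$F[a1$Source == "Model"], a2$F[a2$Source == "Model"],
               tolerance = 1e-9)
})

test_that("lack-of-fit rows are absent without replicated points", {
  f <- amylase_factors()
  d <- bbd_design(f, center_points = 1)
  set.seed(7)
  d$y <- eval_quadratic(random_quadratic(), d[names(f)]) + rnorm(13)
  tab <- anova(rsm_quad(y ~ cs + ga + time, d))
  expect_false(any(tab$Source %in% c("Lack-of-fit", "Pure error")))
  expect_false(attr(tab, "replicated"))
})

test_that("fit statistics match the reported values and the LOO oracle", {
  fit <- paper_fit()
  st <- fit_stats(fit)
  expect_equal(round(st$r_squared, 2), 0.98)
  expect_equal(round(st$adj_r_squared, 2), 0.95)
  expect_equal(round(st$pred_r_squared, 2), 0.81)
  # PRESS equals the literal leave-one-out refit sum of squares
  d <- amylase_bbd()
  loo <- sum(vapply(1:15, function(i) {
    f_i <- rsm_quad(activity ~ cs + ga + time, d[-i, ],
                    factors = amylase_factors())
    (d$activity[i] - as.numeric(predict(f_i, d[i, c("cs", "ga", "time")])))^2
  }, numeric(1)))
  expect_equal(st$press, loo, tolerance = 1e-8)
  expect_true(st$pred_r_squared <= st$adj_r_squared)
  expect_true(st$adj_r_squared <= st$r_squared)
})

test_that("perfect fits give R-squared 1 and PRESS 0", {
  f <- amylase_factors()
  d <- bbd_design(f, center_points = 3)
  d$y <- eval_quadratic(c(100, 5, -2, 1, 0.5, -0.5, 0.01, 0.2, -0.1, 0.05),
                        d[names(f)])
  st <- fit_stats(rsm_quad(y ~ cs + ga + time, d))
  expect_equal(st$r_squared, 1, tolerance = 1e-9)
  expect_equal(st$press, 0, tolerance = 1e-6)
  expect_equal(st$pred_r_squared, 1, tolerance = 1e-9)
})

test_that("constrained optimization recovers interior and boundary optima", {
  # known interior maximum: negative-definite quadratic part
  f <- unit_box_factors()
  d <- bbd_design(f, center_points = 3)
  beta <- c(5, 0.4, -0.2, 0.1, -2, -3, -1.5, 0.3, -0.2, 0.1)
  d$y <- eval_quadratic(beta, d[c("x1", "x2", "x3")])
  fit <- rsm_quad(y ~ x1 + x2 + x3, d)
  opt <- optimize_response(fit)
  Q <- matrix(c(-2, 0.15, -0.1, 0.15, -3, 0.05, -0.1, 0.05, -1.5), 3)
  xs <- solve(-2 * Q, beta[2:4])
  expect_equal(unname(opt$actual), unname(xs), tolerance = 1e-6)
  expect_equal(opt$classification, "maximum")
  expect_equal(unname(opt$boundary), rep("interior", 3))
  expect_equal(opt$predicted,
               eval_quadratic(beta, matrix(xs, 1)), tolerance = 1e-8)

  # the immobilization fit: optimum on the lower edges
  pf <- paper_fit()
  popt <- optimize_response(pf, bounds = list(cs = c(2, 3), ga = c(0.5, 1.5),
                                              time = c(6, 24)))
  expect_equal(unname(popt$boundary[c("ga", "time")]),
               c("at-low", "at-low"))
  expect_equal(unname(popt$actual[["cs"]]), 2.6, tolerance = 0.1 / 2.6)
  expect_equal(popt$predicted, 675, tolerance = 0.02)
  expect_equal(popt$classification, "boundary")
})

test_that("optimizer matches a dense-grid oracle on random quadratics", {
  f <- unit_box_factors()
  d <- bbd_design(f, center_points = 3)
  nm <- c("x1", "x2", "x3")
  ax <- seq(-1, 1, length.out = 41)
  grid <- as.matrix(expand.grid(x1 = ax, x2 = ax, x3 = ax))
  set.seed(99)
  for (i in 1:8) {
    beta <- random_quadratic()
    d$y <- eval_quadratic(beta, d[nm])
    fit <- rsm_quad(y ~ x1 + x2 + x3, d)
    for (dir in c("max", "min")) {
      opt <- optimize_response(fit, direction = dir)
      gv <- eval_quadratic(beta, grid)
      gbest <- if (dir == "max") max(gv) else min(gv)
      # optimizer can only be at least as good as the 41^3 grid
      better <- if (dir == "max") opt$predicted >= gbest - 1e-8
                else opt$predicted <= gbest + 1e-8
      expect_true(better)
      expect_lt(abs(opt$predicted - gbest), max(abs(gv)) * 0.02 + 1e-6)
    }
  }
})

test_that("degenerate quadratics fall back to a boundary vertex", {
  f <- unit_box_factors()
  d <- bbd_design(f, center_points = 3)
  d$y <- eval_quadratic(c(1, 2, -1, 0.5, 0, 0, 0, 0, 0, 0),
                        d[c("x1", "x2", "x3")])
  opt <- optimize_response(rsm_quad(y ~ x1 + x2 + x3, d))
  expect_equal(unname(opt$actual), c(1, -1, 1), tolerance = 1e-6)
  expect_equal(opt$classification, "boundary")
})

test_that("surface grids agree with direct prediction", {
  fit <- paper_fit()
  g <- surface_grid(fit, c("cs", "ga"), fix = 16, resolution = 21)
  expect_equal(nrow(g), 441)
  corners <- g[c(1, 21, 421, 441), ]
  direct <- predict(fit, data.frame(cs = corners$cs, ga = corners$ga,
                                    time = 16))
  expect_equal(corners$response, as.numeric(direct))
  # along cs at mid binding time the surface peaks left of 2.6
  best <- g[which.max(g$response), ]
  expect_true(best$cs >= 2.0 && best$cs <= 2.6)
  # resolution 1 gives the single low-corner node
  g1 <- surface_grid(fit, c("cs", "ga"), fix = 16, resolution = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$response,
               as.numeric(predict(fit, data.frame(cs = 2, ga = 0.5,
                                                  time = 16))))
  expect_error(surface_grid(fit, c("cs", "nope")), "vary")
  expect_error(surface_grid(fit, c("cs", "ga"), fix = 30), "outside")
})

test_that("quadratic parameter recovery under replicate noise is calibrated", {
  truth <- truth_surface()
  nsim <- 500
  hits <- matrix(FALSE, nsim, 10)
  set.seed(2024)
  for (s in seq_len(nsim)) {
    reps <- simulate_bbd_dataset(truth, replicates = 3, seed = NULL)
    fit <- rsm_quad(activity ~ cs + ga + time, reps,
                    factors = truth$factors)
    se <- sqrt(diag(vcov(fit)))
    hits[s, ] <- abs(coef(fit) - truth$coefficients) <= 3 * se
  }
  expect_true(all(colMeans(hits) >= 0.95))
})
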