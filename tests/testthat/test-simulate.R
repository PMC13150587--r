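test_that("the default truth surface encodes the study conditions", {
  tr <- truth_surface()
  expect_equal(unname(tr$coefficients), reported_coefs)
  expect_equal(tr$noise_sd, sqrt(1393))
  expect_equal(names(tr$factors), c("cs", "ga", "time"))
  expect_error(truth_surface(noise_sd = -1), ">= 0")
})

test_that("noise-free simulation closes the generate-refit loop exactly", {
  tr <- truth_surface(noise_sd = 0)
  reps <- simulate_bbd_dataset(tr, replicates = 3, seed = 1)
  expect_equal(nrow(reps), 45)
  expect_equal(as.integer(table(reps$run)), rep(3L, 15))
  mu <- eval_quadratic(tr$coefficients, reps[c("cs", "ga", "time")])
  expect_equal(reps$activity, mu)
  fit <- rsm_quad(activity ~ cs + ga + time, reps, factors = tr$factors)
  expect_equal(unname(coef(fit)), unname(tr$coefficients), tolerance = 1e-9)
})

test_that("simulation is seed-reproducible and floors negative draws", {
  tr <- truth_surface()
  expect_identical(simulate_bbd_dataset(tr, seed = 4),
                   simulate_bbd_dataset(tr, seed = 4))
  # enormous noise forces some draws negative; they are floored, flagged
  loud <- truth_surface(noise_sd = 5000)
  reps <- simulate_bbd_dataset(loud, seed = 4)
  expect_true(attr(reps, "floored") > 0)
  expect_true(all(reps$activity >= 0))
})

test_that("generator means are unbiased at the design points", {
  tr <- truth_surface()
  reps <- simulate_bbd_dataset(tr, replicates = 10000, seed = 13)
  des <- bbd_design(tr$factors)
  mu <- eval_quadratic(tr$coefficients, des[c("cs", "ga", "time")])
  m <- tapply(reps$activity, reps$run, mean)
  se_mean <- tr$noise_sd / sqrt(10000)
  expect_true(all(abs(m - mu) < 3 * se_mean + 0.05))
})

test_that("simulated pure-error MS is centered on the configured variance", {
  tr <- truth_surface()
  set.seed(55)
  ms <- vapply(1:300, function(i) {
    reps <- simulate_bbd_dataset(tr, replicates = 3)
    # pooled pure error over all 15 replicated runs, 2 df each
    within <- tapply(reps$activity, reps$run,
                     function(v) sum((v - mean(v))^2))
    sum(within) / (15 * 2)
  }, numeric(1))
  expect_equal(mean(ms), 1393, tolerance = 0.10)
})

test_that("decay and reuse generators have their closed forms", {
  d <- simulate_decay(0.0429, 100, 0:20, sd_log = 0)
  expect_equal(round(fit_deactivation(d$time_h, d$activity)$half_life, 1),
               16.2)
  expect_equal(simulate_decay(0, 50, 0:5)$activity, rep(50, 6))
  expect_error(simulate_decay(0.1, 100, times = c(-1, 0)), "non-negative")

  ru <- simulate_reuse_profile(0.933, 10)
  expect_equal(cycle_profile(ru$activity)$residual_pct, 100 * 0.933^(0:9))
  # ten cycles at 93.3% retention land near half the initial activity
  expect_equal(cycle_profile(ru$activity)$residual_pct[10], 53.6,
               tolerance = 0.01)
  expect_equal(simulate_reuse_profile(1, 5)$activity, rep(100, 5))
  expect_error(simulate_reuse_profile(1.2, 5), "retention")
})

test_that("noisy decay recovery is calibrated over many series", {
  set.seed(31)
  kd <- vapply(1:500, function(i) {
    d <- simulate_decay(0.0429, 100, seq(0, 20, length.out = 10),
                        sd_log = 0.05)
    fit_deactivation(d$time_h, d$activity)$k_d
  }, numeric(1))
  expect_equal(median(kd), 0.0429, tolerance = 0.02)
})

test_that("end-to-end optimum recovery holds at the default noise level", {
  tr <- truth_surface()
  truth_fit <- optimize_response(
    rsm_quad(activity ~ cs + ga + time,
             simulate_bbd_dataset(truth_surface(noise_sd = 0), seed = 1),
             factors = tr$factors))
  cs_truth <- truth_fit$actual[["cs"]]
  set.seed(77)
  n <- 200
  bounds_ok <- logical(n)
  cs_dev <- numeric(n)
  for (i in seq_len(n)) {
    reps <- simulate_bbd_dataset(tr, replicates = 3)
    run_means <- aggregate(activity ~ run + cs + ga + time, reps, mean)
    fit <- rsm_quad(activity ~ cs + ga + time, run_means,
                    factors = tr$factors)
    opt <- optimize_response(fit)
    bounds_ok[i] <- opt$boundary[["ga"]] == "at-low" &&
      opt$boundary[["time"]] == "at-low"
    cs_dev[i] <- opt$actual[["cs"]] - cs_truth
  }
  # the boundary pattern of the truth optimum is recovered reliably;
  # the chitosan coordinate is recovered without bias but with a
  # sampling spread of ~0.13 at this noise level, so a tight per-run
  # window is not a reliable event and the typical error is asserted
  expect_gte(mean(bounds_ok), 0.90)
  expect_lte(median(abs(cs_dev)), 0.15)
})
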