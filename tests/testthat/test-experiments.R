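test_that("noiseless simulations reproduce the designed expectations", {
  tr <- cs_traits()
  s1 <- simulate_experiment(tr, which = 1, noise_cv = 0)
  expect_true(all(s1$mu_per_day == 0.22))
  s2 <- simulate_experiment(tr, which = 2, noise_cv = 0)
  expect_true(all(s2$mu_per_day == 0.38))
  s3 <- simulate_experiment(tr, beta = 0.836, which = 3, times = 0.5,
                            noise_cv = 0)
  expect_equal(s3$mu_per_day, 0.60 + 0.836 * 0.5)
  expect_error(simulate_experiment(tr, which = 4), "unknown experiment")
  expect_error(simulate_experiment(tr, which = 1, noise_cv = 0.05),
               "seed")

  # default mixotrophy sampling stays within one division interval
  s3d <- simulate_experiment(tr, beta = 0.836, which = 3, noise_cv = 0)
  expect_equal(nrow(s3d), 10)
  expect_equal(max(s3d$t_days), division_time_linear(0.60, 0.836)$T)
})

test_that("simulation noise is reproducible and namespaced per experiment", {
  tr <- cs_traits()
  a <- simulate_experiment(tr, which = 1, noise_cv = 0.05, seed = 5)
  b <- simulate_experiment(tr, which = 1, noise_cv = 0.05, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_experiment(tr, which = 2, noise_cv = 0.05, seed = 5)
  expect_false(any(a$mu_per_day == c2$mu_per_day))
  d <- simulate_experiment(tr, which = 1, noise_cv = 0.05, seed = 6)
  expect_false(identical(a$mu_per_day, d$mu_per_day))
})

test_that("saturation of the free kleptoplast volume triggers a warning", {
  tr <- protist_traits(0.22, 0.38, tau = 0.1, v1 = 5, V1 = 4, Vf = 10)
  expect_warning(
    simulate_experiment(tr, beta = 0.836, which = 3, times = c(0.5, 1),
                        noise_cv = 0),
    "free volume")
})

test_that("zero-noise round trip recovers the generating parameters exactly", {
  tr <- cs_traits()
  est <- estimate_from_experiments(
    simulate_experiment(tr, which = 1, noise_cv = 0),
    simulate_experiment(tr, which = 2, noise_cv = 0),
    simulate_experiment(tr, beta = 0.836, which = 3, noise_cv = 0))
  expect_lt(rel_err(est$Omega1_hat, 0.22), 1e-10)
  expect_lt(rel_err(est$Omega2_hat, 0.38), 1e-10)
  expect_lt(rel_err(est$beta_hat, 0.836), 1e-10)
  expect_lt(rel_err(est$params$kappa, 0.4075485351), 1e-9)

  # constant mixotrophic series: no kleptoplastidy detected
  s3flat <- rate_series(3, seq(0.1, 1, by = 0.1), rep(0.60, 10))
  est0 <- estimate_from_experiments(
    simulate_experiment(tr, which = 1, noise_cv = 0),
    simulate_experiment(tr, which = 2, noise_cv = 0), s3flat)
  expect_equal(est0$beta_hat, 0, tolerance = 1e-12)
  expect_equal(est0$params$kappa, 0, tolerance = 1e-12)
})

test_that("estimation consumes only measurement series, never traits", {
  expect_named(formals(estimate_from_experiments), c("s1", "s2", "s3"))
  # plain data frames (e.g. read from CSV) are accepted
  t <- seq(0.1, 1, by = 0.1)
  est <- estimate_from_experiments(
    data.frame(experiment = 1, t_days = t, mu_per_day = rep(0.22, 10)),
    data.frame(experiment = 2, t_days = t, mu_per_day = rep(0.38, 10)),
    data.frame(experiment = 3, t_days = t, mu_per_day = 0.60 + 0.836 * t))
  expect_lt(rel_err(est$beta_hat, 0.836), 1e-10)
})

test_that("beta estimate is unbiased in the mean and bias shrinks with n", {
  tr <- cs_traits()
  run_reps <- function(n, seeds) {
    vapply(seeds, function(seed) {
      est <- estimate_from_experiments(
        simulate_experiment(tr, which = 1, times = seq_len(n) / n,
                            noise_cv = 0.05, seed = seed),
        simulate_experiment(tr, which = 2, times = seq_len(n) / n,
                            noise_cv = 0.05, seed = seed),
        simulate_experiment(tr, beta = 0.836, which = 3,
                            times = seq_len(n) / n * 0.98,
                            noise_cv = 0.05, seed = seed))
      est$beta_hat
    }, numeric(1))
  }
  bias <- vapply(c(5, 20, 80), function(n)
    abs(mean(run_reps(n, 1:60)) - 0.836) / 0.836, numeric(1))
  expect_lt(bias[2], 0.05)
  expect_lt(bias[3], bias[1] + 0.02)  # no growth of bias with n (noise floor)
  expect_lt(bias[3], 0.03)
})

test_that("rate series round-trip through the CSV dialect", {
  tr <- cs_traits()
  series <- lapply(1:3, function(k)
    simulate_experiment(tr, beta = 0.836, which = k, noise_cv = 0.05,
                        seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_series(series, path)
  back <- read_rate_series(path)
  expect_named(back, c("experiment1", "experiment2", "experiment3"))
  for (k in 1:3)
    expect_equal(back[[k]]$mu_per_day, series[[k]]$mu_per_day,
                 tolerance = 1e-12)
})
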