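test_that("kleptoplast mass accumulates linearly in time", {
  expect_equal(kleptoplast_mass(1, 0.5, 1), 2)
  expect_equal(kleptoplast_mass(0.3, 0.25, 0), 0)
  expect_equal(kleptoplast_mass(0.3, 0.25, 2), 2.4)
  expect_error(kleptoplast_mass(0.3, 0, 1), "tau")
})

test_that("mechanistic beta follows the trait formula", {
  tr <- protist_traits(0.22, 0.38, M1 = 2, m1 = 1, tau = 0.25, gamma = 1)
  expect_equal(beta_mechanistic(tr), 0.44)
  tr0 <- protist_traits(0.22, 0.38, M1 = 2, m1 = 1, tau = 0.25, gamma = 0)
  expect_equal(beta_mechanistic(tr0), 0)
  tru <- protist_traits(0.22, 0.38, M1 = 1, m1 = 1, tau = 1, gamma = 1)
  expect_equal(beta_mechanistic(tru), 0.22)
  expect_error(beta_mechanistic(protist_traits(0.2, 0.3)), "M1")
})

test_that("beta is recovered from measurement series", {
  # single observation: exact pointwise formula
  s <- rate_series(3, t_days = 2, mu_per_day = 0.7)
  expect_equal(beta_from_measurements(0.2, 0.3, s)$beta, 0.1)

  # noiseless affine series: exact recovery
  t <- c(0.25, 0.5, 0.75, 1)
  s3 <- rate_series(3, t, 0.60 + 0.836 * t)
  fit <- beta_from_measurements(0.22, 0.38, s3)
  expect_lt(abs(fit$beta - 0.836), 1e-10)
  expect_false(fit$misfit)

  # noisy series: estimate within 3 SE of truth under a fixed seed
  tr <- cs_traits()
  sn <- simulate_experiment(tr, beta = 0.836, which = 3,
                            times = seq_len(20) / 20, noise_cv = 0.05,
                            seed = 11)
  fitn <- beta_from_measurements(0.22, 0.38, sn)
  expect_lt(abs(fitn$beta - 0.836), 3 * fitn$se)

  # degenerate/misfit handling
  expect_error(beta_from_measurements(0.2, 0.3, rate_series(3, 0, 0.5)),
               "t > 0")
  sneg <- rate_series(3, t, 0.60 - 0.2 * t)
  expect_warning(fneg <- beta_from_measurements(0.22, 0.38, sneg),
                 "negative")
  expect_lt(fneg$beta, 0)
  expect_true(fneg$misfit)
})

test_that("sigma measures feeding-mode balance", {
  expect_equal(sigma_from_rates(0.22, 0.38), 0.9288888889, tolerance = 1e-9)
  expect_equal(round(sigma_from_rates(0.22, 0.38), 2), 0.93)
  expect_equal(sigma_from_rates(0.7, 0.7), 1)
  expect_equal(sigma_from_rates(0.5, 0), 0)
  expect_equal(sigma_from_rates(0.22, 0.38), sigma_from_rates(0.38, 0.22))
  expect_error(sigma_from_rates(0, 0), "> 0")
})

test_that("alpha from traits matches the mass and volume forms and beta identity", {
  tr <- protist_traits(0.22, 0.38, M1 = 0.1, m1 = 0.095, tau = 0.25, gamma = 1)
  expect_equal(alpha_from_traits(tr), 1 * (0.095 / (0.25 * 0.38)) / 0.1)
  tr0 <- protist_traits(0.22, 0.38, M1 = 1, m1 = 0.5, tau = 0.5, gamma = 0)
  expect_equal(alpha_from_traits(tr0), 0)

  # volume form under equal mass density
  trv <- protist_traits(0.22, 0.38, tau = 0.5, gamma = 1, v1 = 2, V1 = 4)
  expect_equal(alpha_from_traits(trv, equal_density = TRUE),
               (2 / 4) / (0.5 * 0.38))

  # algebraic identity alpha * Omega1 * Omega2 = beta over random traits
  for (seed in 1:25) {
    d <- random_parameter_draw(seed = seed)
    expect_equal(alpha_from_traits(d$traits) * d$traits$Omega1 * d$traits$Omega2,
                 d$beta, tolerance = 1e-12)
  }
})

test_that("kappa anchors: balanced high-alpha and case-study values", {
  expect_equal(kappa_from_alpha_sigma(5, 1), 0.3033370453, tolerance = 1e-9)
  expect_equal(round(kappa_from_alpha_sigma(5, 1), 1), 0.3)
  expect_equal(kappa_from_alpha_sigma(0, 0.5), 0)
  k_cs <- kappa_from_alpha_sigma(10, sigma_from_rates(0.22, 0.38))
  expect_equal(k_cs, 0.4075485351, tolerance = 1e-9)
  expect_equal(round(k_cs, 1), 0.4)
  expect_error(kappa_from_alpha_sigma(1, 1.5), "sigma")
})

test_that("kappa parameterizations agree and the index stays in [0,1)", {
  expect_equal(kappa_from_beta(0.22, 0.38, 0), 0)
  expect_equal(kappa_from_beta(0.22, 0.38, 0.836), 0.4075485351,
               tolerance = 1e-9)
  expect_equal(kappa_from_beta(0.3, 0.3, 0.9), kappa_from_alpha_sigma(10, 1))

  # cross-parameterization identity over random draws
  set.seed(99)
  for (i in 1:50) {
    O1 <- runif(1, 0.05, 1); O2 <- runif(1, 0.05, 1)
    beta <- runif(1, 0, 5)
    k1 <- kappa_from_beta(O1, O2, beta)
    k2 <- kappa_from_alpha_sigma(beta / (O1 * O2), sigma_from_rates(O1, O2))
    expect_equal(k1, k2, tolerance = 1e-12)
    expect_gte(k1, 0)
    expect_lt(k1, 1)
  }
})

test_that("combined rate exceeds the additive ceiling only with kleptoplastidy", {
  p <- combined_rate_and_synergy(0.22, 0.38, 0.836)
  expect_equal(p$Omega12, 1.0127411872, tolerance = 1e-9)
  expect_equal(p$dOmega, p$Omega12 - 0.60)
  expect_equal(p$kappa, p$dOmega / p$Omega12)
  expect_equal(p$kappa, kappa_from_beta(0.22, 0.38, 0.836))

  p0 <- combined_rate_and_synergy(0.22, 0.38, 0)
  expect_equal(p0$Omega12, 0.60)
  expect_equal(p0$dOmega, 0)
  expect_equal(p0$kappa, 0)

  # 1/Omega12 equals the linear-rate division interval; synergy non-negative
  set.seed(13)
  for (i in 1:50) {
    O1 <- runif(1, 0.05, 1); O2 <- runif(1, 0.05, 1)
    beta <- runif(1, 0, 5)
    p <- combined_rate_and_synergy(O1, O2, beta)
    expect_equal(1 / p$Omega12, division_time_linear(O1 + O2, beta)$T,
                 tolerance = 1e-10)
    expect_gte(p$Omega12, O1 + O2)
    if (beta > 0) expect_gt(p$dOmega, 0)
  }
})

test_that("kappa sensitivities are closed-form, bounded, and match finite differences", {
  sens0 <- kappa_sensitivity_sigma1(0)
  expect_equal(sens0$dk_dalpha, 1 / 8)
  expect_equal(sens0$dk_dsigma, 0)

  alpha <- seq(0, 100, length.out = 401)
  sens <- kappa_sensitivity_sigma1(alpha)
  # stability: both derivatives bounded well below one
  expect_true(all(sens$dk_dalpha <= 1 / 8))
  expect_true(all(sens$dk_dsigma < 0.172))
  expect_lt(max(sens$dk_dsigma), 0.172)

  # central finite differences of the index agree with the closed forms
  h <- 1e-6
  for (a in c(0.5, 2, 9.657, 50)) {
    fd_a <- (kappa_from_alpha_sigma(a + h, 1) -
             kappa_from_alpha_sigma(a - h, 1)) / (2 * h)
    fd_s <- (kappa_from_alpha_sigma(a, 1) -
             kappa_from_alpha_sigma(a, 1 - h)) / h
    s <- kappa_sensitivity_sigma1(a)
    expect_lt(abs(fd_a - s$dk_dalpha), 1e-6)
    expect_lt(abs(fd_s - s$dk_dsigma), 1e-6)
  }
})

test_that("kappa grid is monotone with its maximum at the rich balanced corner", {
  kg <- kappa_grid()
  expect_equal(dim(kg), c(51, 51))
  expect_equal(round(kg[51, 51], 1), 0.3)
  expect_equal(max(kg), kg[51, 51])
  expect_true(all(kg[, 1] == 0))  # sigma = 0 row: no balance, no kleptoplastidy
  expect_true(all(apply(kg, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(apply(kg, 1, function(row) all(diff(row) >= 0))))

  path <- withr::local_tempfile(fileext = ".csv")
  write_kappa_grid(kg, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), kg, ignore_attr = TRUE)
})
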