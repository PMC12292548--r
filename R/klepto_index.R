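#' Accumulated kleptoplast mass
#'
#' Kleptoplast acquisition is cumulative: the protist digests one prey cell
#' every `tau` days, keeping its chloroplasts (mass `m1` each), so starting
#' from zero the retained kleptoplast mass after `t` days is `m1 * t / tau`.
#' Kleptoplasts are assumed not to carry over through division; the clock
#' restarts at each division.
#'
#' @param m1 Chloroplast mass of one prey cell (ug).
#' @param tau Digestion time per prey cell (days), `> 0`.
#' @param t Time since the last division (days), `>= 0`. Vectorized.
#' @return Accumulated kleptoplast mass in ug.
#' @export
kleptoplast_mass <- function(m1, tau, t) {
  if (m1 < 0) stop("m1 must be >= 0")
  if (tau <= 0) stop("digestion time tau must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  m1 * t / tau
}

#' Mechanistic kleptoplastidy acceleration
#'
#' Relates the phenomenological acceleration `beta` (1/day^2) to
#' morpho-physiological traits: `beta = gamma * Omega1 * m1 / (M1 * tau)`.
#' The kleptoplast photosynthetic contribution grows linearly in time because
#' kleptoplast mass does, and each unit of kleptoplast mass contributes
#' `gamma * Omega1 / M1` to the division rate.
#'
#' @param traits A [protist_traits()] with `M1 > 0` and `tau > 0`.
#' @return beta in 1/day^2.
#' @export
beta_mechanistic <- function(traits) {
  stopifnot(inherits(traits, "protist_traits"))
  if (is.na(traits$M1) || traits$M1 <= 0) stop("M1 must be > 0")
  if (is.na(traits$tau) || traits$tau <= 0) stop("tau must be > 0")
  if (is.na(traits$m1)) stop("m1 is required")
  traits$gamma * traits$Omega1 * traits$m1 / (traits$M1 * traits$tau)
}

#' Estimate beta from division-rate measurements
#'
#' In the mixotrophy experiment the division rate in excess of the autotrophic
#' and heterotrophic baselines grows linearly from zero:
#' `mu3(t) - mu1 - mu2 = beta * t`. A single observation therefore gives
#' `beta = (mu3 - mu1 - mu2) / t` exactly; a series gives the least-squares
#' slope of the excess rate regressed on time *through the origin* (the
#' kleptoplast contribution is structurally zero at `t = 0`). An ordinary
#' regression with a free intercept is available as a diagnostic for model
#' misfit.
#'
#' Measurement noise on division rates is typically multiplicative, so the
#' residual variance grows with the rate itself; the standard error of the
#' through-origin slope is therefore computed with a small-sample
#' heteroscedasticity-consistent (HC3) sandwich estimator rather than the
#' homoscedastic least-squares formula.
#'
#' @param mu1 Autotrophic division rate (divisions/day), from the
#'   inorganic-only experiment.
#' @param mu2 Heterotrophic division rate (divisions/day), from the
#'   organic-only experiment.
#' @param series3 A [rate_series()] (or data frame with columns `t_days`,
#'   `mu_per_day`) from the mixotrophy experiment; at least one observation
#'   with `t > 0`.
#' @param var_mu12 Optional sampling variance of `mu1 + mu2`, propagated into
#'   the standard error of the slope.
#' @param intercept Fit a free intercept instead of forcing the line through
#'   the origin (diagnostic only).
#' @return A list with `beta`, `se`, `n`, `residual_variance`, and logical
#'   `misfit` (`TRUE`, with a warning, when the fitted beta is negative).
#' @export
beta_from_measurements <- function(mu1, mu2, series3, var_mu12 = 0,
                                   intercept = FALSE) {
  obs <- as.data.frame(series3)
  if (!all(c("t_days", "mu_per_day") %in% names(obs)))
    stop("series3 must have columns t_days and mu_per_day")
  if (nrow(obs) == 0) stop("series3 is empty")
  if (all(obs$t_days <= 0))
    stop("series3 must contain at least one observation with t > 0")
  t <- obs$t_days
  y <- obs$mu_per_day - mu1 - mu2
  n <- length(t)
  if (n == 1) {
    beta <- y / t
    se <- if (var_mu12 > 0) sqrt(var_mu12) / t else NA_real_
    rv <- NA_real_
  } else if (intercept) {
    fit <- stats::lm(y ~ t)
    sm <- suppressWarnings(summary(fit))
    beta <- unname(stats::coef(fit)["t"])
    se <- sm$coefficients["t", "Std. Error"]
    rv <- sm$sigma^2
  } else {
    stt <- sum(t^2)
    beta <- sum(t * y) / stt
    e <- y - beta * t
    rv <- sum(e^2) / (n - 1)
    # HC3 leverage correction; leverage of point i through the origin
    h <- t^2 / stt
    var_slope <- sum(t^2 * e^2 / pmax(1 - h, 1e-8)^2) / stt^2
    # mu1/mu2 are themselves estimates; their error shifts every y equally,
    # entering the through-origin slope with weight sum(t)/sum(t^2)
    se <- sqrt(var_slope + (sum(t) / stt)^2 * var_mu12)
  }
  misfit <- is.finite(beta) && beta < 0
  if (misfit)
    warning("fitted beta is negative: linear kleptoplastidy model misfit")
  list(beta = beta, se = se, n = n, residual_variance = rv, misfit = misfit)
}

#' Feeding-mode balance parameter sigma
#'
#' `sigma = 4 Omega1 Omega2 / (Omega1 + Omega2)^2` measures how balanced the
#' autotrophic and heterotrophic modes are: 1 for perfectly balanced
#' mixotrophy (`Omega1 = Omega2`), 0 for a pure autotroph or heterotroph.
#' Symmetric in its arguments.
#'
#' @param Omega1,Omega2 Maximum division rates (divisions/day); not both zero.
#' @return sigma in `[0, 1]`.
#' @examples
#' sigma_from_rates(0.22, 0.38) # ~0.93
#' @export
sigma_from_rates <- function(Omega1, Omega2) {
  if (Omega1 < 0 || Omega2 < 0) stop("rates must be >= 0")
  if (Omega1 + Omega2 <= 0) stop("Omega1 + Omega2 must be > 0")
  4 * Omega1 * Omega2 / (Omega1 + Omega2)^2
}

#' Normalized kleptoplast photosynthetic contribution alpha
#'
#' `alpha = beta / (Omega1 Omega2)` expressed through traits:
#' `alpha = gamma * (m1 / (tau * Omega2)) / M1` — the mass of kleptoplasts
#' accumulated over one heterotrophic division interval, relative to the
#' native chloroplast mass, discounted by the kleptoplast efficiency `gamma`.
#' When masses are unavailable the volume form
#' `gamma * (v1 / (tau * Omega2)) / V1` applies under the assumption that all
#' constituents share the same mass density (`equal_density = TRUE`).
#'
#' @param traits A [protist_traits()].
#' @param Omega2 Maximum heterotrophic division rate (divisions/day), `> 0`.
#'   Defaults to `traits$Omega2`.
#' @param equal_density Use the volume form `v1/V1` in place of `m1/M1`.
#' @return alpha (dimensionless).
#' @export
alpha_from_traits <- function(traits, Omega2 = traits$Omega2,
                              equal_density = FALSE) {
  stopifnot(inherits(traits, "protist_traits"))
  if (is.na(traits$tau) || traits$tau <= 0) stop("tau must be > 0")
  if (Omega2 <= 0) stop("Omega2 must be > 0")
  if (equal_density) {
    if (is.na(traits$V1) || traits$V1 <= 0)
      stop("volume form requires V1 > 0")
    if (is.na(traits$v1)) stop("volume form requires v1")
    ratio <- traits$v1 / traits$V1
  } else {
    if (is.na(traits$M1) || traits$M1 <= 0) stop("M1 must be > 0")
    if (is.na(traits$m1)) stop("m1 is required")
    ratio <- traits$m1 / traits$M1
  }
  traits$gamma * ratio / (traits$tau * Omega2)
}

.kappa_from_discriminant <- function(disc) {
  s <- sqrt(1 + disc)
  (s - 1) / (s + 1)
}

#' Kleptoplastidy index from the dimensionless parameters
#'
#' `kappa = (sqrt(1 + alpha*sigma/2) - 1) / (sqrt(1 + alpha*sigma/2) + 1)`,
#' the fraction of the combined maximum division rate attributable to
#' kleptoplastidy. Lies in `[0, 1)` and increases in both arguments: a large
#' kleptoplast contribution (`alpha`) only pays off when the two feeding
#' modes are balanced (`sigma` near 1).
#'
#' @param alpha Normalized kleptoplast photosynthetic contribution, `>= 0`.
#' @param sigma Feeding-mode balance in `[0, 1]`.
#' @return kappa in `[0, 1)`. Vectorized.
#' @examples
#' kappa_from_alpha_sigma(5, 1)  # ~0.30
#' kappa_from_alpha_sigma(10, sigma_from_rates(0.22, 0.38)) # ~0.41
#' @export
kappa_from_alpha_sigma <- function(alpha, sigma) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]")
  .kappa_from_discriminant(alpha * sigma / 2)
}

#' Kleptoplastidy index from rates and acceleration
#'
#' Equivalent parameterization of the index in terms of the measurable
#' quantities: `kappa` as a function of `2 beta / (Omega1 + Omega2)^2`.
#' Identical to [kappa_from_alpha_sigma()] under `alpha = beta/(Omega1
#' Omega2)` and `sigma = 4 Omega1 Omega2 / (Omega1 + Omega2)^2`.
#'
#' @param Omega1,Omega2 Maximum division rates (divisions/day); sum `> 0`.
#' @param beta Kleptoplastidy acceleration (1/day^2), `>= 0`.
#' @return kappa in `[0, 1)`.
#' @export
kappa_from_beta <- function(Omega1, Omega2, beta) {
  if (Omega1 + Omega2 <= 0) stop("Omega1 + Omega2 must be > 0")
  if (any(beta < 0)) stop("beta must be >= 0")
  .kappa_from_discriminant(2 * beta / (Omega1 + Omega2)^2)
}

#' Combined maximum division rate and kleptoplastidy synergy
#'
#' From the quadratic biological-time relation for a linearly accelerating
#' division rate, the combined maximum rate is
#' `Omega12 = ((Omega1+Omega2)/2) * (sqrt(1 + 2 beta/(Omega1+Omega2)^2) + 1)`.
#' The synergy excess is `dOmega = Omega12 - (Omega1 + Omega2) >= 0` (zero
#' iff `beta = 0`) and the kleptoplastidy index is `kappa = dOmega / Omega12`.
#' `1/Omega12` equals the division interval from
#' [division_time_linear()]`(Omega1 + Omega2, beta)`.
#'
#' @param Omega1,Omega2 Maximum division rates (divisions/day); sum `> 0`.
#' @param beta Kleptoplastidy acceleration (1/day^2), `>= 0`.
#' @return An object of class `klepto_parameters`: `beta`, `alpha` (`NA` when
#'   either rate is zero), `sigma`, `kappa`, `Omega12`, `dOmega`.
#' @examples
#' combined_rate_and_synergy(0.22, 0.38, 0.836)
#' @export
combined_rate_and_synergy <- function(Omega1, Omega2, beta) {
  if (Omega1 < 0 || Omega2 < 0) stop("rates must be >= 0")
  if (Omega1 + Omega2 <= 0) stop("Omega1 + Omega2 must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  S <- Omega1 + Omega2
  Omega12 <- (S / 2) * (sqrt(1 + 2 * beta / S^2) + 1)
  dOmega <- Omega12 - S
  kappa <- dOmega / Omega12
  alpha <- if (Omega1 > 0 && Omega2 > 0) beta / (Omega1 * Omega2) else NA_real_
  structure(list(beta = beta, alpha = alpha,
                 sigma = sigma_from_rates(Omega1, Omega2),
                 kappa = kappa, Omega12 = Omega12, dOmega = dOmega),
            class = "klepto_parameters")
}

#' @export
print.klepto_parameters <- function(x, ...) {
  cat("Kleptoplastidy parameters\n")
  cat(sprintf("  beta    = %.6g /day^2\n", x$beta))
  cat(sprintf("  alpha   = %.6g, sigma = %.6g\n", x$alpha, x$sigma))
  cat(sprintf("  Omega12 = %.6g /day (synergy excess dOmega = %.6g /day)\n",
              x$Omega12, x$dOmega))
  cat(sprintf("  kappa   = %.6g (%.3g%% of the division rate)\n",
              x$kappa, 100 * x$kappa))
  invisible(x)
}

#' Sensitivity of the kleptoplastidy index at sigma = 1
#'
#' Closed-form partial derivatives of `kappa(alpha, sigma)` on the balanced
#' line `sigma = 1`, with `s = sqrt(1 + alpha/2)`:
#' `dkappa/dalpha = 1 / (2 s (s+1)^2)` and
#' `dkappa/dsigma = alpha / (2 s (s+1)^2)`.
#' Both are bounded well below 1 for all `alpha >= 0` (the index is stable to
#' small input perturbations): the alpha-derivative attains its maximum 1/8
#' at `alpha = 0` and the sigma-derivative stays strictly below 0.172.
#'
#' @param alpha Normalized kleptoplast contribution, `>= 0`. Vectorized.
#' @return A list with `dk_dalpha` and `dk_dsigma`.
#' @export
kappa_sensitivity_sigma1 <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  s <- sqrt(1 + alpha / 2)
  denom <- 2 * s * (s + 1)^2
  list(dk_dalpha = 1 / denom, dk_dsigma = alpha / denom)
}

#' Grid of kleptoplastidy-index values over (alpha, sigma)
#'
#' Evaluates `kappa` on a rectangular grid, e.g. for contour plots of the
#' index surface. Rows index alpha, columns sigma; dimnames carry the grid
#' coordinates so the matrix round-trips through CSV.
#'
#' @param alpha_range Numeric length-2, default `c(0, 5)`.
#' @param sigma_range Numeric length-2 within `[0, 1]`, default `c(0, 1)`.
#' @param n_alpha,n_sigma Grid resolutions.
#' @return A `n_alpha` x `n_sigma` matrix of kappa values.
#' @examples
#' kg <- kappa_grid()
#' max(kg) # ~0.30, at the (alpha = 5, sigma = 1) corner
#' @export
kappa_grid <- function(alpha_range = c(0, 5), sigma_range = c(0, 1),
                       n_alpha = 51, n_sigma = 51) {
  stopifnot(length(alpha_range) == 2, length(sigma_range) == 2,
            n_alpha >= 2, n_sigma >= 2)
  if (any(alpha_range < 0)) stop("alpha must be >= 0")
  if (any(sigma_range < 0 | sigma_range > 1)) stop("sigma must lie in [0, 1]")
  a <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  s <- seq(sigma_range[1], sigma_range[2], length.out = n_sigma)
  k <- outer(a, s, kappa_from_alpha_sigma)
  dimnames(k) <- list(alpha = format(a, trim = TRUE),
                      sigma = format(s, trim = TRUE))
  k
}

#' Write a kappa grid as CSV
#'
#' First column holds the alpha values, the header row the sigma values.
#'
#' @param grid A matrix from [kappa_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kappa_grid <- function(grid, path) {
  df <- data.frame(alpha = rownames(grid), grid, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
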