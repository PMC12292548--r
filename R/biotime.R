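#' Biological-time solutions for the division interval
#'
#' Biological time psi(t) is a dimensionless progress variable on `[0, 1]`
#' between two consecutive cell divisions, advancing at the instantaneous
#' division rate: `dpsi/dt = mu(t)`. The division interval `T` is the time at
#' which psi reaches 1. Three solvers are provided: a closed form for a
#' constant rate, a closed form for a rate that grows linearly in time (the
#' kleptoplastidy case), and an adaptive-quadrature solver for arbitrary
#' non-negative rate functions.
#'
#' @name biotime
NULL

new_biotime_solution <- function(T, psi, method) {
  structure(list(T = T, psi_of_t = psi, method = method),
            class = "biotime_solution")
}

#' @export
print.biotime_solution <- function(x, ...) {
  cat(sprintf("Division interval T = %.6g days (1/T = %.6g /day) [%s]\n",
              x$T, 1 / x$T, x$method))
  invisible(x)
}

#' Division interval for a constant division rate
#'
#' With `mu = Omega` constant, biological time integrates to `Omega * T = 1`,
#' so `T = 1/Omega`.
#'
#' @param omega Constant division rate (divisions/day), `> 0`.
#' @return A `biotime_solution` with `T = 1/omega`.
#' @examples
#' division_time_constant(0.22)$T # ~4.55 days
#' @export
division_time_constant <- function(omega) {
  if (omega <= 0) stop("no division: omega must be > 0")
  new_biotime_solution(T = 1 / omega,
                       psi = function(t) pmin(omega * t, 1),
                       method = "closed_form_constant")
}

#' Division interval for a linearly increasing division rate
#'
#' With `mu(t) = omega0 + beta * t` (constant baseline plus kleptoplastidy
#' acceleration), integrating biological time gives the quadratic
#' `1 = omega0 * T + beta * T^2 / 2`, which has exactly one positive root.
#' The root is evaluated in the rationalized form
#' `T = 2 / (omega0 + sqrt(omega0^2 + 2 beta))`, which is cancellation-safe
#' when `beta` is small relative to `omega0^2` and degrades gracefully to
#' `1/omega0` at `beta = 0`.
#'
#' @param omega0 Baseline division rate (divisions/day), `>= 0`.
#' @param beta Kleptoplastidy acceleration (1/day^2), `>= 0`. Not both zero.
#' @return A `biotime_solution`; `1/T` is the combined maximum division rate.
#' @examples
#' division_time_linear(0.60, 0.836) # 1/T ~ 1.013 divisions/day
#' @export
division_time_linear <- function(omega0, beta) {
  if (omega0 < 0 || beta < 0) stop("omega0 and beta must be >= 0")
  if (omega0 == 0 && beta == 0) stop("no division: omega0 and beta both zero")
  T <- 2 / (omega0 + sqrt(omega0^2 + 2 * beta))
  new_biotime_solution(T = T,
                       psi = function(t) pmin(omega0 * t + beta * t^2 / 2, 1),
                       method = "closed_form_linear")
}

#' Division interval for an arbitrary time-dependent division rate
#'
#' Finds the smallest `t` with `integral_0^t mu(s) ds = 1` by adaptive
#' quadrature plus root bracketing on `[0, t_max]`.
#'
#' @param mu_of_t Vectorized non-negative rate function of time (days ->
#'   divisions/day).
#' @param t_max Search horizon in days. The default of 365 days prevents an
#'   unbounded search when the rate is near zero.
#' @param tol Relative tolerance on `T`.
#' @return A `biotime_solution` with `method = "numeric"`.
#' @examples
#' division_time_numeric(function(t) 0.60 + 0.836 * t)$T
#' @export
division_time_numeric <- function(mu_of_t, t_max = 365, tol = 1e-8) {
  stopifnot(is.function(mu_of_t), t_max > 0)
  Psi <- function(t) {
    if (t == 0) return(0)
    stats::integrate(mu_of_t, 0, t, rel.tol = tol / 10,
                     abs.tol = tol / 10)$value
  }
  total <- Psi(t_max)
  if (total < 1)
    stop(sprintf(
      "horizon too short: integral of mu over [0, %g] is %.4g < 1",
      t_max, total))
  root <- stats::uniroot(function(t) Psi(t) - 1, lower = 0, upper = t_max,
                         tol = tol * min(1, t_max))
  T <- root$root
  new_biotime_solution(T = T,
                       psi = function(t) pmin(vapply(pmin(t, T), Psi,
                                                     numeric(1)), 1),
                       method = "numeric")
}
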