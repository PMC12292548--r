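#' Resource environment for a mixotrophic protist
#'
#' Describes the availability of one inorganic resource (dissolved nutrients
#' used by photosynthesis) and one organic resource (chloroplast-bearing prey
#' cells). Concentrations can be supplied either raw, as `(R, K)` pairs in
#' ug/L, or already normalized as `r = R/K`; mixing the two conventions in one
#' call is rejected because the normalized values would be ambiguous.
#'
#' @param R1,R2 Raw concentrations of the inorganic and organic resource
#'   (ug/L). Supply together with `K1`, `K2`.
#' @param K1,K2 Half-saturation constants (ug/L); strictly positive.
#' @param r1,r2 Pre-normalized concentrations `R/K` (dimensionless).
#'   Mutually exclusive with the raw form.
#' @return An object of class `resource_environment` with elements `r1`, `r2`
#'   (always populated) and, for the raw form, `R1`, `K1`, `R2`, `K2`.
#' @examples
#' resource_environment(R1 = 50, K1 = 5, R2 = 30, K2 = 10)
#' resource_environment(r1 = 10, r2 = 3)
#' @export
resource_environment <- function(R1 = NULL, K1 = NULL, R2 = NULL, K2 = NULL,
                                 r1 = NULL, r2 = NULL) {
  raw  <- !is.null(R1) || !is.null(K1) || !is.null(R2) || !is.null(K2)
  norm <- !is.null(r1) || !is.null(r2)
  if (raw && norm)
    stop("supply either raw (R, K) pairs or normalized r values, not both")
  if (raw) {
    for (nm in c("R1", "K1", "R2", "K2"))
      if (is.null(get(nm))) stop("raw form requires all of R1, K1, R2, K2")
    if (R1 < 0 || R2 < 0) stop("resource concentrations must be >= 0")
    if (K1 <= 0 || K2 <= 0) stop("half-saturation constants must be > 0")
    env <- list(R1 = R1, K1 = K1, R2 = R2, K2 = K2,
                r1 = R1 / K1, r2 = R2 / K2)
  } else {
    if (is.null(r1) || is.null(r2))
      stop("normalized form requires both r1 and r2")
    if (r1 < 0 || r2 < 0) stop("normalized concentrations must be >= 0")
    env <- list(r1 = r1, r2 = r2)
  }
  structure(env, class = "resource_environment")
}

#' @export
print.resource_environment <- function(x, ...) {
  cat("Resource environment\n")
  if (!is.null(x$R1))
    cat(sprintf("  inorganic: R1 = %g, K1 = %g ug/L\n  organic:   R2 = %g, K2 = %g ug/L\n",
                x$R1, x$K1, x$R2, x$K2))
  cat(sprintf("  normalized: r1 = %g, r2 = %g\n", x$r1, x$r2))
  invisible(x)
}

#' Classify an environment as resource-rich
#'
#' An environment is rich in a resource when its normalized concentration is
#' far above the half-saturation constant, so the Monod factor is effectively
#' saturated. The default cutoff `r >= 100` keeps the saturation error of
#' `r/(1+r)` below 1%.
#'
#' @param env A [resource_environment()].
#' @param threshold Dimensionless cutoff operationalizing "much greater
#'   than 1".
#' @return A list with logical `is_rich_1`, `is_rich_2` and the `threshold`
#'   used.
#' @export
rich_environment_flag <- function(env, threshold = 100) {
  stopifnot(inherits(env, "resource_environment"), threshold > 0)
  list(is_rich_1 = env$r1 >= threshold,
       is_rich_2 = env$r2 >= threshold,
       threshold = threshold)
}

#' Monod division rate for a single resource
#'
#' The saturating division-rate law `mu = Omega * r / (1 + r)` written in the
#' normalized concentration `r = R/K`. The rate is strictly below the maximum
#' `Omega` for any finite `r` and approaches it in resource-rich conditions.
#'
#' @param omega_max Maximum division rate (divisions/day), `>= 0`.
#' @param r Normalized resource concentration, `>= 0`. Vectorized.
#' @return Division rate in divisions/day.
#' @examples
#' monod_rate(1, 1)      # half-saturation midpoint: 0.5
#' monod_rate(0.22, 1e6) # saturated: ~0.22
#' @export
monod_rate <- function(omega_max, r) {
  if (any(omega_max < 0)) stop("omega_max must be >= 0")
  if (any(r < 0)) stop("normalized concentration r must be >= 0")
  omega_max * r / (1 + r)
}

#' Division rate on two substitutable resources
#'
#' Additive Monod kinetics for one inorganic and one organic resource:
#' `mu = Omega1 r1/(1+r1) + Omega2 r2/(1+r2)`, bounded above by
#' `Omega1 + Omega2`.
#'
#' @param traits A [protist_traits()] object (only `Omega1`, `Omega2` used).
#' @param env A [resource_environment()].
#' @return Division rate in divisions/day.
#' @examples
#' tr <- protist_traits(Omega1 = 0.22, Omega2 = 0.38)
#' two_resource_rate(tr, resource_environment(r1 = 1, r2 = 3)) # 0.395
#' @export
two_resource_rate <- function(traits, env) {
  stopifnot(inherits(traits, "protist_traits"),
            inherits(env, "resource_environment"))
  monod_rate(traits$Omega1, env$r1) + monod_rate(traits$Omega2, env$r2)
}

#' Mixotrophic division rate at arbitrary resource concentrations
#'
#' Generalizes the resource-rich mixotrophy law to moderate concentrations:
#' the autotrophic and heterotrophic Monod terms are each scaled by their own
#' saturation factor, and the kleptoplastidy acceleration term `beta * t` is
#' scaled by the *product* of the two factors — kleptoplastidy is synergistic
#' and vanishes whenever either resource is absent.
#'
#' The returned value carries the attribute `note =
#' "unvalidated generalization"`: this moderate-concentration form has not
#' been established against experimental data and should be treated as a
#' modelling hypothesis.
#'
#' @param traits A [protist_traits()] object.
#' @param beta Kleptoplastidy acceleration (1/day^2), `>= 0`.
#' @param env A [resource_environment()].
#' @param t Time since the last division (days), `>= 0`.
#' @return Division rate in divisions/day, with attribute `note`.
#' @export
mixotrophic_rate_general <- function(traits, beta, env, t) {
  stopifnot(inherits(traits, "protist_traits"),
            inherits(env, "resource_environment"))
  if (beta < 0) stop("beta must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  f1 <- env$r1 / (1 + env$r1)
  f2 <- env$r2 / (1 + env$r2)
  mu <- traits$Omega1 * f1 + traits$Omega2 * f2 + beta * t * f1 * f2
  attr(mu, "note") <- "unvalidated generalization"
  mu
}
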