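#' Exponential growth trajectory
#'
#' Population concentration under exponential growth at a constant division
#' rate: `c/c0 = exp(rate * t)`. The natural-exponential convention is used
#' deliberately — "division rate" here is the specific growth rate `mu` of
#' the Monod law (`dc/dt = mu c`), not a binary-fission doubling rate, and
#' only base e reproduces a three-orders-of-magnitude gain over 7 days at
#' 1 division/day (base 2 would give barely two orders).
#'
#' @param rate Division rate (divisions/day).
#' @param t_end Horizon in days, `> 0`. Default one week.
#' @param n_points Grid size, `>= 2`. Default 169 (hourly over a week).
#' @param scenario_label Optional label attached to the trajectory.
#' @return A data frame of class `growth_trajectory` with columns `t_days`
#'   and `c_over_c0`, and attributes `rate` and `scenario_label`.
#' @examples
#' tail(exponential_trajectory(1, t_end = 7), 1) # c/c0 ~ 1097
#' @export
exponential_trajectory <- function(rate, t_end = 7, n_points = 169,
                                   scenario_label = NULL) {
  stopifnot(t_end > 0, n_points >= 2)
  t <- seq(0, t_end, length.out = n_points)
  structure(data.frame(t_days = t, c_over_c0 = exp(rate * t)),
            rate = rate, scenario_label = scenario_label,
            class = c("growth_trajectory", "data.frame"))
}

#' The four bloom scenarios
#'
#' Exponential trajectories for the four canonical resource conditions:
#' \enumerate{
#'   \item inorganic-rich only — rate `Omega1` (autotrophy);
#'   \item organic-rich only — rate `Omega2` (heterotrophy);
#'   \item rich in both, kleptoplastidy suppressed — rate `Omega1 + Omega2`;
#'   \item rich in both, kleptoplastidy operational — rate `Omega12`.
#' }
#'
#' @param Omega1,Omega2 Maximum division rates (divisions/day).
#' @param beta Kleptoplastidy acceleration (1/day^2).
#' @param t_end,n_points Grid, as in [exponential_trajectory()].
#' @param rounded Round the scenario-4 rate to the nearest integer before
#'   simulating (to mimic presentations that quote the rounded rate);
#'   default uses the exact combined rate.
#' @return A named list of four `growth_trajectory` objects.
#' @examples
#' sc <- four_scenarios(0.22, 0.38, 0.836)
#' vapply(sc, attr, numeric(1), "rate")
#' @export
four_scenarios <- function(Omega1, Omega2, beta, t_end = 7, n_points = 169,
                           rounded = FALSE) {
  Omega12 <- combined_rate_and_synergy(Omega1, Omega2, beta)$Omega12
  if (rounded) Omega12 <- round(Omega12)
  rates <- c(inorganic_only = Omega1, organic_only = Omega2,
             both_no_klepto = Omega1 + Omega2, both_klepto = Omega12)
  out <- lapply(seq_along(rates), function(i)
    exponential_trajectory(rates[[i]], t_end, n_points,
                           scenario_label = names(rates)[i]))
  names(out) <- names(rates)
  out
}

#' Flatten scenario trajectories to one long data frame
#'
#' @param scenarios List of `growth_trajectory` objects from
#'   [four_scenarios()].
#' @return Data frame with columns `scenario`, `t_days`, `c_over_c0`.
#' @export
scenarios_to_data_frame <- function(scenarios) {
  do.call(rbind, lapply(scenarios, function(tr)
    data.frame(scenario = attr(tr, "scenario_label"),
               t_days = tr$t_days, c_over_c0 = tr$c_over_c0,
               row.names = NULL)))
}

#' Multi-species community specification
#'
#' Parameter container for `N` protist species feeding on `N1` inorganic and
#' `N2` organic resource types: per-species maximum rates for each resource
#' and a kleptoplastidy acceleration for each (inorganic, organic) pair. The
#' model has `N * (N1 + N2 + N1*N2)` parameters in total.
#'
#' @param Omega1_matrix `N x N1` matrix of inorganic maximum rates
#'   (divisions/day).
#' @param Omega2_matrix `N x N2` matrix of organic maximum rates.
#' @param beta_tensor `N x N1 x N2` array of accelerations (1/day^2).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(Omega1_matrix, Omega2_matrix, beta_tensor) {
  Omega1_matrix <- as.matrix(Omega1_matrix)
  Omega2_matrix <- as.matrix(Omega2_matrix)
  N <- nrow(Omega1_matrix)
  N1 <- ncol(Omega1_matrix)
  N2 <- ncol(Omega2_matrix)
  if (nrow(Omega2_matrix) != N)
    stop("Omega1_matrix and Omega2_matrix must have the same number of rows")
  if (!identical(dim(beta_tensor), as.integer(c(N, N1, N2))))
    stop(sprintf("beta_tensor must have dimensions %d x %d x %d", N, N1, N2))
  if (any(Omega1_matrix < 0) || any(Omega2_matrix < 0) || any(beta_tensor < 0))
    stop("all community parameters must be >= 0")
  structure(list(N = N, N1 = N1, N2 = N2,
                 Omega1_matrix = Omega1_matrix,
                 Omega2_matrix = Omega2_matrix,
                 beta_tensor = beta_tensor),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    "Community: %d species, %d inorganic + %d organic resources (%d parameters)\n",
    x$N, x$N1, x$N2, x$N * (x$N1 + x$N2 + x$N1 * x$N2)))
  invisible(x)
}

#' Per-species division rates in a resource-rich multi-species community
#'
#' In environments rich in every resource, each species grows at the sum of
#' its autotrophic maxima, its heterotrophic maxima, and the accumulated
#' kleptoplastidy terms: `mu_i = sum_j Omega1[i,j] + sum_k Omega2[i,k] +
#' sum_jk beta[i,j,k] * t`. Species evolve independently (no competition or
#' resource depletion).
#'
#' @param spec A [community_spec()].
#' @param t Time since last division (days), `>= 0`.
#' @return Numeric vector of length `N` (divisions/day).
#' @export
multispecies_rates <- function(spec, t) {
  stopifnot(inherits(spec, "community_spec"))
  if (t < 0) stop("t must be >= 0")
  rowSums(spec$Omega1_matrix) + rowSums(spec$Omega2_matrix) +
    apply(spec$beta_tensor, 1, sum) * t
}
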