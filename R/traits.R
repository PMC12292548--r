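#' Morpho-physiological traits of a mixotrophic protist
#'
#' Bundles the maximum division rates on each resource with the
#' morpho-physiological quantities that determine the mechanistic
#' kleptoplastidy acceleration: chloroplast masses, digestion time, and the
#' relative photosynthetic efficiency of kleptoplasts. Volume analogues
#' (`v1`, `V1`, `Vf`) support the equal-mass-density route to the
#' dimensionless parameter alpha when masses are unavailable.
#'
#' @param Omega1 Maximum division rate on the inorganic resource
#'   (divisions/day).
#' @param Omega2 Maximum division rate on the organic resource
#'   (divisions/day).
#' @param M1 Mass of the protist's native chloroplasts (ug).
#' @param m1 Chloroplast mass of one prey cell (ug).
#' @param tau Time to digest one prey cell (days); must be positive when
#'   heterotrophy is modelled.
#' @param gamma Photosynthetic efficiency of a unit kleptoplast mass relative
#'   to native chloroplasts (dimensionless). Bounded to `[0, 1]` by default
#'   because acquired chloroplasts sit away from the cell surface in inferior
#'   light conditions; set `allow_gamma_gt_1 = TRUE` to lift the bound.
#' @param v1 Chloroplast volume of one prey cell (um^3).
#' @param V1 Native chloroplast volume of the protist (um^3).
#' @param Vf Free cell volume available for accumulating kleptoplasts (um^3).
#' @param allow_gamma_gt_1 Permit `gamma > 1`.
#' @return An object of class `protist_traits`.
#' @examples
#' protist_traits(Omega1 = 0.22, Omega2 = 0.38)
#' @export
protist_traits <- function(Omega1, Omega2,
                           M1 = NA_real_, m1 = NA_real_, tau = NA_real_,
                           gamma = 1,
                           v1 = NA_real_, V1 = NA_real_, Vf = NA_real_,
                           allow_gamma_gt_1 = FALSE) {
  if (Omega1 < 0 || Omega2 < 0) stop("maximum division rates must be >= 0")
  num <- c(M1 = M1, m1 = m1, v1 = v1, V1 = V1, Vf = Vf)
  if (any(!is.na(num) & num < 0)) stop("masses and volumes must be >= 0")
  if (!is.na(tau) && tau <= 0) stop("digestion time tau must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (gamma > 1 && !allow_gamma_gt_1)
    stop("gamma > 1 is disallowed by default; set allow_gamma_gt_1 = TRUE")
  structure(list(Omega1 = Omega1, Omega2 = Omega2,
                 M1 = M1, m1 = m1, tau = tau, gamma = gamma,
                 v1 = v1, V1 = V1, Vf = Vf),
            class = "protist_traits")
}

#' @export
print.protist_traits <- function(x, ...) {
  cat("Protist traits\n")
  cat(sprintf("  Omega1 = %g /day (inorganic), Omega2 = %g /day (organic)\n",
              x$Omega1, x$Omega2))
  cat(sprintf("  gamma = %g", x$gamma))
  if (!is.na(x$M1) || !is.na(x$m1) || !is.na(x$tau))
    cat(sprintf("; M1 = %g ug, m1 = %g ug, tau = %g d", x$M1, x$m1, x$tau))
  cat("\n")
  if (!is.na(x$V1) || !is.na(x$v1) || !is.na(x$Vf))
    cat(sprintf("  volumes: v1 = %g, V1 = %g, Vf = %g um^3\n",
                x$v1, x$V1, x$Vf))
  invisible(x)
}
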