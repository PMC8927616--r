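#' Symmetric totally mixed Nash equilibrium curve
#'
#' At a symmetric totally mixed Nash equilibrium in memory-one strategies,
#' player 1 must be indifferent in both coordinates: the partial derivatives
#' of the stationary payoff with respect to player 1's `alpha` and `gamma`,
#' evaluated at the symmetric point, both vanish.  Both derivatives share the
#' conic factor
#' \deqn{5\alpha^2 + 9\gamma^2 - 14\alpha\gamma + 14\alpha - 10\gamma + 1 = 0,}
#' which is the operative ("derived") equilibrium curve inside the unit
#' square.  A previously reported version of this conic omits the term linear
#' in `alpha` (`variant = "printed"`, `5a^2 + 9g^2 - 14ag - 10g + 1`); it is
#' retained for transparency but is inconsistent with the curve's known
#' properties (it admits unit-square solutions with tolerance to defection far
#' above 0.3) and is not used by any solver in this package.
#'
#' Both variants share the `alpha = 0` endpoints `gamma = 1/9` and
#' `gamma = 1`.
#'
#' @param alpha,gamma Probabilities in \[0, 1\] (vectorized, recycled).
#' @param variant `"derived"` (default) or `"printed"`.
#' @return `nash_implicit()` returns the numeric residual of the conic (zero
#'   exactly on the curve).
#' @seealso [nash_points()], [max_tolerance()], [foc_residuals()]
#' @export
nash_implicit <- function(alpha, gamma, variant = c("derived", "printed")) {
  variant <- match.arg(variant)
  if (any(alpha < 0 | alpha > 1 | gamma < 0 | gamma > 1, na.rm = TRUE))
    stop("alpha and gamma must lie in [0, 1]", call. = FALSE)
  k <- nash_conic_coefficients(variant)
  k[["a2"]] * alpha^2 + k[["g2"]] * gamma^2 + k[["ag"]] * alpha * gamma +
    k[["a1"]] * alpha + k[["g1"]] * gamma + k[["c0"]]
}

nash_conic_coefficients <- function(variant = c("derived", "printed")) {
  variant <- match.arg(variant)
  c(a2 = 5, g2 = 9, ag = -14, a1 = if (variant == "derived") 14 else 0,
    g1 = -10, c0 = 1)
}

#' Gamma-roots of the Nash conic at fixed alpha
#'
#' Solves the conic as a quadratic in `gamma` for a given `alpha`.  Used to
#' parameterize the curve branch-wise.
#'
#' @param alpha Probability (scalar).
#' @inheritParams nash_implicit
#' @param clamp_tol Negative discriminants larger than `-clamp_tol` are
#'   treated as zero (branch-merge point).
#' @return Numeric vector of 0, 1 or 2 roots (ascending), possibly outside
#'   \[0, 1\]; `numeric(0)` when the discriminant is negative.
#' @export
nash_gamma_roots <- function(alpha, variant = c("derived", "printed"),
                             clamp_tol = 1e-10) {
  variant <- match.arg(variant)
  k <- nash_conic_coefficients(variant)
  A <- k[["g2"]]
  B <- k[["ag"]] * alpha + k[["g1"]]
  C <- k[["a2"]] * alpha^2 + k[["a1"]] * alpha + k[["c0"]]
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    if (disc > -clamp_tol) disc <- 0 else return(numeric(0))
  }
  sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
}

#' Maximal tolerance to defection on the Nash curve
#'
#' The largest `alpha` attained on the symmetric totally mixed Nash curve
#' within the unit square.  It is the point where the curve's two
#' gamma-branches merge, i.e. the root of the discriminant of the
#' gamma-quadratic, computed here in closed form.  For the derived conic the
#' discriminant is `16 (alpha^2 - 14 alpha + 4)`, whose relevant root is
#' `7 - 3 sqrt(5)` (approximately 0.2918).
#'
#' @inheritParams nash_implicit
#' @return Numeric scalar, the supremum of `alpha` over the curve.
#' @export
max_tolerance <- function(variant = c("derived", "printed")) {
  variant <- match.arg(variant)
  # the curve still has a unit-square point at alpha = 1 (printed variant)
  r1 <- nash_gamma_roots(1, variant, clamp_tol = 0)
  if (length(r1) > 0L && any(r1 >= 0 & r1 <= 1)) return(1)
  k <- nash_conic_coefficients(variant)
  # discriminant of the gamma-quadratic, as a quadratic in alpha
  A <- k[["ag"]]^2 - 4 * k[["g2"]] * k[["a2"]]
  B <- 2 * k[["ag"]] * k[["g1"]] - 4 * k[["g2"]] * k[["a1"]]
  C <- k[["g1"]]^2 - 4 * k[["g2"]] * k[["c0"]]
  roots <- sort(Re(polyroot(c(C, B, A))))
  inside <- roots[roots > 0 & roots <= 1]
  if (length(inside) == 0L)
    stop("no discriminant root in (0, 1]; curve unbounded in alpha",
         call. = FALSE)
  min(inside)
}

#' Sample points along the Nash curve
#'
#' Returns `n` points along the derived-variant curve, ordered by a monotone
#' parameterization that runs from the endpoint `(0, 1/9)` up the lower
#' gamma-branch to the branch-merge point at [max_tolerance()], then back
#' along the upper branch to `(0, 1)`.
#'
#' @param n Number of points (at least 2).
#' @inheritParams nash_implicit
#' @return A data frame with columns `alpha`, `gamma`.
#' @export
nash_points <- function(n, variant = c("derived", "printed")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  n <- as.integer(n)
  amax <- max_tolerance(variant)
  t <- seq(0, 1, length.out = n)
  alpha <- ifelse(t <= 0.5, 2 * t, 2 - 2 * t) * amax
  lower <- t <= 0.5
  gamma <- vapply(seq_len(n), function(i) {
    r <- nash_gamma_roots(alpha[i], variant, clamp_tol = 1e-8)
    if (length(r) == 0L) return(NA_real_)
    if (lower[i]) r[1L] else r[length(r)]
  }, numeric(1))
  data.frame(alpha = alpha, gamma = gamma)
}

#' Numeric first-order conditions at a symmetric point
#'
#' Central-difference partial derivatives of player 1's stationary payoff
#' with respect to its own `alpha` and `gamma`, holding the opponent fixed at
#' the same `(alpha, gamma)`.  Both vanish exactly on the totally mixed Nash
#' curve; this is the independent oracle against which the closed-form conic
#' is verified.
#'
#' @param alpha,gamma Interior probabilities (scalars).
#' @inheritParams payoff_coefficients
#' @param step Central-difference step.
#' @return Named numeric vector `c(dU_dalpha1, dU_dgamma1)`.
#' @export
foc_residuals <- function(alpha, gamma, payoffs = payoff_matrix(),
                          step = 1e-6) {
  stopifnot(length(alpha) == 1L, length(gamma) == 1L)
  f <- function(a1, g1)
    profile_payoff(c(a1, g1, alpha, gamma), payoffs)
  c(dU_dalpha1 = (f(alpha + step, gamma) - f(alpha - step, gamma)) / (2 * step),
    dU_dgamma1 = (f(alpha, gamma + step) - f(alpha, gamma - step)) / (2 * step))
}
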