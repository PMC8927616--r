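#' First intersection of the traced QRE branch with the Nash curve
#'
#' Locates the first rationality value at which the derived Nash conic
#' changes sign along a continuation trace, then refines the crossing by
#' bisection, re-solving the QRE with warm starts, until the bracketing
#' lambda interval is narrower than `refine_width`.
#'
#' @param trace A [trace_qre()] result starting at `lambda = 0`.
#' @param variant Nash-curve variant handed to [nash_implicit()].  The
#'   printed variant is available for comparison but does not intersect the
#'   traced branch.
#' @param refine_width Bisection stops when the lambda bracket is narrower
#'   than this.
#' @inheritParams payoff_coefficients
#' @return A list with `lambda_intersect`, `alpha_intersect`,
#'   `gamma_intersect`.
#' @export
find_nash_intersection <- function(trace, variant = c("derived", "printed"),
                                   refine_width = 1e-3,
                                   payoffs = payoff_matrix()) {
  variant <- match.arg(variant)
  stopifnot(inherits(trace, "qre_trace"), nrow(trace) >= 2L)
  config <- attr(trace, "config")
  vals <- nash_implicit(pmin(pmax(trace$alpha, 0), 1),
                        pmin(pmax(trace$gamma, 0), 1), variant)
  s <- sign(vals)
  flip <- which(s[-1L] != s[-length(s)] & s[-1L] != 0)
  if (length(flip) == 0L)
    stop("no crossing: the Nash implicit function does not change sign ",
         "along the trace", call. = FALSE)
  i <- flip[1L]
  lo <- trace$lambda[i]; hi <- trace$lambda[i + 1L]
  sign_lo <- s[i]
  pt <- c(trace$alpha[i], trace$gamma[i])
  while (hi - lo > refine_width) {
    mid <- (lo + hi) / 2
    sol <- solve_qre(mid, config, warm_start = pt, payoffs = payoffs)
    v <- nash_implicit(min(max(sol$alpha, 0), 1),
                       min(max(sol$gamma, 0), 1), variant)
    if (sign(v) == sign_lo) {
      lo <- mid; pt <- c(sol$alpha, sol$gamma)
    } else hi <- mid
  }
  sol <- solve_qre((lo + hi) / 2, config, warm_start = pt, payoffs = payoffs)
  list(lambda_intersect = (lo + hi) / 2,
       alpha_intersect = sol$alpha, gamma_intersect = sol$gamma)
}

#' Collapse threshold of a trace toward the defection point
#'
#' The smallest grid rationality value from which every subsequent trace
#' solution lies within Euclidean distance `delta` of the pure-defection
#' point (0, 0).  An error is raised when the tail never enters the
#' delta-ball — which is the honest outcome for the default global-minimum
#' trace: the equilibrium branch continues toward a cooperative boundary
#' equilibrium and never approaches (0, 0) (see the methods vignette and
#' [find_defection_onset()]).
#'
#' @param trace A [trace_qre()] result.
#' @param delta Radius of the ball around (0, 0).
#' @return The threshold rationality value (scalar).
#' @export
find_collapse_threshold <- function(trace, delta = 0.05) {
  stopifnot(inherits(trace, "qre_trace"), delta > 0)
  d <- sqrt(trace$alpha^2 + trace$gamma^2)
  inside <- d < delta
  tail_ok <- rev(cumprod(rev(inside))) == 1
  if (!any(tail_ok))
    stop("no collapse: the trace tail never remains within ", delta,
         " of the defection point (0, 0)", call. = FALSE)
  trace$lambda[which(tail_ok)[1L]]
}

#' Onset of the defection collapse of a single-start trace
#'
#' A plain single-start solver traced over increasing rationality abandons
#' the cooperative equilibrium branch at some rationality value and descends
#' into a non-equilibrium residual minimum in the defection basin, whose
#' minimizer approaches (0, 0) as rationality grows.  This function returns
#' the smallest grid rationality value from which every subsequent solution
#' fails the fixed-point test (residual at or above `residual_tol`), i.e.
#' the onset of that permanent departure.
#'
#' @param trace A [trace_qre()] result, typically
#'   `trace_qre(method = "single_start")`.
#' @param residual_tol Residuals below this count as genuine equilibria.
#' @return The onset rationality value (scalar).
#' @export
find_defection_onset <- function(trace, residual_tol = 1e-6) {
  stopifnot(inherits(trace, "qre_trace"), residual_tol > 0)
  off <- trace$residual >= residual_tol
  tail_off <- rev(cumprod(rev(off))) == 1
  if (!any(tail_off))
    stop("no defection onset: the trace still ends on the equilibrium ",
         "manifold (residual < ", residual_tol, ")", call. = FALSE)
  i <- which(tail_off)[1L]
  if (i == 1L)
    stop("trace never starts on the equilibrium manifold; cannot locate ",
         "a departure", call. = FALSE)
  n <- nrow(trace)
  d_end <- sqrt(trace$alpha[n]^2 + trace$gamma[n]^2)
  d_before <- sqrt(trace$alpha[i - 1L]^2 + trace$gamma[i - 1L]^2)
  if (d_end >= d_before)
    stop("trace left the equilibrium manifold but its tail does not ",
         "descend toward the defection point", call. = FALSE)
  trace$lambda[i]
}

#' Small-rationality segment of a trace
#'
#' The traced QRE points with rationality at or below `lambda_max`
#' (typically the Nash-intersection rationality), as an ordered polyline.
#' This segment acts as the phase boundary separating low- from
#' high-cooperation strategies.
#'
#' @param trace A [trace_qre()] result.
#' @param lambda_max Upper rationality cut-off.
#' @return A data frame with columns `lambda`, `alpha`, `gamma`.
#' @export
qre_segment <- function(trace, lambda_max) {
  stopifnot(inherits(trace, "qre_trace"))
  out <- trace[trace$lambda <= lambda_max, c("lambda", "alpha", "gamma")]
  if (nrow(out) == 0L)
    stop("no trace points at or below lambda_max = ", lambda_max,
         call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a strategy point against the phase-boundary segment
#'
#' Computes the nearest point on the segment polyline to
#' `(alpha_hat, gamma_hat)`.  The point is labelled `"near"` when its
#' distance to the segment is below `near_tol`, otherwise `"above"` when its
#' mutual-cooperation coordinate exceeds that of the nearest segment point
#' and `"below"` otherwise.
#'
#' @param alpha_hat,gamma_hat Strategy coordinates (scalars).
#' @param segment A polyline: data frame or matrix with `alpha`, `gamma`
#'   columns (e.g. from [qre_segment()]).
#' @param near_tol Half-width of the `"near"` band.
#' @return A list with `label` (`"above"`, `"below"` or `"near"`),
#'   `distance`, and `nearest` (named vector `c(alpha, gamma)`).
#' @export
classify_point <- function(alpha_hat, gamma_hat, segment, near_tol = 0.05) {
  stopifnot(length(alpha_hat) == 1L, length(gamma_hat) == 1L)
  seg <- as.matrix(as.data.frame(segment)[, c("alpha", "gamma")])
  if (nrow(seg) < 1L) stop("segment is empty", call. = FALSE)
  if (nrow(seg) == 1L) {
    nearest <- seg[1L, ]
  } else {
    p <- seg[-nrow(seg), , drop = FALSE]
    q <- seg[-1L, , drop = FALSE]
    v <- q - p
    len2 <- rowSums(v^2)
    w <- cbind(alpha_hat - p[, 1L], gamma_hat - p[, 2L])
    t <- rowSums(w * v) / pmax(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    proj <- p + v * t
    d2 <- (proj[, 1L] - alpha_hat)^2 + (proj[, 2L] - gamma_hat)^2
    nearest <- proj[which.min(d2), ]
  }
  dist <- sqrt((nearest[1L] - alpha_hat)^2 + (nearest[2L] - gamma_hat)^2)
  label <- if (dist < near_tol) "near"
           else if (gamma_hat > nearest[2L]) "above" else "below"
  list(label = label, distance = unname(dist),
       nearest = c(alpha = unname(nearest[1L]), gamma = unname(nearest[2L])))
}

#' Compute all QRE landmarks
#'
#' Convenience wrapper that traces the QRE and extracts the numeric
#' landmarks: the first intersection with the derived Nash curve (via the
#' global-minimum continuation trace up to `lambda_max`) and the defection
#' onset (via a single-start trace up to `lambda_max_single`).
#'
#' @param lambda_max Upper end of the continuation trace.
#' @param lambda_max_single Upper end of the single-start trace.
#' @param step Rationality grid step for both traces.
#' @inheritParams payoff_coefficients
#' @param config Optional [solver_config()] overriding the grid defaults
#'   (its `lambda_grid` is replaced by the requested grids).
#' @return A list with `lambda_intersect`, `alpha_intersect`,
#'   `gamma_intersect`, `lambda_collapse`, `segment`, and the two traces
#'   (`trace`, `trace_single`).
#' @export
qre_landmarks <- function(lambda_max = 8, lambda_max_single = 10,
                          step = 0.01, payoffs = payoff_matrix(),
                          config = solver_config()) {
  cfg_main <- config
  cfg_main$lambda_grid <- seq(0, lambda_max, by = step)
  trace <- trace_qre(cfg_main, method = "multistart", payoffs = payoffs)
  hit <- find_nash_intersection(trace, payoffs = payoffs)
  cfg_single <- config
  cfg_single$lambda_grid <- seq(0, lambda_max_single, by = step)
  trace_single <- trace_qre(cfg_single, method = "single_start",
                            payoffs = payoffs)
  onset <- find_defection_onset(trace_single)
  seg <- qre_segment(trace, hit$lambda_intersect)
  # close the polyline with the refined crossing point itself
  seg <- rbind(seg, data.frame(lambda = hit$lambda_intersect,
                               alpha = hit$alpha_intersect,
                               gamma = hit$gamma_intersect))
  c(hit, list(lambda_collapse = onset, segment = seg, trace = trace,
              trace_single = trace_single))
}
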