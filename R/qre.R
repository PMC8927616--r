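#' Restricted stationary cooperation probabilities
#'
#' The logit system compares the payoff of each of player 1's pure-strategy
#' restrictions (`alpha = 0`, `alpha = 1`, `gamma = 0`, `gamma = 1`) against
#' the symmetric point `(alpha, gamma)`.  The restriction is substituted for
#' player 1 in the *asymmetric* stationary-state formulas before the
#' remaining parameters are symmetrized, so the resulting pairs are
#' intentionally not symmetric in `(p1, p2)` and retain `alpha` (resp.
#' `gamma`) inside the `alpha = 0` (resp. other) expressions:
#' \deqn{p_1|_{\alpha=0} = \frac{\alpha\gamma}{1+\gamma(\alpha-\gamma)},\qquad
#'       p_2|_{\alpha=0} = \frac{\alpha}{1+\gamma(\alpha-\gamma)},}
#' and analogously for the other three restrictions.  Symmetrizing *before*
#' the substitution would collapse these four cases to a much poorer set and
#' is not what this package computes.
#'
#' @param alpha,gamma Probabilities in \[0, 1\] (scalars).
#' @param which One of `"alpha0"`, `"alpha1"`, `"gamma0"`, `"gamma1"`.
#' @param tol Degenerate-denominator tolerance.
#' @return Named numeric vector `c(p1, p2)`.
#' @examples
#' restricted_stationary(0.5, 0.5, "alpha0")  # (0.25, 0.5)
#' @export
restricted_stationary <- function(alpha, gamma,
                                  which = c("alpha0", "alpha1",
                                            "gamma0", "gamma1"),
                                  tol = 1e-12) {
  which <- match.arg(which)
  stopifnot(length(alpha) == 1L, length(gamma) == 1L,
            alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  a <- alpha; g <- gamma
  num <- switch(which,
    alpha0 = c(a * g,             a),
    alpha1 = c(1 - a + a * g,     g),
    gamma0 = c(a - a^2,           a - a^2 + a * g),
    gamma1 = c(2 * a - a^2,       a - a^2 + a * g))
  den <- switch(which,
    alpha0 = 1 + g * (a - g),
    alpha1 = 1 - (1 - g) * (a - g),
    gamma0 = 1 - a * (a - g),
    gamma1 = 1 - (a - 1) * (a - g))
  if (abs(den) < tol)
    stop("degenerate denominator in restricted stationary state (", which,
         ") at alpha = ", a, ", gamma = ", g, call. = FALSE)
  c(p1 = num[1L] / den, p2 = num[2L] / den)
}

#' Restricted pure-strategy payoffs
#'
#' Player 1's stationary expected payoff under each of the four
#' pure-strategy restrictions, obtained by substituting the
#' [restricted_stationary()] pairs into the bilinear payoff.  Vectorized over
#' `alpha` and `gamma`; singular points (vanishing denominators, e.g. the
#' corner `alpha = 0, gamma = 1` for the `alpha = 0` case) yield `NaN`.
#'
#' @param alpha,gamma Probabilities in \[0, 1\] (equal-length vectors).
#' @inheritParams payoff_coefficients
#' @return A list with numeric components `u_alpha0`, `u_alpha1`, `u_gamma0`,
#'   `u_gamma1`.
#' @examples
#' restricted_payoffs(0.5, 0.5)$u_alpha0  # 4.75
#' @export
restricted_payoffs <- function(alpha, gamma, payoffs = payoff_matrix()) {
  a <- alpha; g <- gamma
  b <- payoff_coefficients(payoffs)
  U <- function(p1, p2)
    b[["b11"]] * p1 * p2 + b[["b1"]] * p1 + b[["b2"]] * p2 + b[["b0"]]
  d0 <- 1 + g * (a - g)
  d1 <- 1 - (1 - g) * (a - g)
  d2 <- 1 - a * (a - g)
  d3 <- 1 - (a - 1) * (a - g)
  list(
    u_alpha0 = U(a * g / d0,           a / d0),
    u_alpha1 = U((1 - a + a * g) / d1, g / d1),
    u_gamma0 = U((a - a^2) / d2,       (a - a^2 + a * g) / d2),
    u_gamma1 = U((2 * a - a^2) / d3,   (a - a^2 + a * g) / d3))
}

#' Restricted payoffs, verbatim closed forms
#'
#' The previously published closed-form expressions for the four restricted
#' payoffs, transcribed verbatim.  The `alpha`-pair is algebraically
#' identical to [restricted_payoffs()]; the `gamma`-pair is *not* — its
#' leading terms (`-(alpha^2 + alpha)` and `-alpha^2`) disagree with the
#' substitution of the restricted stationary probabilities into the payoff
#' (which gives `-(alpha - alpha^2)` and `-(2 alpha - alpha^2)`).  The
#' function exists so that this documented inconsistency can be asserted;
#' every solver in the package uses [restricted_payoffs()].
#'
#' @inheritParams restricted_payoffs
#' @return A list like [restricted_payoffs()].
#' @keywords internal
#' @export
restricted_payoffs_printed <- function(alpha, gamma) {
  a <- alpha; g <- gamma
  d0 <- g * (a - g) + 1
  d1 <- -(a - g) * (1 - g) + 1
  d2 <- -a * (a - g) + 1
  d3 <- -(a - 1) * (a - g) + 1
  list(
    u_alpha0 = -4 * a^2 * g / d0^2 - a * g / d0 + 9 * a / d0 + 1,
    u_alpha1 = -4 * g * (-a * (1 - g) + 1) / d1^2 + 9 * g / d1 -
      (-a * (1 - g) + 1) / d1 + 1,
    u_gamma0 = -(a^2 + a) / d2 -
      4 * (-a^2 + a) * (-a * (a - g) + a) / d2^2 +
      9 * (-a * (a - g) + a) / d2 + 1,
    u_gamma1 = -(a * (a - 1) + a) / d3 -
      4 * (-a * (a - 1) + a) * (-a * (a - g) + a) / d3^2 +
      9 * (-a * (a - g) + a) / d3 + 1)
}

#' Logit response to restricted payoffs
#'
#' The logit choice probabilities at rationality `lam`:
#' `alpha_response = exp(lam u_a1) / (exp(lam u_a0) + exp(lam u_a1))` and
#' analogously for `gamma`.  Computed as
#' `1 / (1 + exp(lam (u0 - u1)))` with the exponent clamped to +/- 700, so
#' the result is finite for every finite input (including `lam = 1e6`).
#'
#' @param restricted A list as returned by [restricted_payoffs()].
#' @param lam Non-negative rationality parameter.
#' @return A list with components `alpha_response`, `gamma_response`, each in
#'   \[0, 1\].
#' @export
logit_response <- function(restricted, lam) {
  stopifnot(lam >= 0)
  sat <- function(delta)
    1 / (1 + exp(pmin(pmax(lam * delta, -700), 700)))
  list(alpha_response = sat(restricted$u_alpha0 - restricted$u_alpha1),
       gamma_response = sat(restricted$u_gamma0 - restricted$u_gamma1))
}

#' Fixed-point residual of the symmetric logit system
#'
#' The squared deviation
#' `(alpha_response - alpha)^2 + (gamma_response - gamma)^2`, zero exactly at
#' a symmetric quantal response equilibrium.  Vectorized over `alpha` and
#' `gamma`.  At singular points of the restricted payoffs the residual is
#' reported as 2 (the supremum of the residual on the unit square), keeping
#' grid sweeps and bounded optimizers well-defined.
#'
#' @inheritParams restricted_payoffs
#' @param lam Non-negative rationality parameter.
#' @return Numeric vector of residuals (non-negative).
#' @export
qre_residual <- function(alpha, gamma, lam, payoffs = payoff_matrix()) {
  r <- logit_response(restricted_payoffs(alpha, gamma, payoffs), lam)
  out <- (r$alpha_response - alpha)^2 + (r$gamma_response - gamma)^2
  out[!is.finite(out)] <- 2
  out
}

#' Solver configuration
#'
#' @param lambda_grid Ascending non-negative grid of rationality values for
#'   [trace_qre()].  The default spans 0 to 200 in steps of 0.01; analyses in
#'   this package typically truncate it (`seq(0, 8, by = 0.01)` covers every
#'   landmark).
#' @param restart_grid_size Points per axis of the deterministic restart
#'   lattice on the unit square.
#' @param refine_top Number of best lattice points refined by local
#'   minimization at each solve (the full lattice is always *evaluated*; see
#'   the methods vignette).
#' @param local_tol Convergence tolerance handed to the local minimizer
#'   (`factr`-style absolute reduction).
#' @param residual_tol A solution counts as converged when its residual is
#'   below this value.
#' @param continuation Warm-start each solve in a trace from the previous
#'   solution.
#' @param seed Integer seed, recorded for provenance.  All solvers are
#'   deterministic; the seed matters only for the simulation modules.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(lambda_grid = seq(0, 200, by = 0.01),
                          restart_grid_size = 21L,
                          refine_top = 10L,
                          local_tol = 1e-12,
                          residual_tol = 1e-10,
                          continuation = TRUE,
                          seed = NULL) {
  stopifnot(is.numeric(lambda_grid), length(lambda_grid) >= 1L,
            all(lambda_grid >= 0), !is.unsorted(lambda_grid),
            restart_grid_size >= 2L, refine_top >= 1L,
            local_tol > 0, residual_tol > 0, is.logical(continuation))
  structure(list(lambda_grid = lambda_grid,
                 restart_grid_size = as.integer(restart_grid_size),
                 refine_top = as.integer(refine_top),
                 local_tol = local_tol, residual_tol = residual_tol,
                 continuation = isTRUE(continuation), seed = seed),
            class = "solver_config")
}

# one bounded local minimization of the residual
qre_local_min <- function(start, lam, payoffs, local_tol = 1e-12,
                          maxit = 500L) {
  fn <- function(x) qre_residual(x[1L], x[2L], lam, payoffs)
  # the residual is a smooth rational-logit composite, safe to evaluate
  # slightly outside the box, so a plain central stencil works at the bounds
  gr <- function(x, h = 1e-6) {
    c(fn(c(x[1L] + h, x[2L])) - fn(c(x[1L] - h, x[2L])),
      fn(c(x[1L], x[2L] + h)) - fn(c(x[1L], x[2L] - h))) / (2 * h)
  }
  stats::optim(start, fn, gr = gr, method = "L-BFGS-B",
               lower = c(0, 0), upper = c(1, 1),
               control = list(factr = max(local_tol / 1e-15, 1),
                              maxit = maxit))
}

#' Solve the symmetric QRE at one rationality value
#'
#' Minimizes the fixed-point residual over the unit square by deterministic
#' multistart: the residual is evaluated on a `restart_grid_size`-squared
#' lattice, the best `refine_top` lattice points (plus the warm start, if
#' given) are refined by bounded local minimization, and the best refined
#' minimum is returned.  When several refined minima tie within `1e-8` of the
#' best residual and a warm start exists, the one closest (Euclidean) to the
#' warm start is returned, which makes continuation traces follow a
#' continuous equilibrium branch.
#'
#' @param lam Non-negative rationality parameter.
#' @param config A [solver_config()].
#' @param warm_start Optional numeric `c(alpha, gamma)` used as an extra
#'   start and as the tie-break anchor.
#' @inheritParams payoff_coefficients
#' @return An object of class `qre_solution`: a list with `lam`, `alpha`,
#'   `gamma`, `residual`, `n_minima_found`, `converged`.
#' @examples
#' s <- solve_qre(0)
#' c(s$alpha, s$gamma)  # (0.5, 0.5): at zero rationality choices are uniform
#' @export
solve_qre <- function(lam, config = solver_config(), warm_start = NULL,
                      payoffs = payoff_matrix()) {
  stopifnot(inherits(config, "solver_config"), lam >= 0)
  grid1 <- seq(0, 1, length.out = config$restart_grid_size)
  lattice <- expand.grid(alpha = grid1, gamma = grid1)
  vals <- qre_residual(lattice$alpha, lattice$gamma, lam, payoffs)
  ord <- order(vals)
  k <- min(config$refine_top, nrow(lattice))
  starts <- lapply(ord[seq_len(k)],
                   function(i) c(lattice$alpha[i], lattice$gamma[i]))
  if (!is.null(warm_start)) {
    stopifnot(is.numeric(warm_start), length(warm_start) == 2L)
    starts <- c(list(pmin(pmax(warm_start, 0), 1)), starts)
  }
  fits <- lapply(starts, qre_local_min, lam = lam, payoffs = payoffs,
                 local_tol = config$local_tol)
  pars <- do.call(rbind, lapply(fits, `[[`, "par"))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best_val <- min(vals)
  tied <- which(vals <= best_val + 1e-8)
  pick <- if (!is.null(warm_start) && length(tied) > 1L) {
    d2 <- (pars[tied, 1L] - warm_start[1L])^2 +
      (pars[tied, 2L] - warm_start[2L])^2
    tied[which.min(d2)]
  } else tied[which.min(vals[tied])]
  n_minima <- nrow(merge_close_points(pars, 0.02))
  structure(list(lam = lam, alpha = pars[pick, 1L], gamma = pars[pick, 2L],
                 residual = vals[pick], n_minima_found = n_minima,
                 converged = vals[pick] < config$residual_tol),
            class = "qre_solution")
}

#' @export
print.qre_solution <- function(x, ...) {
  cat(sprintf(
    "QRE solution at lambda = %.4g: alpha = %.6f, gamma = %.6f (residual %.3g%s)\n",
    x$lam, x$alpha, x$gamma, x$residual,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

merge_close_points <- function(pts, radius) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      j <- (i + 1L):nrow(pts)
      d <- sqrt((pts[j, 1L] - pts[i, 1L])^2 + (pts[j, 2L] - pts[i, 2L])^2)
      keep[j[d < radius]] <- FALSE
    }
  }
  pts[keep, , drop = FALSE]
}

#' Trace the QRE over a rationality grid
#'
#' Sweeps the rationality grid of `config` in ascending order, solving the
#' symmetric QRE at each value and recording the solution.
#'
#' Two tracing methods are provided.  `"multistart"` (the default) targets
#' the *global* residual minimum at every grid value, warm-starting from the
#' previous solution when `config$continuation` is on; ties are broken toward
#' the warm start so the trace follows a continuous equilibrium branch.
#' `"single_start"` instead performs one bounded local minimization per grid
#' value, always started from `start` — this emulates a plain single-start
#' solver and is the mode that exhibits the defection collapse: at high
#' rationality the local solve abandons the cooperative equilibrium branch
#' and descends into a non-equilibrium residual minimum in the defection
#' basin (see [find_defection_onset()]).
#'
#' @param config A [solver_config()].
#' @param method `"multistart"` or `"single_start"`.
#' @param start Fixed starting point for `method = "single_start"`.
#' @inheritParams payoff_coefficients
#' @return A data frame of class `qre_trace` with columns `lambda`, `alpha`,
#'   `gamma`, `residual`, `n_minima_found`, `converged`, in ascending
#'   `lambda` order.
#' @export
trace_qre <- function(config = solver_config(),
                      method = c("multistart", "single_start"),
                      start = c(0.5, 0.5), payoffs = payoff_matrix()) {
  method <- match.arg(method)
  stopifnot(inherits(config, "solver_config"))
  lams <- config$lambda_grid
  n <- length(lams)
  out <- data.frame(lambda = lams, alpha = NA_real_, gamma = NA_real_,
                    residual = NA_real_, n_minima_found = NA_integer_,
                    converged = NA)
  warm <- NULL
  for (i in seq_len(n)) {
    if (method == "multistart") {
      s <- solve_qre(lams[i], config, warm_start = warm, payoffs = payoffs)
      if (config$continuation) warm <- c(s$alpha, s$gamma)
      out[i, -1L] <- list(s$alpha, s$gamma, s$residual, s$n_minima_found,
                          s$converged)
    } else {
      fit <- qre_local_min(start, lams[i], payoffs,
                           local_tol = config$local_tol)
      out[i, -1L] <- list(fit$par[1L], fit$par[2L], fit$value, NA_integer_,
                          fit$value < config$residual_tol)
    }
  }
  structure(out, class = c("qre_trace", "data.frame"),
            method = method, config = config)
}

#' Census of local residual minima
#'
#' Counts distinct strict local minima of the fixed-point residual on an
#' interior lattice (8-neighbour strict comparison), refining each candidate
#' by bounded local minimization and merging refined minima closer than
#' `merge_radius`.
#'
#' @param lam Non-negative rationality parameter.
#' @param grid_resolution Lattice points per axis (at least 101).
#' @inheritParams payoff_coefficients
#' @param merge_radius Refined minima closer than this are counted once.
#' @return Integer count of distinct local minima.  The refined locations
#'   are attached as attribute `"minima"` (matrix with columns alpha, gamma).
#' @export
count_local_minima <- function(lam, grid_resolution = 201L,
                               payoffs = payoff_matrix(),
                               merge_radius = 0.02) {
  stopifnot(grid_resolution >= 101L)
  x <- seq(0, 1, length.out = grid_resolution)
  F <- outer(x, x, qre_residual, lam = lam, payoffs = payoffs)
  n <- grid_resolution
  core <- 2L:(n - 1L)
  strict <- matrix(TRUE, n - 2L, n - 2L)
  M <- F[core, core]
  for (di in -1L:1L) for (dj in -1L:1L) {
    if (di == 0L && dj == 0L) next
    strict <- strict & (M < F[core + di, core + dj])
  }
  idx <- which(strict, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- 0L
    attr(out, "minima") <- matrix(numeric(0), 0L, 2L)
    return(out)
  }
  cand <- cbind(x[idx[, 1L] + 1L], x[idx[, 2L] + 1L])
  refined <- t(apply(cand, 1L, function(p)
    qre_local_min(p, lam, payoffs)$par))
  merged <- merge_close_points(refined, merge_radius)
  out <- nrow(merged)
  attr(out, "minima") <- merged
  out
}
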