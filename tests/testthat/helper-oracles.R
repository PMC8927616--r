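# Independent oracles and shared fixtures for the test suite.

# Stationary cooperation probabilities by brute force: the pair state
# (c1, c2) is a 4-state Markov chain whose next choices depend only on the
# opponent's current choice.  Solve pi = pi P and read off the marginals.
chain_stationary <- function(a1, g1, a2, g2) {
  states <- expand.grid(c1 = c(TRUE, FALSE), c2 = c(TRUE, FALSE))
  P <- matrix(0, 4L, 4L)
  for (i in 1:4) {
    p1 <- if (states$c2[i]) g1 else a1   # player 1 responds to c2
    p2 <- if (states$c1[i]) g2 else a2
    for (j in 1:4) {
      pr1 <- if (states$c1[j]) p1 else 1 - p1
      pr2 <- if (states$c2[j]) p2 else 1 - p2
      P[i, j] <- pr1 * pr2
    }
  }
  # stationary distribution: solve (P' - I) pi = 0 with sum constraint
  A <- rbind(t(P) - diag(4L), rep(1, 4L))
  pi <- qr.solve(A, c(rep(0, 4L), 1))
  c(p1 = sum(pi[states$c1]), p2 = sum(pi[states$c2]))
}

# Dense-grid argmin of the QRE residual (brute-force global-minimum oracle).
# A second enumeration pass at step 1e-5 inside the winning cell removes the
# coarse grid's own discretization error (step 1/(resolution-1)), so the
# oracle locates the minimum to ~1e-5 without any local optimizer.
grid_argmin <- function(lam, resolution = 401L) {
  x <- seq(0, 1, length.out = resolution)
  F <- outer(x, x, qrepd::qre_residual, lam = lam)
  w <- which(F == min(F), arr.ind = TRUE)[1L, ]
  h <- 1 / (resolution - 1L)
  xs <- seq(max(x[w[1L]] - h, 0), min(x[w[1L]] + h, 1), by = 1e-5)
  ys <- seq(max(x[w[2L]] - h, 0), min(x[w[2L]] + h, 1), by = 1e-5)
  Ff <- outer(xs, ys, qrepd::qre_residual, lam = lam)
  wf <- which(Ff == min(Ff), arr.ind = TRUE)[1L, ]
  c(alpha = xs[wf[1L]], gamma = ys[wf[2L]], value = min(Ff))
}

# residual of the stationary linear system at a profile
stationary_system_residual <- function(v, p) {
  r1 <- p[1L] - (v[2L] * p[2L] + v[1L] * (1 - p[2L]))
  r2 <- p[2L] - (v[4L] * p[1L] + v[3L] * (1 - p[1L]))
  max(abs(c(r1, r2)))
}

# traces are expensive; compute once per run and share across test files
.trace_cache <- new.env(parent = emptyenv())
cached_trace <- function(lambda_max, step, method = "multistart") {
  key <- paste(method, lambda_max, step, sep = "|")
  if (is.null(.trace_cache[[key]])) {
    cfg <- qrepd::solver_config(lambda_grid = seq(0, lambda_max, by = step))
    .trace_cache[[key]] <- qrepd::trace_qre(cfg, method = method)
  }
  .trace_cache[[key]]
}
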