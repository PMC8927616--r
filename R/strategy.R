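#' Memory-one (Markov) strategy
#'
#' A memory-one strategy for the iterated Prisoner's Dilemma is the pair
#' (alpha, gamma): `alpha` is the *tolerance to defection*, the probability of
#' cooperating after the opponent defected in the previous round; `gamma` is
#' *mutual cooperation*, the probability of cooperating after the opponent
#' cooperated.
#'
#' @param alpha,gamma Probabilities in \[0, 1\].
#' @return An object of class `markov_strategy` (named list `alpha`, `gamma`).
#' @examples
#' markov_strategy(0, 1)  # grim-ish: cooperate only after cooperation
#' @export
markov_strategy <- function(alpha, gamma) {
  if (!is.numeric(alpha) || !is.numeric(gamma) || length(alpha) != 1L ||
      length(gamma) != 1L || !is.finite(alpha) || !is.finite(gamma) ||
      alpha < 0 || alpha > 1 || gamma < 0 || gamma > 1)
    stop("alpha and gamma must be single probabilities in [0, 1]",
         call. = FALSE)
  structure(list(alpha = as.numeric(alpha), gamma = as.numeric(gamma)),
            class = "markov_strategy")
}

#' @export
print.markov_strategy <- function(x, ...) {
  cat(sprintf("Markov strategy: alpha = %.4g (after D), gamma = %.4g (after C)\n",
              x$alpha, x$gamma))
  invisible(x)
}

#' Strategy profile of two players
#'
#' @param player1,player2 [markov_strategy()] objects.
#' @return An object of class `strategy_profile`.
#' @export
strategy_profile <- function(player1, player2) {
  stopifnot(inherits(player1, "markov_strategy"),
            inherits(player2, "markov_strategy"))
  structure(list(player1 = player1, player2 = player2),
            class = "strategy_profile")
}

#' One-round memory-one response
#'
#' Draws the focal player's choice given the opponent's previous-round choice:
#' cooperate with probability `gamma` if the opponent cooperated, `alpha`
#' otherwise.  Uses the current R random stream.
#'
#' @param prev_opponent_cooperated Logical scalar.
#' @param strategy A [markov_strategy()].
#' @param n Number of independent draws.
#' @return Character vector of `"C"` / `"D"` of length `n`.
#' @export
markov_response <- function(prev_opponent_cooperated, strategy, n = 1L) {
  stopifnot(is.logical(prev_opponent_cooperated),
            length(prev_opponent_cooperated) == 1L,
            inherits(strategy, "markov_strategy"))
  p <- if (prev_opponent_cooperated) strategy$gamma else strategy$alpha
  ifelse(stats::runif(n) < p, "C", "D")
}

#' Stationary cooperation probabilities of a strategy profile
#'
#' Solves the stationary state of the coupled response dynamics
#' `p1 = gamma1 p2 + alpha1 (1 - p2)`, `p2 = gamma2 p1 + alpha2 (1 - p1)`,
#' in closed form:
#' `p1 = (alpha1 - alpha2 (alpha1 - gamma1)) / (1 - (alpha1 - gamma1)(alpha2 - gamma2))`
#' and symmetrically for `p2`.  The profile is degenerate when the denominator
#' vanishes, i.e. `(alpha1 - gamma1)(alpha2 - gamma2) = 1` (for instance
#' tit-for-tat-reversed pairs), in which case no unique stationary state
#' exists and an error is raised.
#'
#' @param profile A [strategy_profile()], or a numeric vector
#'   `c(alpha1, gamma1, alpha2, gamma2)`.
#' @param tol Degeneracy tolerance on `|d1 * d2 - 1|`.
#' @return Named numeric vector `c(p1, p2)` of stationary cooperation
#'   probabilities.
#' @examples
#' pr <- strategy_profile(markov_strategy(0.3, 0.7), markov_strategy(0.3, 0.7))
#' stationary_probabilities(pr)  # (0.5, 0.5)
#' @export
stationary_probabilities <- function(profile, tol = 1e-12) {
  v <- profile_as_vector(profile)
  a1 <- v[1L]; g1 <- v[2L]; a2 <- v[3L]; g2 <- v[4L]
  d1 <- a1 - g1; d2 <- a2 - g2
  den <- 1 - d1 * d2
  if (abs(den) < tol)
    stop("degenerate strategy profile: (alpha1 - gamma1)(alpha2 - gamma2) = 1, ",
         "no unique stationary state", call. = FALSE)
  c(p1 = (a1 - a2 * d1) / den, p2 = (a2 - a1 * d2) / den)
}

#' Stationary expected payoff of a strategy profile
#'
#' Player 1's expected stage payoff at the stationary cooperation
#' probabilities of the profile.
#'
#' @inheritParams stationary_probabilities
#' @inheritParams payoff_coefficients
#' @return Numeric scalar payoff.
#' @export
profile_payoff <- function(profile, payoffs = payoff_matrix(), tol = 1e-12) {
  p <- stationary_probabilities(profile, tol = tol)
  expected_payoff(p[["p1"]], p[["p2"]], payoffs)
}

profile_as_vector <- function(profile) {
  if (inherits(profile, "strategy_profile"))
    return(c(profile$player1$alpha, profile$player1$gamma,
             profile$player2$alpha, profile$player2$gamma))
  if (is.numeric(profile) && length(profile) == 4L)
    return(as.numeric(profile))
  stop("profile must be a strategy_profile or numeric vector of length 4",
       call. = FALSE)
}
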