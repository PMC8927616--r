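#' Simulate one pair playing the iterated game
#'
#' Round 1 choices are independent Bernoulli draws with probability
#' `initial_coop_prob`; from round 2 on each player responds to the
#' opponent's previous-round choice with its memory-one strategy.
#'
#' @param s1,s2 [markov_strategy()] objects for the two players.
#' @param rounds Number of rounds (at least 1).
#' @param initial_coop_prob First-round cooperation probability.
#' @param experiment_id,phase,group_id,pair_id,player_ids Identifiers written
#'   into the log.
#' @param seed Optional integer seed (set before any draw).
#' @return A play-log data frame (see [validate_play_log()]) with
#'   `2 * rounds` rows.
#' @examples
#' log <- simulate_pair(markov_strategy(0, 1), markov_strategy(0, 1),
#'                      rounds = 5, initial_coop_prob = 1, seed = 1)
#' all(log$choice == "C")  # mutual cooperation is absorbing for (0, 1)
#' @export
simulate_pair <- function(s1, s2, rounds, initial_coop_prob = 0.5,
                          experiment_id = "E1", phase = "before",
                          group_id = "all", pair_id = "P1",
                          player_ids = c("p1", "p2"), seed = NULL) {
  stopifnot(inherits(s1, "markov_strategy"), inherits(s2, "markov_strategy"),
            rounds >= 1, initial_coop_prob >= 0, initial_coop_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  rounds <- as.integer(rounds)
  alpha <- c(s1$alpha, s2$alpha)
  gamma <- c(s1$gamma, s2$gamma)
  coop <- matrix(NA, rounds, 2L)
  coop[1L, ] <- stats::runif(2L) < initial_coop_prob
  if (rounds > 1L) for (t in 2L:rounds) {
    prev_opp <- coop[t - 1L, 2L:1L]
    p <- ifelse(prev_opp, gamma, alpha)
    coop[t, ] <- stats::runif(2L) < p
  }
  data.frame(
    experiment_id = experiment_id, phase = phase, group_id = group_id,
    round = rep(seq_len(rounds), each = 2L),
    pair_id = pair_id,
    player_id = rep(player_ids, rounds),
    choice = ifelse(t(coop)[cbind(rep(1:2, rounds),
                                  rep(seq_len(rounds), each = 2L))],
                    "C", "D"),
    stringsAsFactors = FALSE)
}

#' Synthetic experiment design
#'
#' Describes one two-phase experiment: `n_players` strangers play the
#' iterated game together before socialization, then split into
#' `n_groups_after` equal groups that play again.  Each player's memory-one
#' strategy is drawn per phase from a uniform box over (alpha, gamma); the
#' default boxes (`[0, 0.3] x [0, 0.4]` before, `[0.2, 0.7] x [0.5, 1]`
#' after) are synthetic stand-ins calibrated so that pooled cooperation
#' rates bracket the empirically reported 22% / 58% — see the methods
#' vignette.
#'
#' @param n_players Even number of participants (default 12).
#' @param rounds_before,rounds_after Inclusive integer ranges from which the
#'   per-experiment round counts are drawn (defaults 11–22 and 15–20).
#' @param n_groups_after Number of equal groups after socialization.
#' @param strategy_before,strategy_after Lists with `alpha_range` and
#'   `gamma_range` (each `c(lo, hi)` within \[0, 1\]).
#' @param pairing `"rematch_each_round"` (random perfect matching within the
#'   group every round) or `"fixed"` (one matching kept for the phase).
#' @param initial_coop_prob First-round cooperation probability.
#' @param seed Optional integer seed used by [generate_experiment()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_players = 12L,
                              rounds_before = c(11L, 22L),
                              rounds_after = c(15L, 20L),
                              n_groups_after = 2L,
                              strategy_before = list(
                                alpha_range = c(0, 0.3),
                                gamma_range = c(0, 0.4)),
                              strategy_after = list(
                                alpha_range = c(0.2, 0.7),
                                gamma_range = c(0.5, 1.0)),
                              pairing = c("rematch_each_round", "fixed"),
                              initial_coop_prob = 0.5,
                              seed = NULL) {
  pairing <- match.arg(pairing)
  n_players <- as.integer(n_players)
  n_groups_after <- as.integer(n_groups_after)
  if (n_players < 2L || n_players %% 2L != 0L)
    stop("n_players must be even and at least 2", call. = FALSE)
  if (n_players %% n_groups_after != 0L ||
      (n_players / n_groups_after) %% 2L != 0L)
    stop("players must split into equal even-sized groups", call. = FALSE)
  chk_range <- function(r) is.numeric(r) && length(r) == 2L && r[1] <= r[2]
  stopifnot(chk_range(rounds_before), chk_range(rounds_after),
            chk_range(strategy_before$alpha_range),
            chk_range(strategy_before$gamma_range),
            chk_range(strategy_after$alpha_range),
            chk_range(strategy_after$gamma_range),
            initial_coop_prob >= 0, initial_coop_prob <= 1)
  structure(list(n_players = n_players, rounds_before = rounds_before,
                 rounds_after = rounds_after,
                 n_groups_after = n_groups_after,
                 strategy_before = strategy_before,
                 strategy_after = strategy_after, pairing = pairing,
                 initial_coop_prob = initial_coop_prob, seed = seed),
            class = "experiment_design")
}

# simulate one group for one phase; strategies is an n x 2 matrix (alpha,
# gamma) indexed like players
simulate_group_phase <- function(players, strategies, rounds, pairing,
                                 initial_coop_prob, experiment_id, phase,
                                 group_id) {
  n <- length(players)
  match_once <- function() matrix(sample(n), ncol = 2L, byrow = TRUE)
  matchings <- if (pairing == "fixed") {
    m <- match_once(); replicate(rounds, m, simplify = FALSE)
  } else replicate(rounds, match_once(), simplify = FALSE)
  coop <- matrix(NA, rounds, n)
  coop[1L, ] <- stats::runif(n) < initial_coop_prob
  opp_of <- function(m) {
    o <- integer(n); o[m[, 1L]] <- m[, 2L]; o[m[, 2L]] <- m[, 1L]; o
  }
  if (rounds > 1L) for (t in 2L:rounds) {
    opp <- opp_of(matchings[[t]])
    prev_opp <- coop[t - 1L, opp]
    p <- ifelse(prev_opp, strategies[, 2L], strategies[, 1L])
    coop[t, ] <- stats::runif(n) < p
  }
  rows <- lapply(seq_len(rounds), function(t) {
    m <- matchings[[t]]
    idx <- as.vector(t(m))                      # pair1 p, pair1 q, pair2 p, ...
    data.frame(
      experiment_id = experiment_id, phase = phase, group_id = group_id,
      round = t,
      pair_id = rep(sprintf("%s_R%02d_%d", group_id, t,
                            seq_len(nrow(m))), each = 2L),
      player_id = players[idx],
      choice = ifelse(coop[t, idx], "C", "D"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate one synthetic two-phase experiment
#'
#' Draws per-player strategies from the design's phase boxes, simulates the
#' pre-socialization phase with all players in one group, splits the players
#' at random into the post-socialization groups, and simulates those.  The
#' result is fully reproducible from `design$seed`.
#'
#' @param design An [experiment_design()].
#' @param experiment_id Identifier written into the log.
#' @return A play-log data frame covering both phases, with per-player true
#'   strategies attached as attribute `"true_strategies"` (data frame with
#'   columns `phase`, `player_id`, `alpha`, `gamma`).
#' @export
generate_experiment <- function(design = experiment_design(),
                                experiment_id = "E1") {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_players
  players <- sprintf("p%02d", seq_len(n))
  draw_strats <- function(box)
    cbind(alpha = stats::runif(n, box$alpha_range[1], box$alpha_range[2]),
          gamma = stats::runif(n, box$gamma_range[1], box$gamma_range[2]))
  s_before <- draw_strats(design$strategy_before)
  s_after <- draw_strats(design$strategy_after)
  r_before <- sample(design$rounds_before[1]:design$rounds_before[2], 1L)
  r_after <- sample(design$rounds_after[1]:design$rounds_after[2], 1L)
  before <- simulate_group_phase(players, s_before, r_before,
                                 design$pairing, design$initial_coop_prob,
                                 experiment_id, "before", "all")
  split_idx <- sample(n)
  gsize <- n / design$n_groups_after
  after <- do.call(rbind, lapply(seq_len(design$n_groups_after), function(g) {
    members <- sort(split_idx[((g - 1L) * gsize + 1L):(g * gsize)])
    simulate_group_phase(players[members],
                         s_after[members, , drop = FALSE], r_after,
                         design$pairing, design$initial_coop_prob,
                         experiment_id, "after", sprintf("G%d", g))
  }))
  out <- rbind(before, after)
  rownames(out) <- NULL
  attr(out, "true_strategies") <- rbind(
    data.frame(phase = "before", player_id = players,
               alpha = s_before[, 1L], gamma = s_before[, 2L]),
    data.frame(phase = "after", player_id = players,
               alpha = s_after[, 1L], gamma = s_after[, 2L]))
  out
}
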