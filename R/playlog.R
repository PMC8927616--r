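#' Validate a round-by-round play log
#'
#' A play log is a data frame with columns `experiment_id`, `phase`
#' (`"before"` or `"after"` socialization), `group_id`, `round`, `pair_id`,
#' `player_id`, `choice` (`"C"` or `"D"`).  Within every
#' (experiment, phase, round, pair) there must be exactly two records from
#' two distinct players, and rounds within an (experiment, phase) must be
#' consecutive starting at 1.
#'
#' @param records A play-log data frame.
#' @return Invisibly `TRUE`; stops with a descriptive error on a malformed
#'   log.
#' @export
validate_play_log <- function(records) {
  need <- c("experiment_id", "phase", "group_id", "round", "pair_id",
            "player_id", "choice")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("play log must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("play log is empty", call. = FALSE)
  if (!all(records$choice %in% c("C", "D")))
    stop("choice values must be exactly \"C\" or \"D\"", call. = FALSE)
  if (!all(records$phase %in% c("before", "after")))
    stop("phase values must be \"before\" or \"after\"", call. = FALSE)
  key <- interaction(records$experiment_id, records$phase, records$round,
                     records$pair_id, drop = TRUE)
  sizes <- table(key)
  if (any(sizes != 2L))
    stop("malformed log: every (experiment, phase, round, pair) needs ",
         "exactly 2 records", call. = FALSE)
  two_players <- vapply(split(records$player_id, key),
                        function(p) length(unique(p)) == 2L, logical(1))
  if (!all(two_players))
    stop("malformed log: a pair must consist of two distinct players",
         call. = FALSE)
  ep <- split(records$round, interaction(records$experiment_id,
                                         records$phase, drop = TRUE))
  ok <- vapply(ep, function(r) {
    u <- sort(unique(r)); identical(u, seq_along(u))
  }, logical(1))
  if (!all(ok))
    stop("malformed log: rounds within an (experiment, phase) must be ",
         "consecutive from 1", call. = FALSE)
  invisible(TRUE)
}

# focal/opponent view: one row per record with the opponent's choice this
# round and (where the same pairing persisted) the opponent's previous choice
focal_opponent_table <- function(records) {
  r <- records[, c("experiment_id", "phase", "group_id", "round", "pair_id",
                   "player_id", "choice")]
  opp <- merge(r, r[, c("experiment_id", "phase", "round", "pair_id",
                        "player_id", "choice")],
               by = c("experiment_id", "phase", "round", "pair_id"),
               suffixes = c("", "_opp"))
  opp <- opp[opp$player_id != opp$player_id_opp, ]
  prev <- opp[, c("experiment_id", "phase", "round", "player_id",
                  "player_id_opp", "choice_opp")]
  prev$round <- prev$round + 1L
  names(prev)[names(prev) == "choice_opp"] <- "prev_opp_choice"
  out <- merge(opp, prev,
               by = c("experiment_id", "phase", "round", "player_id",
                      "player_id_opp"),
               all.x = TRUE)
  out[order(out$experiment_id, out$phase, out$round, out$player_id), ]
}

#' Transition counts per player
#'
#' Counts, for every player, the memory-one transitions observable in a play
#' log: how often the player faced a cooperating (resp. defecting) opponent
#' in the previous round of a persisting pairing, and how often the player
#' responded with cooperation.  First rounds of a pairing, and rounds after a
#' re-match, carry no transition.
#'
#' @inheritParams validate_play_log
#' @return A data frame with one row per (experiment, phase, group, player)
#'   and count columns `n_opp_coop`, `n_coop_after_coop`, `n_opp_defect`,
#'   `n_coop_after_defect`.
#' @export
transition_counts <- function(records) {
  validate_play_log(records)
  fo <- focal_opponent_table(records)
  fo <- fo[!is.na(fo$prev_opp_choice), ]
  key <- c("experiment_id", "phase", "group_id", "player_id")
  base <- unique(records[, key])
  if (nrow(fo) == 0L) {
    counts <- cbind(base, n_opp_coop = 0L, n_coop_after_coop = 0L,
                    n_opp_defect = 0L, n_coop_after_defect = 0L)
    rownames(counts) <- NULL
    return(counts)
  }
  agg <- aggregate(
    cbind(n_opp_coop = fo$prev_opp_choice == "C",
          n_coop_after_coop = fo$prev_opp_choice == "C" & fo$choice == "C",
          n_opp_defect = fo$prev_opp_choice == "D",
          n_coop_after_defect = fo$prev_opp_choice == "D" & fo$choice == "C"),
    by = fo[, key], FUN = sum)
  out <- merge(base, agg, by = key, all.x = TRUE)
  for (cl in c("n_opp_coop", "n_coop_after_coop", "n_opp_defect",
               "n_coop_after_defect"))
    out[[cl]][is.na(out[[cl]])] <- 0L
  out[order(out$experiment_id, out$phase, out$group_id, out$player_id), ]
}

#' Estimate a Markov strategy from a play log
#'
#' The transition-count estimator: `gamma_hat` is the fraction of
#' cooperative responses among rounds whose (persisting) opponent cooperated
#' in the previous round, `alpha_hat` the analogue after opponent defection.
#' All records passed in are pooled, so the function serves both for a
#' single player's records and for a pooled group (pooled counts, not means
#' of per-player ratios).  A zero denominator yields a missing (`NA`)
#' estimate.
#'
#' @inheritParams validate_play_log
#' @return An object of class `strategy_estimate`: a list with `alpha_hat`,
#'   `gamma_hat` (possibly `NA`) and the four transition counts.
#' @export
estimate_strategy <- function(records) {
  counts <- transition_counts(records)
  n_oc <- sum(counts$n_opp_coop)
  n_cc <- sum(counts$n_coop_after_coop)
  n_od <- sum(counts$n_opp_defect)
  n_cd <- sum(counts$n_coop_after_defect)
  structure(list(
    alpha_hat = if (n_od > 0L) n_cd / n_od else NA_real_,
    gamma_hat = if (n_oc > 0L) n_cc / n_oc else NA_real_,
    n_opp_coop = n_oc, n_coop_after_coop = n_cc,
    n_opp_defect = n_od, n_coop_after_defect = n_cd),
    class = "strategy_estimate")
}

#' @export
print.strategy_estimate <- function(x, ...) {
  cat(sprintf(
    "Markov strategy estimate: alpha_hat = %s (%d/%d), gamma_hat = %s (%d/%d)\n",
    format(x$alpha_hat, digits = 4), x$n_coop_after_defect, x$n_opp_defect,
    format(x$gamma_hat, digits = 4), x$n_coop_after_coop, x$n_opp_coop))
  invisible(x)
}

#' Pooled group-level strategy estimate
#'
#' Pools transition counts across all players present in `records` and forms
#' the count ratios — the maximum-likelihood estimate under a shared
#' memory-one strategy.  For a single player's records this equals
#' [estimate_strategy()].
#'
#' @inheritParams validate_play_log
#' @return A `strategy_estimate`.
#' @export
aggregate_group <- function(records) {
  estimate_strategy(records)
}

#' Overall cooperation rate of a play log
#'
#' The fraction of all recorded choices (every round, including first
#' rounds) that are cooperative.
#'
#' @inheritParams validate_play_log
#' @return Numeric scalar in \[0, 1\].
#' @export
cooperation_rate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty play log", call. = FALSE)
  if (!"choice" %in% names(records) ||
      !all(records$choice %in% c("C", "D")))
    stop("play log must have a choice column of \"C\"/\"D\"", call. = FALSE)
  mean(records$choice == "C")
}

#' Per-group summary of estimates, rates and classifications
#'
#' Splits a play log by (experiment, phase, group), computes the pooled
#' strategy estimate and cooperation rate of each cell, and — when a
#' phase-boundary `segment` is supplied — classifies each cell's estimated
#' strategy with [classify_point()].  Cells with a missing estimate are left
#' unclassified and counted in the `n_missing` attribute.
#'
#' @inheritParams validate_play_log
#' @param segment Optional polyline for classification (see
#'   [qre_segment()]).
#' @param near_tol Near-band half-width for [classify_point()].
#' @return A data frame with one row per (experiment, phase, group).
#' @export
summarize_groups <- function(records, segment = NULL, near_tol = 0.05) {
  validate_play_log(records)
  cells <- split(records, interaction(records$experiment_id, records$phase,
                                      records$group_id, drop = TRUE))
  rows <- lapply(cells, function(cell) {
    est <- estimate_strategy(cell)
    out <- data.frame(
      experiment_id = cell$experiment_id[1L], phase = cell$phase[1L],
      group_id = cell$group_id[1L],
      alpha_hat = est$alpha_hat, gamma_hat = est$gamma_hat,
      n_opp_coop = est$n_opp_coop,
      n_coop_after_coop = est$n_coop_after_coop,
      n_opp_defect = est$n_opp_defect,
      n_coop_after_defect = est$n_coop_after_defect,
      cooperation_rate = cooperation_rate(cell),
      label = NA_character_, boundary_distance = NA_real_)
    if (!is.null(segment) && !is.na(est$alpha_hat) && !is.na(est$gamma_hat)) {
      cl <- classify_point(est$alpha_hat, est$gamma_hat, segment, near_tol)
      out$label <- cl$label
      out$boundary_distance <- cl$distance
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$experiment_id, out$phase, out$group_id), ]
  rownames(out) <- NULL
  n_missing <- sum(is.na(out$alpha_hat) | is.na(out$gamma_hat))
  if (n_missing > 0L)
    warning(n_missing, " group(s) with a missing strategy estimate were ",
            "not classified", call. = FALSE)
  attr(out, "n_missing") <- n_missing
  out
}

#' Read / write play logs as CSV
#'
#' The CSV carries exactly the columns
#' `experiment_id, phase, group_id, round, pair_id, player_id, choice`
#' with a mandatory header.
#'
#' @param path File path.
#' @return `read_play_log()` returns a validated play-log data frame.
#' @export
read_play_log <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(
                               experiment_id = "character",
                               phase = "character",
                               group_id = "character",
                               round = "integer",
                               pair_id = "character",
                               player_id = "character",
                               choice = "character"))
  validate_play_log(records)
  records
}

#' @param records A play-log data frame.
#' @rdname read_play_log
#' @export
write_play_log <- function(records, path) {
  validate_play_log(records)
  cols <- c("experiment_id", "phase", "group_id", "round", "pair_id",
            "player_id", "choice")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
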