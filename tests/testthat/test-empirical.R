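# build a fixed-pair two-player log from explicit choice sequences
two_player_log <- function(focal, opp, phase = "before") {
  rounds <- length(focal)
  data.frame(
    experiment_id = "E1", phase = phase, group_id = "all",
    round = rep(seq_len(rounds), each = 2L), pair_id = "P1",
    player_id = rep(c("f", "o"), rounds),
    choice = as.vector(rbind(focal, opp)), stringsAsFactors = FALSE)
}

test_that("transition counts reproduce a hand-counted log", {
  log <- two_player_log(c("C", "D", "C", "C", "D", "C"),
                        c("C", "C", "D", "C", "D", "D"))
  counts <- transition_counts(log)
  f <- counts[counts$player_id == "f", ]
  # focal faced opponent-C before rounds 2, 3, 5 and responded C once (round 3);
  # faced opponent-D before rounds 4, 6 and cooperated both times
  expect_identical(c(f$n_opp_coop, f$n_coop_after_coop,
                     f$n_opp_defect, f$n_coop_after_defect),
                   c(3L, 1L, 2L, 2L))
  # opponent faced focal-C before rounds 2, 4, 5 (responded C, C, D) and
  # focal-D before rounds 3, 6 (responded D, D)
  o <- counts[counts$player_id == "o", ]
  expect_identical(c(o$n_opp_coop, o$n_coop_after_coop,
                     o$n_opp_defect, o$n_coop_after_defect),
                   c(3L, 2L, 2L, 0L))
  pooled <- estimate_strategy(log)
  expect_equal(pooled$gamma_hat, 3 / 6)
  expect_equal(pooled$alpha_hat, 2 / 4)
})

test_that("degenerate denominators yield missing estimates, not zeroes", {
  log <- two_player_log(rep("C", 10), rep("C", 10))
  est <- estimate_strategy(log)
  expect_identical(est$n_opp_defect, 0L)
  expect_true(is.na(est$alpha_hat))
  expect_equal(est$gamma_hat, 1)
  # an always-cooperating focal against a mixed opponent: both ratios are 1
  log2 <- two_player_log(rep("C", 10),
                         c("C", "D", "C", "D", "D", "C", "C", "D", "C", "C"))
  f <- transition_counts(log2)
  f <- f[f$player_id == "f", ]
  expect_equal(f$n_coop_after_coop / f$n_opp_coop, 1)
  expect_equal(f$n_coop_after_defect / f$n_opp_defect, 1)
})

test_that("group aggregation pools counts rather than averaging ratios", {
  # two pairs in one group: focal players with 1/2 and 3/4 after-C records
  a <- two_player_log(c("C", "C", "D"), c("C", "C", "C"))       # f: 1 of 2
  b <- two_player_log(c("C", "C", "C", "C", "D"),
                      c("C", "C", "C", "C", "C"))               # f: 3 of 4
  b$pair_id <- "P2"
  b$player_id <- sub("^f$", "f2", sub("^o$", "o2", b$player_id))
  log <- rbind(a, b)
  counts <- transition_counts(log)
  focal <- counts[counts$player_id %in% c("f", "f2"), ]
  pooled_gamma <- sum(focal$n_coop_after_coop) / sum(focal$n_opp_coop)
  mean_of_ratios <- mean(focal$n_coop_after_coop / focal$n_opp_coop)
  expect_equal(pooled_gamma, 4 / 6)
  expect_equal(mean_of_ratios, 0.625)
  # pooled estimate over everything equals the ratio of summed counts
  est <- aggregate_group(log)
  expect_equal(est$gamma_hat,
               sum(counts$n_coop_after_coop) / sum(counts$n_opp_coop))
  # count conservation: per-player counts sum to the pooled counts
  expect_identical(sum(counts$n_opp_coop), est$n_opp_coop)
  expect_identical(sum(counts$n_coop_after_defect), est$n_coop_after_defect)
  # single-pair records give the same answer through either entry point
  expect_equal(aggregate_group(a), estimate_strategy(a))
})

test_that("re-matched rounds contribute no transitions", {
  # two pairs of players swap partners between rounds 2 and 3
  log <- data.frame(
    experiment_id = "E1", phase = "before", group_id = "all",
    round = rep(1:3, each = 4L),
    pair_id = c("A", "A", "B", "B",  "A", "A", "B", "B",  "A", "A", "B", "B"),
    player_id = c("p1", "p2", "p3", "p4",  "p1", "p2", "p3", "p4",
                  "p1", "p3", "p2", "p4"),
    choice = "C", stringsAsFactors = FALSE)
  counts <- transition_counts(log)
  # rounds 1->2 persist (4 transitions); rounds 2->3 re-match (none)
  expect_identical(sum(counts$n_opp_coop + counts$n_opp_defect), 4L)
})

test_that("cooperation rate counts every record and ignores labels", {
  log <- two_player_log(c("C", "D", "C"), c("D", "D", "D"))
  expect_equal(cooperation_rate(log), 2 / 6)
  relabeled <- log
  relabeled$pair_id <- "X9"
  relabeled$player_id <- rep(c("z1", "z2"), 3)
  expect_identical(cooperation_rate(relabeled), cooperation_rate(log))
  expect_error(cooperation_rate(log[0, ]), "empty")
})

test_that("malformed logs are rejected with informative errors", {
  log <- two_player_log(c("C", "D"), c("C", "C"))
  expect_error(validate_play_log(log[-1, ]), "exactly 2 records")
  gap <- log; gap$round <- c(1L, 1L, 3L, 3L)
  expect_error(validate_play_log(gap), "consecutive")
  bad <- log; bad$choice[1] <- "X"
  expect_error(validate_play_log(bad), "C.*D")
  selfpair <- log; selfpair$player_id <- "f"
  expect_error(validate_play_log(selfpair), "distinct")
})

test_that("pooled estimates recover a known symmetric strategy", {
  set.seed(2024)
  truth <- markov_strategy(0.3, 0.7)
  logs <- lapply(seq_len(100), function(k)
    simulate_pair(truth, truth, rounds = 500L,
                  pair_id = sprintf("P%03d", k),
                  player_ids = sprintf("p%03d_%d", k, 1:2)))
  log <- do.call(rbind, logs)
  est <- estimate_strategy(log)
  expect_lt(abs(est$alpha_hat - 0.3), 0.02)
  expect_lt(abs(est$gamma_hat - 0.7), 0.02)
})

test_that("play logs survive a CSV round trip", {
  log <- simulate_pair(markov_strategy(0.2, 0.9), markov_strategy(0.5, 0.5),
                       rounds = 7L, seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_play_log(log, path)
  back <- read_play_log(path)
  expect_equal(back, log)
})

test_that("group summaries report estimates, rates and classifications", {
  design <- experiment_design(seed = 77)
  log <- generate_experiment(design)
  seg <- data.frame(alpha = c(0.5, 0.2), gamma = c(0.5, 0.47))
  s <- summarize_groups(log, segment = seg)
  expect_identical(nrow(s), 3L)  # one before-cell, two after-groups
  expect_true(all(s$label %in% c("above", "below", "near", NA)))
  expect_true(all(s$cooperation_rate >= 0 & s$cooperation_rate <= 1))
  direct <- estimate_strategy(log[log$phase == "before", ])
  expect_equal(s$gamma_hat[s$phase == "before"], direct$gamma_hat)
})
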