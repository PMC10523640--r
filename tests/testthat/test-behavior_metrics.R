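test_that("instantaneous fractions match a brute-force windowed count", {
  set.seed(1)
  odors <- sample(c("A", "B"), 20, replace = TRUE)
  rew <- stats::rbinom(20, 1, 0.5)
  log <- make_choice_log(odors, rew)
  fr <- instantaneous_fractions(log, window = 10)
  expect_true(all(is.na(fr$choice_frac[1:9])))
  for (t in 10:20) {
    win <- (t - 9):t
    expect_equal(fr$choice_frac[t], mean(odors[win] == "A"))
    nr <- sum(rew[win])
    if (nr == 0) {
      expect_true(is.na(fr$reward_frac[t]))
    } else {
      expect_equal(fr$reward_frac[t],
                   sum(rew[win] & odors[win] == "A") / nr)
    }
  }
})

test_that("degenerate fraction series behave as documented", {
  log_all_a <- make_choice_log(rep("A", 15), rep(1, 15))
  fr <- instantaneous_fractions(log_all_a)
  expect_true(all(fr$choice_frac[10:15] == 1))
  expect_true(all(fr$reward_frac[10:15] == 1))
  log_alt <- make_choice_log(rep(c("A", "B"), 10), rep(0, 20))
  fr2 <- instantaneous_fractions(log_alt)
  expect_true(all(fr2$choice_frac[10:20] == 0.5))
  expect_true(all(is.na(fr2$reward_frac[10:20])))
  expect_error(instantaneous_fractions(make_choice_log("A", 1)[0, ]), "empty")
})

test_that("block matching recovers identity and flat relationships", {
  # choice fraction == reward fraction in every block -> slope 1, intercept 0
  set.seed(2)
  logs <- lapply(1:6, function(i) {
    fr <- stats::runif(1, 0.2, 0.8)
    n <- 40
    odors <- rep(c("A", "B"), round(c(fr, 1 - fr) * n))
    make_choice_log(odors, rep(1, n), fly_id = i)   # every choice rewarded
  })
  bm <- block_matching(logs)
  expect_equal(bm$slope, 1, tolerance = 1e-10)
  expect_equal(bm$intercept, 0, tolerance = 1e-10)
  # choice fraction pinned at 0.5 regardless of reward fraction -> slope 0
  logs_flat <- lapply(1:6, function(i) {
    odors <- rep(c("A", "B"), 20)
    rew <- c(rep(1, 15), rep(0, 25))[sample.int(40)]
    make_choice_log(odors, rew, fly_id = i)
  })
  expect_lt(abs(block_matching(logs_flat)$slope), 0.35)
  expect_error(block_matching(list(make_choice_log(rep("A", 5), rep(0, 5)))),
               "reward")
})

test_that("undermatching MSE has the documented algebra", {
  set.seed(3)
  log <- make_choice_log(sample(c("A", "B"), 40, TRUE), stats::rbinom(40, 1, 0.7))
  fr <- instantaneous_fractions(log, 10)
  ok <- stats::complete.cases(fr)
  expect_equal(undermatching_mse(log),
               mean((fr$choice_frac[ok] - fr$reward_frac[ok])^2))
  # identical series -> 0: every A choice rewarded, no B rewards, all-A window
  log_id <- make_choice_log(rep("A", 20), rep(1, 20))
  expect_equal(undermatching_mse(log_id), 0)
  # relabeling odors leaves the MSE unchanged
  expect_equal(undermatching_mse(relabel_log(log)), undermatching_mse(log))
})

test_that("transition dynamics align, orient, and average curves", {
  cfg <- three_block_config(40L)
  # step-function agent: deterministic preference flip exactly at each block
  step_odors <- c(rep("A", 40), rep("B", 40), rep("A", 40))
  log <- make_choice_log(step_odors, rep(1, 120),
                         block_index = rep(1:3, each = 40))
  td <- transition_dynamics(log, cfg, lags = -5:15, window = 1)
  expect_equal(nrow(td), 21L)
  expect_equal(td$n[td$lag == 0], c(2L))
  # both transitions flip toward the newly richer odor: oriented curve steps 0 -> 1
  expect_true(all(td$mean[td$lag < 0] == 0))
  expect_true(all(td$mean[td$lag >= 0] == 1))
  # below-threshold transitions are dropped with a warning
  cfg_small <- task_config(data.frame(n_trials = 40L, p_A = c(0.5, 0.6),
                                      p_B = c(0.5, 0.4)))
  expect_warning(td0 <- transition_dynamics(log, cfg_small, min_prob_change = 0.4),
                 "min_prob_change")
  expect_equal(nrow(td0), 0L)
})

test_that("covariance-rule agents adapt over tens of trials, not one", {
  logs <- simulate_matching_population("both", n_flies = 15L, seed = 21)
  cfgs <- lapply(1:15, function(i) { set.seed(21 + i - 1); random_block_schedule() })
  # some schedules have no transition with |delta p_A| >= 0.4; those
  # contribute empty curves (with a warning) and are dropped
  curves <- do.call(rbind, lapply(seq_along(logs), function(i)
    suppressWarnings(transition_dynamics(logs[[i]], cfgs[[i]], lags = -10:30))))
  agg <- tapply(curves$mean, curves$lag, mean, na.rm = TRUE)
  lag <- as.integer(names(agg))
  before <- mean(agg[lag < 0])
  late <- mean(agg[lag >= 20])
  just_after <- agg[lag == 1]
  expect_gt(late, before + 0.15)          # preference reverses
  expect_lt(just_after, late - 0.1)       # ...but not within a single trial
})

test_that("WSLS table is a normalized joint distribution", {
  # an agent that literally plays WSLS has zero off-diagonal mass
  cfg <- task_config(data.frame(n_trials = 200L, p_A = 0.7, p_B = 0.2))
  out <- run_session(cfg, wsls_agent(), seed = 6)
  w <- wsls_comparison(out$log)
  expect_equal(sum(w$table), 1)
  expect_equal(w$agreement, 1)
  expect_equal(w$table["stay", "switch"] + w$table["switch", "stay"], 0)
  # random chooser with random rewards: cells ~ product of marginals
  set.seed(7)
  log_rand <- make_choice_log(sample(c("A", "B"), 4000, TRUE),
                              stats::rbinom(4000, 1, 0.5))
  wr <- wsls_comparison(log_rand)
  marg_pred <- rowSums(wr$table); marg_real <- colSums(wr$table)
  for (i in 1:2) for (j in 1:2)
    expect_lt(abs(wr$table[i, j] - marg_pred[i] * marg_real[j]), 0.03)
})

test_that("history-conditional probabilities match a brute-force scan", {
  set.seed(8)
  odors <- sample(c("A", "B"), 300, TRUE)
  rew <- stats::rbinom(300, 1, 0.4) == 1
  log <- make_choice_log(odors, rew)
  pat <- data.frame(odor_id = c("A", "A"), rewarded = c(TRUE, FALSE))
  hp <- history_conditional_probs(log, pat)
  # brute force
  hits <- 0; nxt_a <- 0
  for (t in 1:(300 - 2)) {
    if (odors[t] == "A" && rew[t] && odors[t + 1] == "A" && !rew[t + 1]) {
      hits <- hits + 1
      nxt_a <- nxt_a + (odors[t + 2] == "A")
    }
  }
  expect_equal(hp$count, hits)
  expect_equal(unname(hp$p_next["A"]), nxt_a / hits)
  # deterministic repeat-last agent: P(stay) = 1 for any realized pattern
  log_rep <- make_choice_log(rep("B", 50), stats::rbinom(50, 1, 0.5) == 1)
  hp_rep <- history_conditional_probs(log_rep,
    data.frame(odor_id = "B", rewarded = FALSE))
  expect_equal(unname(hp_rep$p_next["B"]), 1)
  # never-seen pattern: masked with count 0
  hp0 <- history_conditional_probs(log_rep,
    data.frame(odor_id = "A", rewarded = TRUE))
  expect_equal(hp0$count, 0L)
  expect_true(all(is.na(hp0$p_next)))
})

test_that("memoryless agents are near chance after three losses on one odor", {
  cfg <- task_config(data.frame(n_trials = 2000L, p_A = 0.5, p_B = 0.5),
                     baiting = FALSE)
  out <- run_session(cfg, fixed_accept_agent(0.5, 0.5), seed = 9)
  pat <- data.frame(odor_id = rep("A", 3), rewarded = rep(FALSE, 3))
  hp <- history_conditional_probs(out$log, pat)
  expect_gt(hp$count, 20)
  expect_lt(abs(hp$p_next[["A"]] - 0.5), 3 * sqrt(0.25 / hp$count))
})

test_that("matching metrics are symmetric under odor relabeling", {
  logs <- simulate_matching_population("both", n_flies = 6L, seed = 31)
  bm <- block_matching(logs)
  bm_rel <- block_matching(lapply(logs, relabel_log))
  expect_equal(bm_rel$slope, bm$slope, tolerance = 1e-10)
  w <- wsls_comparison(logs[[1]])
  w_rel <- wsls_comparison(relabel_log(logs[[1]]))
  expect_equal(as.numeric(w_rel$table), as.numeric(w$table))
})
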