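test_that("KC patterns realize sparseness and overlap exactly", {
  ens <- kc_ensemble(100, 0.1, overlap = 0)
  expect_equal(sum(kc_response(ens, "A")), 10)
  expect_equal(sum(kc_response(ens, "A") * kc_response(ens, "B")), 0)
  ens5 <- kc_ensemble(100, 0.1, overlap = 0.5)
  expect_equal(sum(kc_response(ens5, "A") * kc_response(ens5, "B")), 5)
  expect_error(kc_response(ens, "C"), "unknown odor")
  # noise jitters but never below zero; noiseless returns the pattern exactly
  set.seed(1)
  ensn <- kc_ensemble(100, 0.1, noise_sd = 0.3)
  act <- kc_response(ensn, "A")
  expect_true(all(act >= 0))
  expect_false(identical(act, kc_response(kc_ensemble(100, 0.1), "A")))
})

test_that("MBON drive is the weighted sum of KC input", {
  ag <- mb_agent()
  kc <- kc_response(ag$ensemble, "A")
  ag0 <- ag; ag0$W <- rep(0, 100)
  expect_equal(mbon_activity(ag0, kc), 0)
  expect_equal(mbon_activity(ag, kc), 10 * ag$w0)
  ag2 <- ag; ag2$W <- 2 * ag$W
  expect_equal(mbon_activity(ag2, kc), 2 * mbon_activity(ag, kc))
  expect_error(mbon_activity(ag, kc[1:5]), "length")
})

test_that("reject sigmoid is calibrated and monotone", {
  ag <- mb_agent()
  expect_equal(p_reject(ag, ag$m0), 0.5)
  expect_lte(p_reject(ag, 0), 0.02)
  expect_gte(p_reject(ag, ag$w_max * ag$ensemble$n_active), 0.98)
  m <- seq(0, 20, by = 0.5)
  expect_true(all(diff(p_reject(ag, m)) > 0))
  expect_error(mb_agent(sigmoid_slope = 100), "sigmoid")
})

test_that("plasticity variants follow their sign algebra", {
  ens <- kc_ensemble()
  kc <- kc_response(ens, "A")
  eta <- -0.05
  # noncov, R = 1: depression by eta on active cells only
  ag <- mb_agent(ens, plasticity_rule("noncov", eta))
  ag1 <- apply_plasticity(ag, kc, 1)
  expect_equal(ag1$W - ag$W, eta * kc)
  # noncov, R = 0: no change
  expect_equal(apply_plasticity(ag, kc, 0)$W, ag$W)
  # reward_exp, R = 0, E_R = 0: zero product
  agr <- mb_agent(ens, plasticity_rule("reward_exp", eta))
  expect_equal(apply_plasticity(agr, kc, 0)$W, agr$W)
  # reward_exp, R = 0, E_R = 0.8: omission potentiates active synapses
  agr$e_r <- 0.8
  dW <- apply_plasticity(agr, kc, 0)$W - agr$W
  expect_equal(dW, -0.8 * eta * kc)
  expect_true(all(dW[kc > 0] > 0))
  expect_error(plasticity_rule("noncov", eta = 0.1), "eta")
})

test_that("weights stay within [0, w_max] under all rules", {
  set.seed(3)
  for (v in c("noncov", "reward_exp", "sensory_exp", "both")) {
    ag <- mb_agent(kc_ensemble(), plasticity_rule(v, -0.4))
    for (i in 1:200) {
      kc <- kc_response(ag$ensemble, sample(c("A", "B"), 1))
      r <- stats::rbinom(1, 1, 0.5)
      ag <- apply_plasticity(ag, kc, r)
      ag <- update_expectations(ag, kc, r)
      expect_true(all(ag$W >= 0 & ag$W <= ag$w_max))
    }
  }
})

test_that("expectations follow the leaky-average recursion", {
  ag <- mb_agent(rule = plasticity_rule("both", tau_r = 3.5, tau_s = 3.5))
  kc <- kc_response(ag$ensemble, "A")
  ag1 <- update_expectations(ag, kc, 1)
  expect_equal(ag1$e_r, 1 / 3.5)
  # closed form after n rewarded updates from 0: 1 - (1 - 1/tau)^n
  agn <- ag
  for (i in 1:7) agn <- update_expectations(agn, kc, 1)
  expect_equal(agn$e_r, 1 - (1 - 1 / 3.5)^7)
  expect_equal(agn$e_s, kc * (1 - (1 - 1 / 3.5)^7))
})

test_that("reward expectation converges to the reward rate", {
  # constant choice of one odor with baiting off: E_R -> p
  set.seed(4)
  p <- 0.6
  ers <- replicate(30, {
    ag <- mb_agent(rule = plasticity_rule("reward_exp", -0.01))
    kc <- kc_response(ag$ensemble, "A")
    for (i in 1:150) ag <- update_expectations(ag, kc, stats::rbinom(1, 1, p))
    ag$e_r
  })
  se_theory <- sqrt(p * (1 - p) / (2 * 3.5 - 1))   # AR(1) stationary sd
  expect_lt(abs(mean(ers) - p), 2 * se_theory / sqrt(30))
})

test_that("noncovariance weights are non-increasing and odor-specific", {
  set.seed(5)
  cfg <- three_block_config(40L)
  ag <- mb_agent(kc_ensemble(), plasticity_rule("noncov"))
  w_prev <- ag$W
  # track through a real session via repeated short runs
  out <- run_session(cfg, ag, seed = 5)
  expect_true(all(out$agent$W <= w_prev + 1e-12))
  # never-rewarded odor's KCs keep exactly their initial weights (overlap 0)
  cfg2 <- task_config(data.frame(n_trials = 80L, p_A = 1, p_B = 0))
  out2 <- run_session(cfg2, mb_agent(kc_ensemble(), plasticity_rule("noncov")),
                      seed = 6)
  b_cells <- kc_response(out2$agent$ensemble, "B") > 0
  expect_equal(out2$agent$W[b_cells], rep(1, sum(b_cells)))
  expect_lt(mean(out2$agent$W[!b_cells & kc_response(out2$agent$ensemble, "A") > 0]), 0.2)
})

test_that("a zero learning rate leaves behavior at chance", {
  cfg <- three_block_config(40L)
  logs <- simulate_population(cfg, plasticity_rule("both", eta = 0),
                              n_flies = 10L, seed = 7)
  frac <- mean(unlist(lapply(logs, function(l) choices(l)$odor_id == "A")))
  expect_lt(abs(frac - 0.5), 0.05)
  final_w <- run_session(cfg, mb_agent(rule = plasticity_rule("both", 0)),
                         seed = 7)$agent$W
  expect_equal(final_w, rep(1, 100))
})

test_that("population simulation is seed-reproducible", {
  cfg <- three_block_config(20L)
  l1 <- simulate_population(cfg, n_flies = 2L, seed = 9)
  l2 <- simulate_population(cfg, n_flies = 2L, seed = 9)
  expect_identical(lapply(l1, as.data.frame), lapply(l2, as.data.frame))
})

test_that("steady-state choice covariance vanishes for covariance rules", {
  # at equilibrium the product of choice-conditioned reward and the
  # expectation-subtracted DAN term averages to ~0
  set.seed(10)
  cfg <- task_config(data.frame(n_trials = 400L, p_A = 0.6, p_B = 0.3))
  out <- run_session(cfg, mb_agent(rule = plasticity_rule("reward_exp")),
                     seed = 10)
  ch <- choices(out$log)
  ch <- ch[ch$trial_index > 100, ]
  # recompute E_R along the choice sequence
  e_r <- 0; resid <- numeric(nrow(ch))
  for (t in seq_len(nrow(ch))) {
    resid[t] <- ch$rewarded[t] - e_r
    e_r <- (1 - 1 / 3.5) * e_r + ch$rewarded[t] / 3.5
  }
  for (o in c("A", "B")) {
    m <- mean(resid[ch$odor_id == o])
    se <- stats::sd(resid[ch$odor_id == o]) / sqrt(sum(ch$odor_id == o))
    expect_lt(abs(m), 4 * se)
  }
})

test_that("winner-take-all variant differentiates rules", {
  cfg <- three_block_config()
  # symmetric probabilities: choice fraction ~0.5
  cfg_sym <- task_config(data.frame(n_trials = 200L, p_A = 0.4, p_B = 0.4))
  logs_sym <- simulate_winner_take_all(cfg_sym, plasticity_rule("both"),
                                       n_agents = 10L, seed = 11)
  frac <- mean(unlist(lapply(logs_sym, function(l) choices(l)$odor_id == "A")))
  expect_lt(abs(frac - 0.5), 0.1)
  # covariance rule: matching; noncov: slope strictly between 0 and 1
  logs_cov <- simulate_winner_take_all(cfg, plasticity_rule("both"),
                                       n_agents = 25L, seed = 12)
  logs_non <- simulate_winner_take_all(cfg, plasticity_rule("noncov"),
                                       n_agents = 25L, seed = 13)
  s_cov <- block_matching(logs_cov)$slope
  s_non <- block_matching(logs_non)$slope
  expect_gt(s_cov, 0.6)          # near-matching
  expect_gt(s_non, 0)            # in between flat...
  expect_lt(s_non, s_cov)        # ...and the covariance rule's slope
  expect_lt(s_non, 1)
})
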