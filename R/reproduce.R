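# End-to-end reproduction scenarios: each runs a seeded simulation through
# the relevant analysis and compares the computed quantity with the model's
# predicted value.

reproduce_scenarios <- function() list(
  covariance_matching_slope = list(
    description = "block matching slope, full covariance rule (50 agents)",
    expected = 1, tolerance = 0.1,
    compute = function(seed) {
      logs <- simulate_matching_population("both", n_flies = 50L, seed = seed)
      block_matching(logs)$slope
    }),
  reward_exp_matching_slope = list(
    description = "block matching slope, reward-expectation rule (50 agents)",
    expected = 1, tolerance = 0.1,
    compute = function(seed) {
      logs <- simulate_matching_population("reward_exp", n_flies = 50L,
                                           seed = seed)
      block_matching(logs)$slope
    }),
  sensory_exp_matching_slope = list(
    description = "block matching slope, sensory-expectation rule (50 agents)",
    expected = 1, tolerance = 0.1,
    compute = function(seed) {
      logs <- simulate_matching_population("sensory_exp", n_flies = 50L,
                                           seed = seed)
      block_matching(logs)$slope
    }),
  noncov_flat_slope = list(
    description = "block matching slope, noncovariance rule (50 agents)",
    expected = 0, tolerance = 0.3,
    compute = function(seed) {
      logs <- simulate_matching_population("noncov", n_flies = 50L, seed = seed)
      block_matching(logs)$slope
    }),
  noncov_plateau_100_0 = list(
    description = "noncov asymptotic choice % toward rewarded odor, 100:0",
    expected = 75, tolerance = 5,
    compute = function(seed) noncov_plateau(1, 0, seed = seed)),
  noncov_plateau_80_20 = list(
    description = "noncov asymptotic choice % toward richer odor, 80:20",
    expected = 50, tolerance = 5,
    compute = function(seed) noncov_plateau(0.8, 0.2, seed = seed)),
  leaky_tau_recovery = list(
    description = "median recovered leaky-integrator timescale (true tau 7)",
    expected = 7, tolerance = 3,
    compute = function(seed) {
      set.seed(seed)
      cfg <- random_block_schedule()
      logs <- simulate_leaky_agent(cfg, tau = 7, n_agents = 20L, seed = seed)
      stats::median(vapply(logs, function(l) fit_leaky_integrator(l)$tau,
                           numeric(1)))
    })
)

#' Simulate a matching-task population under randomized block schedules
#'
#' Convenience wrapper: each agent gets its own randomized three-block
#' 80-trial schedule (consecutive blocks differ) and an independent seed.
#'
#' @param variant plasticity-rule variant.
#' @param n_flies number of agents.
#' @param seed base seed; fly \code{i} uses \code{seed + i - 1}.
#' @param ensemble a \code{kc_ensemble}.
#' @return List of \code{trial_log}.
#' @export
simulate_matching_population <- function(variant = "both", n_flies = 50L,
                                         seed = 1L,
                                         ensemble = kc_ensemble()) {
  rule <- plasticity_rule(variant)
  lapply(seq_len(check_count(n_flies, "n_flies")), function(i) {
    set.seed(seed + i - 1L)
    cfg <- random_block_schedule()
    agent <- mb_agent(ensemble, rule)
    run_session(cfg, agent, fly_id = i, seed = seed + i - 1L)$log
  })
}

#' Asymptotic noncovariance choice preference
#'
#' Simulates noncovariance-rule agents through 60 unrewarded (naive) and 60
#' training trials with the given baiting probabilities and averages the
#' choice fraction toward the richer odor over the last \code{last_n}
#' training trials, across agents.
#'
#' @param p_rich,p_lean training-block baiting probabilities.
#' @param n_flies number of agents.
#' @param seed base seed.
#' @param last_n number of final training trials to average.
#' @return Mean choice percentage (0-100) toward the richer odor.
#' @export
noncov_plateau <- function(p_rich = 1, p_lean = 0, n_flies = 50L, seed = 1L,
                           last_n = 20L) {
  cfg <- task_config(data.frame(n_trials = c(60L, 60L),
                                p_A = c(0, p_rich), p_B = c(0, p_lean)))
  logs <- simulate_population(cfg, plasticity_rule("noncov"), kc_ensemble(),
                              n_flies = n_flies, seed = seed)
  fracs <- vapply(logs, function(log) {
    ch <- choices(log)
    tail_ch <- ch[ch$trial_index > 120L - last_n, ]
    mean(tail_ch$odor_id == "A")
  }, numeric(1))
  100 * mean(fracs)
}

#' Run reproduction scenarios
#'
#' Recomputes headline model predictions from scratch (simulation through
#' analysis) and compares each with its predicted value and tolerance.
#'
#' @param scenarios character vector of scenario names; default all. See
#'   \code{names(mbforage:::reproduce_scenarios())}.
#' @param seed base integer seed for all randomness.
#' @param quiet suppress per-scenario printing.
#' @return data.frame with \code{scenario}, \code{computed}, \code{expected},
#'   \code{tolerance}, \code{pass}, \code{seed}.
#' @export
reproduce <- function(scenarios = NULL, seed = 1L, quiet = FALSE) {
  all_sc <- reproduce_scenarios()
  scenarios <- scenarios %||% names(all_sc)
  unknown <- setdiff(scenarios, names(all_sc))
  if (length(unknown))
    stop_validation("unknown scenario(s): ", paste(unknown, collapse = ", "))
  out <- do.call(rbind, lapply(scenarios, function(nm) {
    sc <- all_sc[[nm]]
    val <- sc$compute(seed)
    pass <- abs(val - sc$expected) <= sc$tolerance
    if (!quiet)
      cat(sprintf("%-28s computed %8.3f  expected %g +/- %g  [%s]  seed %d\n",
                  nm, val, sc$expected, sc$tolerance,
                  if (pass) "ok" else "FAIL", seed))
    data.frame(scenario = nm, computed = val, expected = sc$expected,
               tolerance = sc$tolerance, pass = pass, seed = seed)
  }))
  invisible(out)
}
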