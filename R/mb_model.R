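# Mushroom-body-inspired generative agent: sparse KC odor representations,
# plastic KC->MBON weights with a depression-based learning rate (eta < 0),
# a sigmoidal reject readout, and four candidate plasticity rules.

#' Kenyon-cell odor ensemble
#'
#' Each odor activates a sparse binary subset of the KC population. Overlap
#' between the two odors' subsets is realized exactly by construction;
#' per-encounter activity can be jittered with Gaussian noise (clipped at 0).
#'
#' @param n_kc total number of Kenyon cells.
#' @param active_fraction fraction of cells active per odor.
#' @param overlap fraction of each odor's active cells shared with the other.
#' @param noise_sd standard deviation of per-encounter activity jitter.
#' @return An object of class \code{kc_ensemble} holding the two patterns.
#' @export
kc_ensemble <- function(n_kc = 100L, active_fraction = 0.1, overlap = 0,
                        noise_sd = 0) {
  n_kc <- check_count(n_kc, "n_kc")
  check_probability(active_fraction, "active_fraction")
  check_probability(overlap, "overlap")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_validation("noise_sd must be non-negative")
  n_active <- round(n_kc * active_fraction)
  if (n_active < 1L) stop_validation("active_fraction too small: no active cells")
  n_shared <- round(overlap * n_active)
  if (2L * n_active - n_shared > n_kc)
    stop_validation("n_kc too small for the requested patterns")
  pat_a <- pat_b <- numeric(n_kc)
  pat_a[seq_len(n_active)] <- 1
  pat_b[seq.int(n_active - n_shared + 1L, 2L * n_active - n_shared)] <- 1
  structure(list(n_kc = n_kc, n_active = n_active,
                 overlap = n_shared / n_active, noise_sd = noise_sd,
                 patterns = cbind(A = pat_a, B = pat_b)),
            class = "kc_ensemble")
}

#' @export
print.kc_ensemble <- function(x, ...) {
  cat("KC ensemble:", x$n_kc, "cells,", x$n_active, "active/odor, overlap",
      x$overlap, ", noise sd", x$noise_sd, "\n")
  invisible(x)
}

#' Realized KC activity for one odor encounter
#'
#' @param ensemble a \code{kc_ensemble}.
#' @param odor_id \code{"A"} or \code{"B"}.
#' @return Non-negative activity vector: the odor's binary pattern plus
#'   Gaussian jitter of sd \code{noise_sd}, clipped at 0.
#' @export
kc_response <- function(ensemble, odor_id) {
  if (!odor_id %in% colnames(ensemble$patterns))
    stop_validation("unknown odor id: ", odor_id)
  s <- ensemble$patterns[, odor_id]
  if (ensemble$noise_sd > 0)
    s <- pmax(s + stats::rnorm(length(s), 0, ensemble$noise_sd), 0)
  s
}

#' Specify a plasticity rule variant
#'
#' The weight update at each choice is \code{dW_i = eta * K_i * D} with the
#' KC factor \code{K_i = S_i} or \code{S_i - E(S_i)} and the DAN factor
#' \code{D = R} or \code{R - E(R)}, depending on the variant:
#' \describe{
#'   \item{noncov}{\code{eta * S_i * R} (no expectations)}
#'   \item{reward_exp}{\code{eta * S_i * (R - E(R))}}
#'   \item{sensory_exp}{\code{eta * (S_i - E(S_i)) * R}}
#'   \item{both}{\code{eta * (S_i - E(S_i)) * (R - E(R))}}
#' }
#' \code{eta < 0} reflects the fly's depression-based learning; with the
#' reject readout, depression of a rewarded odor's synapses makes that odor
#' more likely to be accepted. Expectations are recency-weighted averages
#' with per-trial timescales \code{tau_r}, \code{tau_s}.
#'
#' @param variant one of \code{"noncov"}, \code{"reward_exp"},
#'   \code{"sensory_exp"}, \code{"both"}.
#' @param eta learning rate, must be <= 0 (0 disables learning).
#' @param tau_r,tau_s expectation timescales in trials (>= 1).
#' @return An object of class \code{plasticity_rule}.
#' @export
plasticity_rule <- function(variant = c("both", "noncov", "reward_exp",
                                        "sensory_exp"),
                            eta = -0.3, tau_r = 3.5, tau_s = 3.5) {
  variant <- match.arg(variant)
  if (!is.numeric(eta) || length(eta) != 1L || eta > 0)
    stop_validation("eta must be <= 0 (depression-based rule)")
  if (tau_r < 1 || tau_s < 1)
    stop_validation("expectation timescales must be >= 1 trial")
  structure(list(variant = variant, eta = eta, tau_r = tau_r, tau_s = tau_s),
            class = "plasticity_rule")
}

#' @export
print.plasticity_rule <- function(x, ...) {
  cat("Plasticity rule:", x$variant, " eta =", x$eta,
      " tau_R =", x$tau_r, " tau_S =", x$tau_s, "\n")
  invisible(x)
}

rule_uses_reward_exp <- function(variant) variant %in% c("reward_exp", "both")
rule_uses_sensory_exp <- function(variant) variant %in% c("sensory_exp", "both")

#' Create a mushroom-body agent
#'
#' Weights start uniform at \code{w0} and are clipped to \code{[0, 2 * w0]}
#' after every update (synaptic saturation, floor at 0). The sigmoid of the
#' reject readout is calibrated so that the naive agent rejects with
#' probability exactly 0.5 (midpoint at the initial MBON drive) and behaves
#' near-deterministically at the extremes: with the default slope
#' \code{m0 / 16}, fully depressed weights give reject probability well below
#' 0.02 and saturated weights well above 0.98, so learned preferences are
#' expressed sharply while the naive baseline stays at chance.
#'
#' @param ensemble a \code{kc_ensemble}.
#' @param rule a \code{plasticity_rule}.
#' @param w0 initial uniform KC->MBON weight.
#' @param sigmoid_slope slope of the reject sigmoid; default \code{m0 / 16}.
#' @return An object of class \code{mb_agent}.
#' @export
mb_agent <- function(ensemble = kc_ensemble(), rule = plasticity_rule(),
                     w0 = 1, sigmoid_slope = NULL) {
  stopifnot(inherits(ensemble, "kc_ensemble"), inherits(rule, "plasticity_rule"))
  if (w0 <= 0) stop_validation("w0 must be positive")
  m0 <- w0 * ensemble$n_active
  s <- sigmoid_slope %||% (m0 / 16)
  if (s <= 0 || stats::plogis(-m0 / s) > 0.02)
    stop_validation("sigmoid slope too shallow: reject probability at m = 0 ",
                    "must be <= 0.02")
  structure(list(ensemble = ensemble, rule = rule,
                 W = rep(w0, ensemble$n_kc), w0 = w0, w_max = 2 * w0,
                 e_r = 0, e_s = rep(0, ensemble$n_kc),
                 m0 = m0, s = s),
            class = "mb_agent", rule_name = rule$variant)
}

#' @export
print.mb_agent <- function(x, ...) {
  cat("MB agent (", x$rule$variant, "): mean W =",
      signif(mean(x$W), 4), ", E(R) =", signif(x$e_r, 4), "\n")
  invisible(x)
}

#' MBON drive for a KC activity vector
#'
#' @param agent an \code{mb_agent}.
#' @param kc activity vector (length \code{n_kc}).
#' @return \code{m = sum(W * kc)}, non-negative.
#' @export
mbon_activity <- function(agent, kc) {
  if (length(kc) != length(agent$W))
    stop_validation("KC activity length does not match weight vector")
  sum(agent$W * kc)
}

#' Reject probability from MBON drive
#'
#' Higher MBON activity encodes a greater tendency to reject; the drive is
#' passed through a logistic nonlinearity with midpoint \code{m0} and slope
#' \code{s}.
#'
#' @param agent an \code{mb_agent}.
#' @param m MBON drive (>= 0).
#' @return Probability of rejecting the encountered odor.
#' @export
p_reject <- function(agent, m) {
  stats::plogis((m - agent$m0) / agent$s)
}

#' Apply one plasticity update at a choice
#'
#' Updates the weight vector according to the rule variant (see
#' \code{\link{plasticity_rule}}) and clips it to \code{[0, w_max]}.
#' Expectations used are the state before this event; call
#' \code{\link{update_expectations}} afterwards.
#'
#' @param agent an \code{mb_agent}.
#' @param kc realized KC activity at the choice.
#' @param reward harvested reward, 0 or 1.
#' @return The updated agent.
#' @export
apply_plasticity <- function(agent, kc, reward) {
  rule <- agent$rule
  kc_term <- if (rule_uses_sensory_exp(rule$variant)) kc - agent$e_s else kc
  dan_term <- if (rule_uses_reward_exp(rule$variant)) reward - agent$e_r else reward
  agent$W <- pmin(pmax(agent$W + rule$eta * kc_term * dan_term, 0), agent$w_max)
  agent
}

#' Update reward and sensory expectations
#'
#' Recency-weighted running averages, updated once per choice:
#' \code{E(R) <- (1 - 1/tau_R) E(R) + (1/tau_R) R} and elementwise
#' \code{E(S) <- (1 - 1/tau_S) E(S) + (1/tau_S) kc}.
#'
#' @inheritParams apply_plasticity
#' @return The updated agent.
#' @export
update_expectations <- function(agent, kc, reward) {
  rule <- agent$rule
  agent$e_r <- (1 - 1 / rule$tau_r) * agent$e_r + reward / rule$tau_r
  agent$e_s <- (1 - 1 / rule$tau_s) * agent$e_s + kc / rule$tau_s
  agent
}

#' @rdname encounter_response
#' @export
encounter_response.mb_agent <- function(agent, odor_id, ...) {
  kc <- kc_response(agent$ensemble, odor_id)
  pr <- p_reject(agent, mbon_activity(agent, kc))
  list(accepted = stats::runif(1) >= pr, kc = kc, agent = agent)
}

#' @rdname post_choice_update
#' @export
post_choice_update.mb_agent <- function(agent, kc, reward, ...) {
  agent <- apply_plasticity(agent, kc, reward)
  update_expectations(agent, kc, reward)
}

#' Simulate a population of mushroom-body agents
#'
#' Runs \code{n_flies} independent sessions, fly \code{i} seeded with
#' \code{seed + i - 1}.
#'
#' @param config a \code{task_config}.
#' @param rule a \code{plasticity_rule}.
#' @param ensemble a \code{kc_ensemble}.
#' @param n_flies number of independent agents.
#' @param seed base integer seed.
#' @param w0 initial weight (see \code{\link{mb_agent}}).
#' @return List of \code{trial_log}, one per fly.
#' @export
simulate_population <- function(config, rule = plasticity_rule(),
                                ensemble = kc_ensemble(), n_flies = 50L,
                                seed = 1L, w0 = 1) {
  n_flies <- check_count(n_flies, "n_flies")
  lapply(seq_len(n_flies), function(i) {
    agent <- mb_agent(ensemble, rule, w0)
    run_session(config, agent, fly_id = i, seed = seed + i - 1L)$log
  })
}

#' Simulate winner-take-all agents (both options present)
#'
#' The original circuit variant: on every trial both odors' KC populations
#' are active, each drives its own output pathway, and the choice is the
#' pathway with the larger noisy motor drive (here, the smaller MBON reject
#' drive, since MBON activity encodes avoidance). Plasticity is applied with
#' both sensory inputs active at the time of reward. KC noise (or the
#' explicit decision noise) is what lets a noncovariance rule partially
#' differentiate the options in this task, giving a choice-vs-reward slope
#' strictly between flat and unity.
#'
#' @param config a \code{task_config}.
#' @param rule a \code{plasticity_rule}.
#' @param ensemble a \code{kc_ensemble}; a positive \code{noise_sd} is
#'   expected for this variant.
#' @param n_agents number of independent agents.
#' @param seed base integer seed.
#' @param decision_sd sd of additional Gaussian noise on each pathway's
#'   drive at the comparison.
#' @param w0 initial weight.
#' @return List of \code{trial_log}, one per agent (one choice row per
#'   trial; no encounter loop).
#' @export
simulate_winner_take_all <- function(config, rule = plasticity_rule(),
                                     ensemble = kc_ensemble(noise_sd = 0.05),
                                     n_agents = 50L, seed = 1L,
                                     decision_sd = 0, w0 = 1) {
  stopifnot(inherits(config, "task_config"))
  n_agents <- check_count(n_agents, "n_agents")
  if (ensemble$noise_sd <= 0 && decision_sd <= 0)
    warning("winner-take-all with no KC or decision noise is degenerate")
  lapply(seq_len(n_agents), function(i) {
    set.seed(seed + i - 1L)
    agent <- mb_agent(ensemble, rule, w0)
    state <- bait_state(c(A = FALSE, B = FALSE))
    rows <- vector("list", sum(config$blocks$n_trials))
    trial <- 0L
    for (b in seq_len(nrow(config$blocks))) {
      blk <- config$blocks[b, ]
      for (k in seq_len(blk$n_trials)) {
        trial <- trial + 1L
        state <- if (config$baiting) {
          update_baits(state, blk$p_A, blk$p_B)
        } else {
          bait_state(c(A = stats::runif(1) < blk$p_A,
                       B = stats::runif(1) < blk$p_B))
        }
        kc_a <- kc_response(agent$ensemble, "A")
        kc_b <- kc_response(agent$ensemble, "B")
        drive_a <- mbon_activity(agent, kc_a) + stats::rnorm(1, 0, decision_sd)
        drive_b <- mbon_activity(agent, kc_b) + stats::rnorm(1, 0, decision_sd)
        odor <- if (drive_a < drive_b) "A" else "B"
        h <- harvest(state, odor)
        state <- h$state
        agent <- post_choice_update(agent, kc_a + kc_b, h$reward)
        rows[[trial]] <- data.frame(
          fly_id = i, trial_index = trial, block_index = b,
          encounter_index = 1L, odor_id = odor, accepted = TRUE,
          is_choice = TRUE, rewarded = h$reward == 1L, forced = FALSE)
      }
    }
    trial_log(do.call(rbind, rows),
              meta = list(fly_id = i, seed = seed + i - 1L,
                          rule = paste0("wta_", rule$variant)))
  })
}

#' Simulate leaky-integrator value agents
#'
#' A reference generator for timescale-recovery analyses: each option's value
#' is an exponentially weighted average of its reward history with timescale
#' \code{tau}, and choices follow
#' \code{P(A) = plogis(beta * (V_A - V_B) + bias)}.
#'
#' @param config a \code{task_config}.
#' @param tau value timescale in trials.
#' @param beta inverse temperature of the softmax choice rule.
#' @param bias additive choice bias toward odor A.
#' @param n_agents number of agents.
#' @param seed base integer seed.
#' @return List of \code{trial_log} (one choice row per trial).
#' @export
simulate_leaky_agent <- function(config, tau = 7, beta = 5, bias = 0,
                                 n_agents = 20L, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  if (tau < 1) stop_validation("tau must be >= 1")
  lapply(seq_len(check_count(n_agents, "n_agents")), function(i) {
    set.seed(seed + i - 1L)
    state <- bait_state(c(A = FALSE, B = FALSE))
    v <- c(A = 0, B = 0)
    rows <- vector("list", sum(config$blocks$n_trials))
    trial <- 0L
    for (b in seq_len(nrow(config$blocks))) {
      blk <- config$blocks[b, ]
      for (k in seq_len(blk$n_trials)) {
        trial <- trial + 1L
        state <- if (config$baiting) {
          update_baits(state, blk$p_A, blk$p_B)
        } else {
          bait_state(c(A = stats::runif(1) < blk$p_A,
                       B = stats::runif(1) < blk$p_B))
        }
        p_a <- stats::plogis(beta * (v[["A"]] - v[["B"]]) + bias)
        odor <- if (stats::runif(1) < p_a) "A" else "B"
        h <- harvest(state, odor)
        state <- h$state
        v <- (1 - 1 / tau) * v
        v[odor] <- v[odor] + h$reward / tau
        rows[[trial]] <- data.frame(
          fly_id = i, trial_index = trial, block_index = b,
          encounter_index = 1L, odor_id = odor, accepted = TRUE,
          is_choice = TRUE, rewarded = h$reward == 1L, forced = FALSE)
      }
    }
    trial_log(do.call(rbind, rows),
              meta = list(fly_id = i, seed = seed + i - 1L,
                          rule = "leaky_integrator"))
  })
}
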