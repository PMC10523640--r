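# Reference agents and log builders used across tests.

# Agent that accepts odor A with probability a and odor B with probability b,
# independent of history. Oracle for the encounter-alternation closed form.
fixed_accept_agent <- function(a, b) {
  structure(list(p = c(A = a, B = b)), class = "fixed_accept_agent")
}
encounter_response.fixed_accept_agent <- function(agent, odor_id, ...) {
  list(accepted = stats::runif(1) < agent$p[[odor_id]], kc = NULL,
       agent = agent)
}
post_choice_update.fixed_accept_agent <- function(agent, kc, reward, ...) agent
registerS3method("encounter_response", "fixed_accept_agent",
                 encounter_response.fixed_accept_agent,
                 envir = asNamespace("mbforage"))
registerS3method("post_choice_update", "fixed_accept_agent",
                 post_choice_update.fixed_accept_agent,
                 envir = asNamespace("mbforage"))

# Agent that literally plays win-stay/lose-switch (accepts only the target
# odor; starts on A).
wsls_agent <- function() {
  structure(list(target = "A"), class = "wsls_agent")
}
encounter_response.wsls_agent <- function(agent, odor_id, ...) {
  list(accepted = odor_id == agent$target, kc = NULL, agent = agent)
}
post_choice_update.wsls_agent <- function(agent, kc, reward, ...) {
  if (!reward) agent$target <- if (agent$target == "A") "B" else "A"
  agent
}
registerS3method("encounter_response", "wsls_agent",
                 encounter_response.wsls_agent,
                 envir = asNamespace("mbforage"))
registerS3method("post_choice_update", "wsls_agent",
                 post_choice_update.wsls_agent,
                 envir = asNamespace("mbforage"))

# Build a choice-only trial log from parallel vectors.
make_choice_log <- function(odors, rewarded, fly_id = 1L, block_index = 1L) {
  n <- length(odors)
  trial_log(data.frame(
    fly_id = fly_id, trial_index = seq_len(n),
    block_index = rep_len(block_index, n), encounter_index = 1L,
    odor_id = odors, accepted = TRUE, is_choice = TRUE,
    rewarded = as.logical(rewarded), forced = FALSE))
}

# Swap odor labels A <-> B everywhere in a log.
relabel_log <- function(log) {
  meta <- attr(log, "meta")
  df <- as.data.frame(log)
  df$odor_id <- ifelse(df$odor_id == "A", "B", "A")
  trial_log(df, meta = meta)
}

three_block_config <- function(n_trials = 80L) {
  task_config(data.frame(n_trials = n_trials,
                         p_A = c(0.8, 0.2, 0.8), p_B = c(0.2, 0.8, 0.2)))
}
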