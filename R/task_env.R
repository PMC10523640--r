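#' Configure a baited two-odor dynamic-foraging task
#'
#' A session is a sequence of blocks; within a block each odor has a fixed
#' baiting probability. At the start of every trial each currently unbaited
#' odor becomes baited independently with its block probability; a bait, once
#' set, persists until that odor is chosen (harvested). With \code{baiting =
#' FALSE} reward is instead an independent Bernoulli draw at each choice.
#'
#' @param blocks data.frame (or matrix) with columns \code{n_trials},
#'   \code{p_A}, \code{p_B}, one row per block.
#' @param baiting logical; if \code{TRUE} (default) rewards persist until
#'   collected.
#' @param n_odors number of odor options; the analytics assume 2.
#' @return An object of class \code{task_config}.
#' @examples
#' cfg <- task_config(data.frame(n_trials = 80,
#'                               p_A = c(0.8, 0.1, 0.4),
#'                               p_B = c(0.2, 0.4, 0.1)))
#' @export
task_config <- function(blocks, baiting = TRUE, n_odors = 2L) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) < 1L) stop_validation("block list must be non-empty")
  required <- c("n_trials", "p_A", "p_B")
  if (!all(required %in% names(blocks)))
    stop_validation("blocks must have columns n_trials, p_A, p_B")
  for (i in seq_len(nrow(blocks))) {
    check_count(blocks$n_trials[i], "n_trials")
    check_probability(blocks$p_A[i], "p_A")
    check_probability(blocks$p_B[i], "p_B")
  }
  n_odors <- check_count(n_odors, "n_odors", min = 2L)
  structure(list(blocks = blocks[, required],
                 baiting = isTRUE(baiting),
                 n_odors = n_odors),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Dynamic-foraging task:", nrow(x$blocks), "block(s),",
      sum(x$blocks$n_trials), "trials, baiting",
      if (x$baiting) "on" else "off", "\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Draw a randomized block schedule
#'
#' Samples baiting-probability pairs for a multi-block session from a fixed
#' menu, requiring consecutive blocks to differ so that every session contains
#' informative block transitions.
#'
#' @param n_blocks number of blocks.
#' @param n_trials trials per block.
#' @param pairs matrix with columns \code{p_A}, \code{p_B}: the candidate
#'   probability pairs. Default: (0.8, 0.2), (0.4, 0.1), (0.2, 0.8), (0.1, 0.4).
#' @return A \code{task_config}.
#' @export
random_block_schedule <- function(n_blocks = 3L, n_trials = 80L,
                                  pairs = cbind(p_A = c(0.8, 0.4, 0.2, 0.1),
                                                p_B = c(0.2, 0.1, 0.8, 0.4))) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  idx <- integer(n_blocks)
  idx[1L] <- sample.int(nrow(pairs), 1L)
  for (b in seq_len(n_blocks)[-1L]) {
    repeat {
      idx[b] <- sample.int(nrow(pairs), 1L)
      if (idx[b] != idx[b - 1L]) break
    }
  }
  task_config(data.frame(n_trials = n_trials,
                         p_A = pairs[idx, 1L], p_B = pairs[idx, 2L]))
}

#' Create a bait-availability state
#'
#' @param baited named logical vector, one element per odor.
#' @return An object of class \code{bait_state}.
#' @export
bait_state <- function(baited = c(A = FALSE, B = FALSE)) {
  if (!is.logical(baited) || is.null(names(baited)) || anyNA(baited))
    stop_validation("baited must be a named logical vector")
  structure(baited, class = "bait_state")
}

#' Stochastically replenish baits
#'
#' Each currently unbaited odor becomes baited independently with its
#' probability; already-baited odors stay baited (rewards persist until
#' collected).
#'
#' @param state a \code{bait_state}.
#' @param p_A,p_B per-trial baiting probabilities for the two odors.
#' @return The updated \code{bait_state}.
#' @export
update_baits <- function(state, p_A, p_B) {
  check_probability(p_A, "p_A"); check_probability(p_B, "p_B")
  p <- c(A = p_A, B = p_B)[names(state)]
  new <- state | (stats::runif(length(state)) < p)
  bait_state(stats::setNames(as.logical(new), names(state)))
}

#' Harvest the bait of a chosen odor
#'
#' @param state a \code{bait_state}.
#' @param chosen_odor odor name (e.g. \code{"A"}).
#' @return list with \code{reward} (0/1) and the updated \code{state}; the
#'   chosen odor's bait is cleared, the other odor is untouched.
#' @export
harvest <- function(state, chosen_odor) {
  if (!chosen_odor %in% names(state))
    stop_validation("unknown odor id: ", chosen_odor)
  reward <- as.integer(state[[chosen_odor]])
  state[chosen_odor] <- FALSE
  list(reward = reward, state = bait_state(unclass(state)))
}

# ---- agent interface -------------------------------------------------------

#' Agent hook: respond to an odor encounter
#'
#' Generic called by \code{\link{run_session}} once per encounter. Methods
#' must return \code{list(accepted = logical, kc = numeric or NULL,
#' agent = updated agent)}; \code{kc} is the realized sensory activity to be
#' passed back through \code{\link{post_choice_update}} if the encounter
#' becomes the trial's choice.
#'
#' @param agent the agent object.
#' @param odor_id odor name.
#' @param ... further arguments for methods.
#' @export
encounter_response <- function(agent, odor_id, ...) UseMethod("encounter_response")

#' Agent hook: learn from the trial's choice outcome
#'
#' Called by \code{\link{run_session}} exactly once per trial, after the
#' choice's reward has been harvested.
#'
#' @param agent the agent object.
#' @param kc realized sensory activity at the chosen encounter.
#' @param reward 0/1 harvested reward.
#' @param ... further arguments for methods.
#' @return the updated agent.
#' @export
post_choice_update <- function(agent, kc, reward, ...) UseMethod("post_choice_update")

# ---- trial log -------------------------------------------------------------

trial_log_columns <- c("fly_id", "trial_index", "block_index",
                       "encounter_index", "odor_id", "accepted",
                       "is_choice", "rewarded", "forced")

#' Construct/validate a trial log
#'
#' One row per odor encounter. Exactly one row per trial is the choice
#' (\code{is_choice}); rewards occur only on choice rows; encounter indices
#' increment by one within a trial.
#'
#' @param df data.frame with columns \code{fly_id}, \code{trial_index},
#'   \code{block_index}, \code{encounter_index}, \code{odor_id},
#'   \code{accepted}, \code{is_choice}, \code{rewarded}, \code{forced}.
#' @param meta optional named list of session metadata (seed, rule name, ...).
#' @return The data.frame with class \code{trial_log}.
#' @export
trial_log <- function(df, meta = list()) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(trial_log_columns, names(df))
  if (length(missing_cols))
    stop_validation("trial log missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  df <- df[, trial_log_columns]
  validate_trial_log(df)
  structure(df, meta = meta, class = c("trial_log", "data.frame"))
}

validate_trial_log <- function(df) {
  if (any(df$rewarded & !df$is_choice))
    stop_validation("rewarded = TRUE on a non-choice row")
  if (any(df$is_choice & !df$accepted))
    stop_validation("a choice row must be an accepted encounter")
  for (fly in unique(df$fly_id)) {
    sub <- df[df$fly_id == fly, ]
    per_trial <- tapply(sub$is_choice, sub$trial_index, sum)
    if (any(per_trial != 1L))
      stop_validation("fly ", fly, ": each trial must have exactly one choice row")
    enc_ok <- tapply(sub$encounter_index, sub$trial_index,
                     function(e) all(e == seq_along(e)))
    if (!all(enc_ok))
      stop_validation("fly ", fly, ": encounter_index must increment by 1 within a trial")
  }
  invisible(df)
}

#' @export
print.trial_log <- function(x, ...) {
  ch <- x[x$is_choice, ]
  cat("Trial log:", length(unique(x$fly_id)), "fly/flies,", nrow(ch),
      "choices,", nrow(x), "encounters,",
      sum(ch$rewarded), "rewards\n")
  meta <- attr(x, "meta")
  if (length(meta))
    cat("  meta:", paste(names(meta), unlist(lapply(meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract the choice rows of a trial log
#'
#' @param log a \code{trial_log}.
#' @return data.frame of choice rows ordered by fly and trial.
#' @export
choices <- function(log) {
  ch <- as.data.frame(log)[log$is_choice, ]
  ch[order(ch$fly_id, ch$trial_index), ]
}

#' Run one dynamic-foraging session
#'
#' Couples an agent to the task. Per trial: baits are replenished, the first
#' encounter's odor is drawn uniformly, and after every rejection the next
#' encounter is deterministically the other odor (rejecting one odorized arm
#' of a Y-maze leads into the other). The first accepted encounter is the
#' trial's choice; its reward is harvested and passed to the agent's learning
#' hook. A safety cap forces acceptance after \code{max_encounters}
#' rejections and flags the row.
#'
#' @param config a \code{task_config}.
#' @param agent an object with \code{\link{encounter_response}} and
#'   \code{\link{post_choice_update}} methods.
#' @param fly_id identifier stored in the log.
#' @param seed optional integer; if given, seeds R's RNG for the session.
#' @param max_encounters forced-acceptance cap per trial.
#' @return list with \code{log} (a \code{trial_log}) and the final
#'   \code{agent}.
#' @export
run_session <- function(config, agent, fly_id = 1L, seed = NULL,
                        max_encounters = 100L) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  odors <- c("A", "B")
  state <- bait_state(stats::setNames(rep(FALSE, 2L), odors))
  rows <- vector("list", sum(config$blocks$n_trials) * 2L)
  nrow_used <- 0L
  trial <- 0L
  for (b in seq_len(nrow(config$blocks))) {
    blk <- config$blocks[b, ]
    for (k in seq_len(blk$n_trials)) {
      trial <- trial + 1L
      if (config$baiting) {
        state <- update_baits(state, blk$p_A, blk$p_B)
      } else {
        state <- bait_state(c(A = stats::runif(1) < blk$p_A,
                              B = stats::runif(1) < blk$p_B))
      }
      odor <- odors[sample.int(2L, 1L)]
      enc <- 0L
      repeat {
        enc <- enc + 1L
        resp <- encounter_response(agent, odor)
        agent <- resp$agent
        forced <- FALSE
        if (!resp$accepted && enc >= max_encounters) {
          resp$accepted <- TRUE
          forced <- TRUE
          warning("encounter cap reached; acceptance forced (fly ", fly_id,
                  ", trial ", trial, ")")
        }
        if (resp$accepted) {
          h <- harvest(state, odor)
          state <- h$state
          agent <- post_choice_update(agent, resp$kc, h$reward)
          nrow_used <- nrow_used + 1L
          rows[[nrow_used]] <- data.frame(
            fly_id = fly_id, trial_index = trial, block_index = b,
            encounter_index = enc, odor_id = odor, accepted = TRUE,
            is_choice = TRUE, rewarded = h$reward == 1L, forced = forced)
          break
        }
        nrow_used <- nrow_used + 1L
        rows[[nrow_used]] <- data.frame(
          fly_id = fly_id, trial_index = trial, block_index = b,
          encounter_index = enc, odor_id = odor, accepted = FALSE,
          is_choice = FALSE, rewarded = FALSE, forced = FALSE)
        odor <- if (odor == "A") "B" else "A"
      }
    }
  }
  log <- trial_log(do.call(rbind, rows[seq_len(nrow_used)]),
                   meta = list(fly_id = fly_id, seed = seed,
                               rule = attr(agent, "rule_name") %||% class(agent)[1L]))
  list(log = log, agent = agent)
}
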