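# Matching-law analytics over trial logs (simulated or experimental).
# "Choice fraction" and "reward fraction" are A/(A+B) proportions; in
# fraction space the matching law is the identity line.

as_log_list <- function(logs) {
  if (inherits(logs, "trial_log")) list(logs) else logs
}

#' Trailing-window choice and reward fractions
#'
#' Causal moving fractions over the trailing \code{window} choices: the
#' fraction of choices made to odor A, and the fraction of rewards obtained
#' from odor A. The first \code{window - 1} trials are masked (\code{NA}), as
#' is the reward fraction wherever the window contains no reward.
#'
#' @param log a \code{trial_log} for a single fly.
#' @param window window length in choices.
#' @return data.frame with \code{trial_index}, \code{choice_frac},
#'   \code{reward_frac}.
#' @export
instantaneous_fractions <- function(log, window = 10L) {
  ch <- choices(log)
  if (nrow(ch) == 0L) stop_validation("empty trial log")
  if (length(unique(ch$fly_id)) > 1L)
    stop_validation("instantaneous_fractions expects a single fly's log")
  window <- check_count(window, "window")
  is_a <- as.numeric(ch$odor_id == "A")
  rew_a <- as.numeric(ch$rewarded & ch$odor_id == "A")
  rew <- as.numeric(ch$rewarded)
  n <- nrow(ch)
  choice_frac <- reward_frac <- rep(NA_real_, n)
  if (n >= window) {
    ca <- cumsum(is_a); cra <- cumsum(rew_a); cr <- cumsum(rew)
    idx <- window:n
    lag0 <- function(x, i) ifelse(i - window >= 1L, x[pmax(i - window, 1L)], 0)
    choice_frac[idx] <- (ca[idx] - lag0(ca, idx)) / window
    rew_in_win <- cr[idx] - lag0(cr, idx)
    rf <- (cra[idx] - lag0(cra, idx)) / rew_in_win
    rf[rew_in_win == 0] <- NA_real_
    reward_frac[idx] <- rf
  }
  data.frame(trial_index = ch$trial_index, choice_frac = choice_frac,
             reward_frac = reward_frac)
}

#' Block-averaged matching summary
#'
#' Computes per-block choice and reward fractions for every fly, pools the
#' blocks, and fits an ordinary least-squares line of choice fraction on
#' reward fraction. Matching corresponds to slope 1; undermatching to slope
#' below 1. Blocks with zero rewards are excluded (and counted).
#'
#' @param logs a \code{trial_log} or list of them.
#' @return An object of class \code{matching_summary}: \code{blocks}
#'   data.frame (fly, block, choice_fraction, reward_fraction), \code{slope},
#'   \code{intercept}, \code{n_excluded}.
#' @export
block_matching <- function(logs) {
  logs <- as_log_list(logs)
  rows <- do.call(rbind, lapply(logs, function(log) {
    ch <- choices(log)
    do.call(rbind, lapply(split(ch, ch$block_index), function(blk) {
      data.frame(fly_id = blk$fly_id[1L], block_index = blk$block_index[1L],
                 choice_fraction = mean(blk$odor_id == "A"),
                 reward_fraction = if (any(blk$rewarded))
                   mean(blk$odor_id[blk$rewarded] == "A") else NA_real_,
                 n_rewards = sum(blk$rewarded))
    }))
  }))
  excluded <- sum(is.na(rows$reward_fraction))
  keep <- rows[!is.na(rows$reward_fraction), ]
  if (nrow(keep) < 2L)
    stop_validation("need at least 2 blocks with rewards to fit a matching line")
  fit <- stats::lm(choice_fraction ~ reward_fraction, data = keep)
  structure(list(blocks = keep,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_excluded = excluded),
            class = "matching_summary")
}

#' @export
print.matching_summary <- function(x, ...) {
  cat("Matching summary:", nrow(x$blocks), "blocks; slope =",
      signif(x$slope, 4), ", intercept =", signif(x$intercept, 4), "\n")
  if (x$n_excluded > 0)
    cat("  (", x$n_excluded, "rewardless block(s) excluded )\n")
  invisible(x)
}

#' Undermatching mean squared error
#'
#' Mean of the squared differences between the instantaneous choice-fraction
#' and reward-fraction series, over trials where both are defined. Zero for a
#' perfectly matching fly; larger for flatter (undermatching) behavior.
#'
#' @inheritParams instantaneous_fractions
#' @return Non-negative scalar.
#' @export
undermatching_mse <- function(log, window = 10L) {
  fr <- instantaneous_fractions(log, window)
  ok <- !is.na(fr$choice_frac) & !is.na(fr$reward_frac)
  if (!any(ok))
    stop_validation("no overlapping unmasked samples in the fraction series")
  mean((fr$choice_frac[ok] - fr$reward_frac[ok])^2)
}

#' Choice dynamics around block transitions
#'
#' Aligns the instantaneous choice-fraction series of every qualifying block
#' transition (those with \code{|delta p_A| >= min_prob_change}) to the
#' transition trial, orients each so that the newly richer odor is positive,
#' and averages across transitions.
#'
#' @param logs a \code{trial_log} or list of them. Each log must carry block
#'   probabilities via \code{attr(log, "meta")$config} or be paired with
#'   \code{config}.
#' @param config the \code{task_config} the logs were generated under.
#' @param min_prob_change threshold on \code{|delta p_A|} for a "large"
#'   transition.
#' @param lags window of trial lags around the transition (0 = first trial of
#'   the new block).
#' @param window smoothing window for the instantaneous fractions.
#' @return data.frame with \code{lag}, \code{mean}, \code{se}, \code{n}; zero
#'   rows (with a warning) if no transition qualifies.
#' @export
transition_dynamics <- function(logs, config, min_prob_change = 0.4,
                                lags = -20:40, window = 10L) {
  logs <- as_log_list(logs)
  stopifnot(inherits(config, "task_config"))
  blocks <- config$blocks
  n_blocks <- nrow(blocks)
  if (n_blocks < 2L) {
    warning("no block transitions in config")
    return(data.frame(lag = integer(), mean = numeric(), se = numeric(),
                      n = integer()))
  }
  block_start <- cumsum(c(1L, blocks$n_trials))[seq_len(n_blocks)]
  curves <- list()
  for (log in logs) {
    fr <- instantaneous_fractions(log, window)
    for (b in 2:n_blocks) {
      dp <- blocks$p_A[b] - blocks$p_A[b - 1L]
      if (abs(dp) < min_prob_change) next
      t0 <- block_start[b]
      idx <- t0 + lags
      vals <- rep(NA_real_, length(lags))
      inb <- idx >= 1L & idx <= nrow(fr)
      vals[inb] <- fr$choice_frac[idx[inb]]
      # orient: positive = fraction of choices to the newly richer odor
      if (dp < 0) vals <- 1 - vals
      curves[[length(curves) + 1L]] <- vals
    }
  }
  if (!length(curves)) {
    warning("no transitions exceed min_prob_change = ", min_prob_change)
    return(data.frame(lag = integer(), mean = numeric(), se = numeric(),
                      n = integer()))
  }
  mat <- do.call(rbind, curves)
  data.frame(lag = lags,
             mean = colMeans(mat, na.rm = TRUE),
             se = apply(mat, 2L, function(v) {
               v <- v[!is.na(v)]
               if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
             }),
             n = colSums(!is.na(mat)))
}

#' Win-stay/lose-switch comparison table
#'
#' For every choice after the first, the WSLS heuristic predicts "stay" if
#' the previous choice was rewarded and "switch" otherwise. Returns the 2x2
#' joint probability table of predicted versus realized stay/switch and the
#' model agreement rate.
#'
#' @param logs a \code{trial_log} or list of them.
#' @return list with \code{table} (2x2, rows = predicted, cols = realized,
#'   sums to 1), \code{agreement}, and \code{n} transitions used.
#' @export
wsls_comparison <- function(logs) {
  logs <- as_log_list(logs)
  pred <- real <- character(0)
  for (log in logs) {
    ch <- choices(log)
    if (nrow(ch) < 2L) next
    prev_rew <- ch$rewarded[-nrow(ch)]
    stayed <- ch$odor_id[-1L] == ch$odor_id[-nrow(ch)]
    pred <- c(pred, ifelse(prev_rew, "stay", "switch"))
    real <- c(real, ifelse(stayed, "stay", "switch"))
  }
  if (!length(pred)) stop_validation("need at least 2 choices")
  lev <- c("stay", "switch")
  tab <- table(factor(pred, lev), factor(real, lev)) / length(pred)
  names(dimnames(tab)) <- c("predicted", "realized")
  list(table = tab,
       agreement = sum(diag(tab)),
       n = length(pred))
}

#' Choice probability conditional on a trailing history pattern
#'
#' Scans the choice sequences for exact occurrences of a trailing pattern of
#' (odor, rewarded) pairs and tabulates the empirical probability of the next
#' choice.
#'
#' @param logs a \code{trial_log} or list of them.
#' @param pattern data.frame with columns \code{odor_id} and \code{rewarded},
#'   one row per past trial, oldest first.
#' @return list with \code{p_next} (named probabilities for odors A and B;
#'   \code{NA} if the pattern never occurs) and \code{count} of occurrences.
#' @export
history_conditional_probs <- function(logs, pattern) {
  logs <- as_log_list(logs)
  pattern <- as.data.frame(pattern)
  k <- nrow(pattern)
  if (k < 1L) stop_validation("pattern must have length >= 1")
  nxt <- character(0)
  for (log in logs) {
    ch <- choices(log)
    n <- nrow(ch)
    if (n <= k) next
    for (t in seq_len(n - k)) {
      win <- ch[t:(t + k - 1L), ]
      if (all(win$odor_id == pattern$odor_id) &&
          all(win$rewarded == pattern$rewarded))
        nxt <- c(nxt, ch$odor_id[t + k])
    }
  }
  count <- length(nxt)
  p <- if (count) c(A = mean(nxt == "A"), B = mean(nxt == "B"))
       else c(A = NA_real_, B = NA_real_)
  list(p_next = p, count = count)
}
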