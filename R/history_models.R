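# Descriptive choice models: history logistic regression with shuffle
# controls, and the leaky-integrator value model with timescale estimation.

#' Build the history-regression design for one fly
#'
#' For every choice with a complete \code{n_back}-trial history, the response
#' is 1 if odor A was chosen, and for each lag \code{j = 1..n_back} there are
#' two regressors: a reward code (+1 reward obtained on A, -1 reward on B, 0
#' no reward) and a choice code (+1 A chosen, -1 B chosen).
#'
#' @param log a \code{trial_log} for a single fly.
#' @param n_back history depth in trials; 0 gives an intercept-only design.
#' @return list with \code{x} (matrix, columns \code{reward_lag1..},
#'   \code{choice_lag1..}), \code{y} (0/1 response), \code{trial_index}.
#' @export
build_history_design <- function(log, n_back = 15L) {
  ch <- choices(log)
  n_back <- check_count(n_back, "n_back", min = 0L)
  n <- nrow(ch)
  if (n_back >= n)
    stop_validation("n_back (", n_back, ") must be smaller than the number of choices (", n, ")")
  is_a <- ifelse(ch$odor_id == "A", 1, -1)
  rew_code <- is_a * ch$rewarded
  rows <- (n_back + 1L):n
  y <- as.numeric(ch$odor_id[rows] == "A")
  if (n_back == 0L) {
    x <- matrix(numeric(0), nrow = length(rows), ncol = 0L)
  } else {
    x <- matrix(NA_real_, length(rows), 2L * n_back,
                dimnames = list(NULL, c(paste0("reward_lag", seq_len(n_back)),
                                        paste0("choice_lag", seq_len(n_back)))))
    for (j in seq_len(n_back)) {
      x[, j] <- rew_code[rows - j]
      x[, n_back + j] <- is_a[rows - j]
    }
  }
  list(x = x, y = y, trial_index = ch$trial_index[rows], n_back = n_back)
}

#' Fit a history logistic regression
#'
#' Maximum-likelihood logistic fit with a tiny ridge penalty on all
#' coefficients except the bias (guards against perfect separation). Fit
#' quality is the percent deviance explained relative to the bias-only null
#' fitted on the same rows.
#'
#' @param design output of \code{\link{build_history_design}} (or any list
#'   with \code{x}, \code{y}).
#' @param l2 ridge penalty.
#' @return An object of class \code{history_fit}: \code{bias},
#'   \code{reward_coef}, \code{choice_coef}, \code{deviance},
#'   \code{null_deviance}, \code{deviance_explained} (percent),
#'   \code{separated} flag.
#' @export
fit_choice_regression <- function(design, l2 = 1e-4) {
  x <- design$x; y <- design$y
  if (length(unique(y)) < 2L)
    stop_validation("responses are all identical; nothing to fit")
  fit <- ridge_logistic(x, y, lambda = l2)
  dev_null <- null_deviance(y)
  coefs <- fit$coefficients[-1L]
  n_back <- design$n_back %||% (ncol(x) / 2L)
  structure(list(
    bias = unname(fit$coefficients[1L]),
    reward_coef = coefs[grep("^reward_lag", names(coefs))],
    choice_coef = coefs[grep("^choice_lag", names(coefs))],
    coefficients = coefs,
    deviance = fit$deviance,
    null_deviance = dev_null,
    deviance_explained = percent_deviance_explained(fit$deviance, dev_null),
    separated = fit$separated,
    n = length(y), n_back = n_back),
    class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat("History logistic fit:", x$n_back, "-trial history, n =", x$n, "\n",
      " deviance explained =", signif(x$deviance_explained, 4), "%\n")
  if (x$separated) cat("  (flag: near-separation, ridge-stabilized)\n")
  invisible(x)
}

#' Shuffle control for history-regression coefficients
#'
#' Permutes each fly's (choice, reward) trial sequence uniformly, rebuilds the
#' history design, and refits, yielding a null coefficient distribution that
#' destroys trial-to-trial dependence while preserving the marginal choice
#' bias. Reports a two-sided empirical p-value per coefficient.
#'
#' @param log a \code{trial_log} for a single fly.
#' @param n_back history depth.
#' @param n_shuffles number of permutations (>= 100).
#' @param seed integer seed.
#' @param l2 ridge penalty.
#' @return list with \code{observed} (the real \code{history_fit}),
#'   \code{null_coefs} (matrix, one row per shuffle), \code{p_values}.
#' @export
shuffle_control <- function(log, n_back = 15L, n_shuffles = 200L, seed = 1L,
                            l2 = 1e-4) {
  if (n_shuffles < 100L) stop_validation("n_shuffles must be >= 100")
  observed <- fit_choice_regression(build_history_design(log, n_back), l2)
  ch <- choices(log)
  set.seed(seed)
  null_coefs <- matrix(NA_real_, n_shuffles, length(observed$coefficients),
                       dimnames = list(NULL, names(observed$coefficients)))
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(nrow(ch))
    shuf <- ch
    shuf$odor_id <- ch$odor_id[perm]
    shuf$rewarded <- ch$rewarded[perm]
    shuf_log <- trial_log(data.frame(
      fly_id = shuf$fly_id, trial_index = seq_len(nrow(shuf)),
      block_index = shuf$block_index, encounter_index = 1L,
      odor_id = shuf$odor_id, accepted = TRUE, is_choice = TRUE,
      rewarded = shuf$rewarded, forced = FALSE))
    f <- tryCatch(fit_choice_regression(build_history_design(shuf_log, n_back), l2),
                  mbforage_validation_error = function(e) NULL)
    if (!is.null(f)) null_coefs[s, ] <- f$coefficients
  }
  null_coefs <- null_coefs[stats::complete.cases(null_coefs), , drop = FALSE]
  p <- vapply(seq_along(observed$coefficients), function(j) {
    obs <- observed$coefficients[j]
    nd <- null_coefs[, j]
    (1 + sum(abs(nd) >= abs(obs))) / (1 + length(nd))
  }, numeric(1))
  names(p) <- names(observed$coefficients)
  list(observed = observed, null_coefs = null_coefs, p_values = p)
}

#' Fit the leaky-integrator value model
#'
#' For each candidate timescale \code{tau}, per-option values are computed as
#' \code{V_o(t+1) = (1 - 1/tau) V_o(t) + (1/tau) R(t) 1[chosen = o]} (both
#' options decay every trial), and choices are modeled as
#' \code{P(A) = plogis(beta (V_A - V_B) + bias)} with \code{(beta, bias)}
#' maximized by logistic regression. The best timescale maximizes the profile
#' log-likelihood.
#'
#' @param log a \code{trial_log} for a single fly.
#' @param tau_grid candidate timescales (trials, >= 1).
#' @return An object of class \code{leaky_fit}: \code{tau}, \code{beta},
#'   \code{bias}, \code{profile} (data.frame tau, loglik), \code{degenerate}
#'   flag (single-odor logs).
#' @export
fit_leaky_integrator <- function(log, tau_grid = 1:30) {
  if (!length(tau_grid)) stop_validation("tau_grid must be non-empty")
  if (any(tau_grid < 1)) stop_validation("all tau must be >= 1")
  ch <- choices(log)
  y <- as.numeric(ch$odor_id == "A")
  degenerate <- length(unique(ch$odor_id)) < 2L
  if (degenerate)
    warning("log contains choices of a single odor; leaky fit is degenerate")
  n <- nrow(ch)
  profile <- data.frame(tau = tau_grid, loglik = NA_real_,
                        beta = NA_real_, bias = NA_real_)
  for (g in seq_along(tau_grid)) {
    tau <- tau_grid[g]
    v_a <- v_b <- 0
    dv <- numeric(n)
    for (t in seq_len(n)) {
      dv[t] <- v_a - v_b
      decay <- 1 - 1 / tau
      inc <- ch$rewarded[t] / tau
      v_a <- decay * v_a + if (ch$odor_id[t] == "A") inc else 0
      v_b <- decay * v_b + if (ch$odor_id[t] == "B") inc else 0
    }
    if (degenerate || stats::var(dv) == 0) {
      p <- mean(y)
      profile$loglik[g] <- -null_deviance(y) / 2
      profile$beta[g] <- 0
      profile$bias[g] <- stats::qlogis(min(max(p, 1e-12), 1 - 1e-12))
    } else {
      fit <- ridge_logistic(matrix(dv, ncol = 1,
                                   dimnames = list(NULL, "value_diff")),
                            y, lambda = 1e-6)
      profile$loglik[g] <- fit$loglik
      profile$beta[g] <- unname(fit$coefficients[2L])
      profile$bias[g] <- unname(fit$coefficients[1L])
    }
  }
  best <- which.max(profile$loglik)
  structure(list(tau = tau_grid[best], beta = profile$beta[best],
                 bias = profile$bias[best], profile = profile,
                 degenerate = degenerate),
            class = "leaky_fit")
}

#' @export
print.leaky_fit <- function(x, ...) {
  cat("Leaky-integrator fit: tau =", x$tau, "trials, beta =",
      signif(x$beta, 4), ", bias =", signif(x$bias, 4), "\n")
  invisible(x)
}
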