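# Inferring the plasticity rule from accept/reject behavior.
#
# Because the candidate rules are linear in their components and weights
# accumulate additively, the MBON drive at any encounter decomposes exactly
# into a weighted sum of four history regressors (constant, KC, DAN,
# KC x DAN product), each accumulated over all prior choices and projected
# onto the current odor's KC pattern. Logistic regression of encounter-level
# accept/reject on these regressors recovers the rule-term coefficients; the
# variants differ only in whether the KC and/or DAN factors are
# expectation-subtracted.

rule_variants <- c("noncov", "reward_exp", "sensory_exp", "both")

#' Build rule-component regressors from a trial log
#'
#' For the odor of each encounter, each term's regressor is the sum over all
#' prior choices of that term's value at the choice, weighted by the
#' (fractional) overlap between the chosen odor's KC pattern and the current
#' odor's pattern. The DAN factor is \code{R} or \code{R - E(R)} and the KC
#' factor \code{S} or \code{S - E(S)} according to \code{variant};
#' expectations are recomputed from the log itself with timescale \code{tau}
#' (initialized at 0), so the inference is self-contained given behavior.
#' KC activity uses the noiseless binary patterns (the analyst does not
#' observe sensory noise); overlap enters only through pattern dot products.
#'
#' @param log a \code{trial_log} (accumulators reset per fly).
#' @param variant rule variant, one of \code{"noncov"}, \code{"reward_exp"},
#'   \code{"sensory_exp"}, \code{"both"}.
#' @param tau expectation timescale in trials (both E(R) and E(S)).
#' @param overlap fractional KC overlap between the two odors' patterns.
#' @return An object of class \code{rule_regressors}: \code{x} (matrix with
#'   columns \code{const_term}, \code{kc_term}, \code{dan_term},
#'   \code{product_term}), \code{y} (1 = accept), plus per-row \code{fly_id},
#'   \code{trial_index}, \code{odor_id}.
#' @export
build_rule_regressors <- function(log, variant = "reward_exp", tau = 3.5,
                                  overlap = 0) {
  if (!variant %in% rule_variants)
    stop_validation("unknown rule variant: ", variant)
  check_probability(overlap, "overlap")
  if (tau < 1) stop_validation("tau must be >= 1")
  df <- as.data.frame(log)
  use_er <- rule_uses_reward_exp(variant)
  use_es <- rule_uses_sensory_exp(variant)
  odors <- c("A", "B")
  out <- vector("list", length(unique(df$fly_id)))
  fi <- 0L
  for (fly in unique(df$fly_id)) {
    sub <- df[df$fly_id == fly, ]
    sub <- sub[order(sub$trial_index, sub$encounter_index), ]
    n <- nrow(sub)
    x <- matrix(0, n, 4L, dimnames = list(NULL, c("const_term", "kc_term",
                                                  "dan_term", "product_term")))
    # running sums per target odor; dot(pattern_c, pattern_o)/n_active is 1
    # for the same odor and `overlap` otherwise
    n_choices <- 0
    kc_sum <- c(A = 0, B = 0)       # sum_c dot_frac(K(c), o)
    dan_sum <- 0                    # sum_c D(c)
    prod_sum <- c(A = 0, B = 0)     # sum_c D(c) * dot_frac(K(c), o)
    e_r <- 0
    e_dot <- c(A = 0, B = 0)        # dot(E(S), pattern_o)/n_active
    for (t in seq_len(n)) {
      o <- sub$odor_id[t]
      x[t, ] <- c(n_choices, kc_sum[[o]], dan_sum, prod_sum[[o]])
      if (sub$is_choice[t]) {
        r <- as.numeric(sub$rewarded[t])
        d_val <- if (use_er) r - e_r else r
        dot_frac <- ifelse(odors == o, 1, overlap)
        k_dot <- if (use_es) dot_frac - e_dot else dot_frac
        n_choices <- n_choices + 1
        kc_sum <- kc_sum + k_dot
        dan_sum <- dan_sum + d_val
        prod_sum <- prod_sum + d_val * k_dot
        e_r <- (1 - 1 / tau) * e_r + r / tau
        e_dot <- (1 - 1 / tau) * e_dot + dot_frac / tau
      }
    }
    fi <- fi + 1L
    out[[fi]] <- list(x = x, y = as.numeric(sub$accepted),
                      fly_id = sub$fly_id, trial_index = sub$trial_index,
                      odor_id = sub$odor_id)
  }
  structure(list(x = do.call(rbind, lapply(out, `[[`, "x")),
                 y = unlist(lapply(out, `[[`, "y")),
                 fly_id = unlist(lapply(out, `[[`, "fly_id")),
                 trial_index = unlist(lapply(out, `[[`, "trial_index")),
                 odor_id = unlist(lapply(out, `[[`, "odor_id")),
                 variant = variant, tau = tau, overlap = overlap),
            class = "rule_regressors")
}

#' Fit the four-term rule model to accept/reject behavior
#'
#' Logistic regression of encounter-level accept/reject on the four rule
#' regressors plus a behavioral bias, with a tiny ridge penalty; fit quality
#' is percent deviance explained over the bias-only null.
#'
#' @param regs a \code{rule_regressors} object.
#' @param l2 ridge penalty.
#' @return An object of class \code{rule_fit}: \code{coefficients} (the four
#'   terms), \code{bias}, \code{deviance}, \code{null_deviance},
#'   \code{deviance_explained} (percent), \code{variant}, \code{n}.
#' @export
fit_rule_model <- function(regs, l2 = 1e-4) {
  stopifnot(inherits(regs, "rule_regressors"))
  y <- regs$y
  if (length(y) < 20L)
    stop_validation("need at least 20 encounter rows, got ", length(y))
  if (length(unique(y)) < 2L)
    stop_validation("log is all-", if (y[1] == 1) "accept" else "reject",
                    ": accept/reject regression is unidentifiable")
  fit <- ridge_logistic(regs$x, y, lambda = l2)
  dev_null <- null_deviance(y)
  structure(list(coefficients = fit$coefficients[-1L],
                 bias = unname(fit$coefficients[1L]),
                 deviance = fit$deviance,
                 null_deviance = dev_null,
                 deviance_explained = percent_deviance_explained(fit$deviance,
                                                                 dev_null),
                 separated = fit$separated,
                 variant = regs$variant, n = length(y)),
            class = "rule_fit")
}

#' @export
print.rule_fit <- function(x, ...) {
  cat("Rule fit (", x$variant, "): deviance explained =",
      signif(x$deviance_explained, 4), "% over", x$n, "encounters\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Compare rule variants by deviance explained
#'
#' Fits all four rule variants to the same log and reports each covariance
#' variant's percent deviance explained minus the noncovariance baseline's.
#' Positive values mean the covariance variant predicts the accept/reject
#' sequence better.
#'
#' @param log a \code{trial_log}.
#' @param tau expectation timescale used in the regressors.
#' @param overlap fractional KC overlap.
#' @param l2 ridge penalty.
#' @return data.frame with \code{variant}, \code{deviance_explained},
#'   \code{delta_vs_noncov}; attribute \code{fits} holds the four
#'   \code{rule_fit} objects.
#' @export
compare_variants <- function(log, tau = 3.5, overlap = 0, l2 = 1e-4) {
  fits <- lapply(rule_variants, function(v)
    fit_rule_model(build_rule_regressors(log, v, tau, overlap), l2))
  names(fits) <- rule_variants
  de <- vapply(fits, `[[`, numeric(1), "deviance_explained")
  out <- data.frame(variant = rule_variants,
                    deviance_explained = unname(de),
                    delta_vs_noncov = unname(de - de[["noncov"]]))
  attr(out, "fits") <- fits
  out
}

#' Pairwise correlations of rule coefficients across fits
#'
#' @param fits list of \code{rule_fit} objects (>= 3).
#' @return Correlation matrix of the four term coefficients across fits.
#' @export
coefficient_correlations <- function(fits) {
  if (length(fits) < 3L) stop_validation("need at least 3 fits")
  mat <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  stats::cor(mat)
}

#' Regress fit advantage and product coefficient on undermatching
#'
#' For matched populations of logs and per-fly fit summaries, fits OLS lines
#' of (i) the covariance-vs-noncovariance deviance-explained difference and
#' (ii) the product-term coefficient against each fly's undermatching MSE.
#' In pooled populations containing both covariance- and
#' noncovariance-driven agents, stronger undermatching goes with a smaller
#' covariance advantage (negative slope).
#'
#' @param logs list of \code{trial_log}, one per fly.
#' @param delta_deviance numeric, covariance-minus-noncov deviance explained
#'   per fly.
#' @param product_coef numeric, product-term coefficient per fly.
#' @param window smoothing window for the undermatching series.
#' @return list with \code{delta_fit} and \code{product_fit} (each
#'   \code{slope}, \code{intercept}; \code{NA} with \code{degenerate = TRUE}
#'   if undermatching is constant) and the per-fly \code{data}.
#' @export
matching_vs_fit_regression <- function(logs, delta_deviance, product_coef,
                                       window = 10L) {
  logs <- as_log_list(logs)
  if (length(logs) < 3L) stop_validation("need at least 3 flies")
  if (length(delta_deviance) != length(logs) ||
      length(product_coef) != length(logs))
    stop_validation("logs and fit summaries must be matched per fly")
  mse <- vapply(logs, undermatching_mse, numeric(1), window = window)
  ols <- function(yv) {
    if (stats::var(mse) == 0)
      return(list(slope = NA_real_, intercept = NA_real_, degenerate = TRUE))
    cf <- stats::coef(stats::lm(yv ~ mse))
    list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
         degenerate = FALSE)
  }
  list(delta_fit = ols(delta_deviance),
       product_fit = ols(product_coef),
       data = data.frame(undermatching_mse = mse,
                         delta_deviance = delta_deviance,
                         product_coef = product_coef))
}
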