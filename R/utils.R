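# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("mbforage_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_probability <- function(p, what = "probability") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_validation(what, " must be a single number in [0, 1], got ",
                    deparse(substitute(p)), " = ", format(p))
  invisible(p)
}

check_count <- function(n, what = "count", min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min || n != round(n))
    stop_validation(what, " must be an integer >= ", min)
  invisible(as.integer(n))
}

# Ridge-penalized logistic regression by iteratively reweighted least squares.
# Penalty is lambda * sum(beta^2) on all coefficients except the intercept
# (column named "(Intercept)" must be first when intercept = TRUE). Returns
# coefficients, the unpenalized residual deviance, and convergence info.
#
# A fixed, tiny absolute penalty keeps fits finite under perfect separation
# without materially biasing large-n estimates.
ridge_logistic <- function(x, y, lambda = 1e-4, intercept = TRUE,
                           max_iter = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) stop("NA values in design or response")
  if (length(y) != nrow(x)) stop("design/response dimension mismatch")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (intercept) x <- cbind("(Intercept)" = 1, x)
  p <- ncol(x)
  pen <- rep(lambda, p)
  if (intercept) pen[1L] <- 0
  beta <- numeric(p)
  dev_old <- Inf
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(x, x * w) + diag(2 * pen, p)
    beta_new <- tryCatch(solve(xtwx, crossprod(x, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) { separated <- TRUE; break }
    beta_new <- drop(beta_new)
    dev <- bernoulli_deviance(y, plogis(pmin(pmax(drop(x %*% beta_new), -30), 30)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { beta <- beta_new; break }
    beta <- beta_new
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(x %*% beta), -30), 30)
  mu <- plogis(eta)
  if (max(abs(beta)) > 25) separated <- TRUE
  list(coefficients = stats::setNames(beta, colnames(x)),
       fitted = mu,
       deviance = bernoulli_deviance(y, mu),
       loglik = -bernoulli_deviance(y, mu) / 2,
       separated = separated,
       iterations = it)
}

bernoulli_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Deviance of the bias-only (intercept) model on the same responses.
null_deviance <- function(y) {
  p <- mean(y)
  bernoulli_deviance(y, rep(p, length(y)))
}

percent_deviance_explained <- function(dev_model, dev_null) {
  if (dev_null <= 0) return(0)
  100 * (1 - dev_model / dev_null)
}
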