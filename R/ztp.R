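# Zero-truncated Poisson regression for non-zero contact counts.
#
# Model: Y_ij | Y_ij > 0, log mu_ij = b0 + b1*FL + b2*GC + b3*MS + b4*IP.
# The score of the ZTP log-likelihood is X'(y - E[Y|Y>0]) with truncated
# mean m(mu) = mu / (1 - exp(-mu)), and the observed Hessian equals minus
# X' diag(mu * m'(mu)) X = minus the Fisher information, so Newton-Raphson
# and Fisher scoring coincide.

ztp_mean <- function(mu) mu / (-expm1(-mu))

# d/dmu of the truncated mean; equals Var(Y|Y>0)/mu * ... kept direct.
ztp_mean_deriv <- function(mu) {
  e <- exp(-mu)
  (1 - e - mu * e) / (-expm1(-mu))^2
}

design_matrix <- function(pairs) {
  cbind(1, pairs$fl, pairs$gc, pairs$ms, pairs$ip)
}

#' Zero-truncated Poisson log-likelihood
#'
#' Evaluates the ZTP log-likelihood
#' `sum(y*log(mu) - mu - log(y!) - log(1 - exp(-mu)))` with
#' `mu = exp(beta . x)` over a set of bin pairs.
#'
#' @param beta Numeric 5-vector: intercept and FL, GC, MS, IP slopes.
#' @param pairs Bin-pair table with columns `count, fl, gc, ms, ip`; all
#'   counts must be >= 1.
#' @return The log-likelihood (a single number).
#' @export
ztp_loglik <- function(beta, pairs) {
  stopifnot(length(beta) == 5L)
  if (any(pairs$count < 1)) stop("ZTP likelihood requires counts >= 1")
  eta <- as.vector(design_matrix(pairs) %*% beta)
  if (any(eta > 700)) stop("divergent fit: linear predictor exceeds 700 (mu overflow)")
  mu <- exp(eta)
  y <- pairs$count
  sum(y * eta - mu - lgamma(y + 1) - log(-expm1(-mu)))
}

#' Fit the zero-truncated Poisson regression
#'
#' Maximum-likelihood fit of the ZTP model for one (chromosome, pair
#' class) contact file, by Newton-Raphson with analytic gradient and
#' Hessian, initialized from the ordinary Poisson log-linear fit.
#' Separate fits for the AND and XOR sets absorb the double vs. single
#' ChIP enrichment of the two classes.
#'
#' @param pairs Bin-pair table (all counts >= 1), at least 50 rows.
#' @param tol Convergence tolerance on the gradient infinity-norm.
#' @param max_iter Iteration cap.
#' @return An object of class `ztp_fit` with elements `beta` (named
#'   5-vector), `se` (observed-information standard errors),
#'   `converged`, `n_obs`, `loglik`, `aic`, `bic`,
#'   `iterations`, and the `pair_class`/`chrom` labels when present.
#' @export
fit_ztp <- function(pairs, tol = 1e-8, max_iter = 100L) {
  if (nrow(pairs) < 50L)
    stop("refusing to fit ZTP on ", nrow(pairs),
         " records (< 50); too few bin pairs for a stable fit")
  X <- design_matrix(pairs)
  y <- as.numeric(pairs$count)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    cn <- c("intercept", "fl", "gc", "ms", "ip")
    dropped <- cn[setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("rank-deficient design matrix; collinear covariate(s): ",
         paste(dropped, collapse = ", "))
  }

  beta <- stats::glm.fit(X, y, family = stats::poisson())$coefficients
  converged <- FALSE
  grad_norm <- Inf
  # the gradient sums n terms of order y, so its attainable floor scales
  # with the total count; keep the absolute tol where it is attainable
  grad_tol <- max(tol, 1e-12 * sum(y))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    if (any(eta > 700)) stop("divergent fit: linear predictor exceeds 700")
    mu <- exp(eta)
    grad <- crossprod(X, y - ztp_mean(mu))
    grad_norm <- max(abs(grad))
    if (grad_norm < grad_tol) { converged <- TRUE; break }
    w <- mu * ztp_mean_deriv(mu)
    step <- solve(crossprod(X, X * w), grad)
    # halve the step while it worsens the likelihood (rare, guards early iterations)
    ll_old <- ztp_loglik(beta, pairs)
    lambda <- 1
    repeat {
      cand <- beta + lambda * as.vector(step)
      ll_new <- tryCatch(ztp_loglik(cand, pairs), error = function(e) -Inf)
      if (ll_new >= ll_old - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * as.vector(step)
  }
  if (!converged)
    stop("ZTP fit did not converge after ", max_iter,
         " iterations (gradient norm ", format(grad_norm), "); last beta: ",
         paste(signif(beta, 6), collapse = ", "))
  ll <- ztp_loglik(beta, pairs)
  n <- nrow(pairs)
  mu <- exp(as.vector(X %*% beta))
  info <- crossprod(X, X * (mu * ztp_mean_deriv(mu)))
  se <- sqrt(diag(solve(info)))
  structure(list(
    beta = setNames(as.vector(beta), c("intercept", "fl", "gc", "ms", "ip")),
    se = setNames(se, c("intercept", "fl", "gc", "ms", "ip")),
    converged = TRUE,
    n_obs = n,
    loglik = ll,
    aic = 2 * 5 - 2 * ll,
    bic = 5 * log(n) - 2 * ll,
    iterations = it,
    pair_class = if (!is.null(pairs$class)) unique(pairs$class) else NA_character_,
    chrom = if (!is.null(pairs$chrom)) paste(unique(pairs$chrom), collapse = ",") else NA_character_
  ), class = "ztp_fit")
}

#' @export
print.ztp_fit <- function(x, ...) {
  cat("Zero-truncated Poisson fit (", x$pair_class, ", ", x$chrom, ")\n", sep = "")
  print(signif(x$beta, 5))
  cat("n =", x$n_obs, " logLik =", signif(x$loglik, 8),
      " AIC =", signif(x$aic, 8), " BIC =", signif(x$bic, 8), "\n")
  invisible(x)
}

#' Fitted values under a ZTP fit
#'
#' Returns, for each bin pair, either the zero-truncated mean
#' `E[Y | Y > 0] = mu / (1 - exp(-mu))` (the default — the expectation of
#' an observed, necessarily non-zero count) or the raw Poisson mean `mu`.
#'
#' @param fit A `ztp_fit`.
#' @param pairs Bin-pair table with covariate columns.
#' @param type `"truncated"` (default) or `"mean"`.
#' @return A positive numeric vector, one fitted value per pair.
#' @export
predict_fitted <- function(fit, pairs, type = c("truncated", "mean")) {
  type <- match.arg(type)
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  mu <- exp(as.vector(design_matrix(pairs) %*% fit$beta))
  if (type == "truncated") ztp_mean(mu) else mu
}

#' Draw zero-truncated Poisson variates
#'
#' Exact inverse-CDF sampler: `U ~ Uniform(P(Y=0), 1)` mapped through the
#' Poisson quantile function, so every draw is >= 1.
#'
#' @param n Number of draws.
#' @param mu Poisson mean(s), recycled to length `n`.
#' @return Integer vector of positive counts.
#' @export
rztp <- function(n, mu) {
  mu <- rep_len(mu, n)
  p0 <- exp(-mu)
  u <- p0 + runif(n) * (1 - p0)
  as.integer(qpois(u, mu))
}
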