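# Joint negative log-likelihood and analytic gradient for the four families.
# Parameter vector layout: beta (ncol(X)), then gamma (ncol(Z), ZI families),
# then log(k) (NB families). k is log-transformed so the problem is smooth
# and unconstrained.

unpack_theta <- function(theta, pX, pZ, family) {
  beta <- theta[seq_len(pX)]
  gamma <- if (family %in% c("zip", "zinb")) theta[pX + seq_len(pZ)]
  logk <- if (family %in% c("nb", "zinb")) theta[length(theta)]
  list(beta = beta, gamma = gamma, logk = logk)
}

count_loglik_vec <- function(theta, X, Z, y, family) {
  pr <- unpack_theta(theta, ncol(X), if (is.null(Z)) 0L else ncol(Z), family)
  lam <- exp(drop(X %*% pr$beta))
  if (any(!is.finite(lam)) || any(lam <= 0) ||
      (!is.null(pr$logk) &&
         (!is.finite(exp(pr$logk)) || exp(pr$logk) <= 0)))
    return(rep(-Inf, length(y)))
  p <- if (family %in% c("zip", "zinb"))
    pmin(stats::plogis(drop(Z %*% pr$gamma)), 1 - 1e-12)
  fam <- switch(family,
    poisson = count_family("poisson", lam),
    nb      = count_family("nb", lam, k = exp(pr$logk)),
    zip     = count_family("zip", lam, p_zero = p),
    zinb    = count_family("zinb", lam, k = exp(pr$logk), p_zero = p))
  count_pmf(y, fam, log = TRUE)
}

count_loglik <- function(theta, X, Z, y, family) {
  sum(count_loglik_vec(theta, X, Z, y, family))
}

count_score <- function(theta, X, Z, y, family) {
  pX <- ncol(X)
  pZ <- if (is.null(Z)) 0L else ncol(Z)
  pr <- unpack_theta(theta, pX, pZ, family)
  lam <- exp(drop(X %*% pr$beta))
  k <- if (!is.null(pr$logk)) exp(pr$logk)
  if (family == "poisson") {
    return(drop(crossprod(X, y - lam)))
  }
  if (family == "nb") {
    gb <- drop(crossprod(X, (y - lam) * k / (k + lam)))
    gk <- k * sum(digamma(y + k) - digamma(k) + log(k / (k + lam)) +
                    1 - (y + k) / (k + lam))
    return(c(gb, gk))
  }
  p <- stats::plogis(drop(Z %*% pr$gamma))
  i0 <- y == 0
  if (family == "zip") {
    e0 <- exp(-lam)
    den <- pmax(p + (1 - p) * e0, 1e-300)
    db <- ifelse(i0, -(1 - p) * e0 * lam / den, y - lam)
    dg <- ifelse(i0, p * (1 - p) * (1 - e0) / den, -p)
    return(c(drop(crossprod(X, db)), drop(crossprod(Z, dg))))
  }
  # zinb
  B <- exp(k * (log(k) - log(k + lam)))    # NB mass at 0
  den <- pmax(p + (1 - p) * B, 1e-300)
  db <- ifelse(i0, -(1 - p) * B * k * lam / ((k + lam) * den),
               (y - lam) * k / (k + lam))
  dg <- ifelse(i0, p * (1 - p) * (1 - B) / den, -p)
  dk <- ifelse(i0,
               (1 - p) * B * k * (log(k / (k + lam)) + lam / (k + lam)) / den,
               k * (digamma(y + k) - digamma(k) + log(k / (k + lam)) +
                      1 - (y + k) / (k + lam)))
  c(drop(crossprod(X, db)), drop(crossprod(Z, dg)), sum(dk))
}

start_values <- function(X, Z, y, family) {
  # Poisson working fit for beta; excess-zero logit for the gamma intercept;
  # method-of-moments start for k.
  pois <- stats::glm.fit(X, y, family = stats::poisson())
  beta0 <- pois$coefficients
  beta0[!is.finite(beta0)] <- 0
  out <- beta0
  lam0 <- pmax(exp(drop(X %*% beta0)), 1e-8)
  if (family %in% c("zip", "zinb")) {
    excess <- max(1e-3, mean(y == 0) - mean(exp(-lam0)))
    gamma0 <- c(stats::qlogis(excess), rep(0, ncol(Z) - 1L))
    out <- c(out, gamma0)
  }
  if (family %in% c("nb", "zinb")) {
    mbar <- mean(lam0)
    k0 <- mbar^2 / max(stats::var(y) - mbar, mbar / 10)
    out <- c(out, log(min(max(k0, 0.05), 1e4)))
  }
  out
}

#' Fit a count regression model by maximum likelihood
#'
#' Fits Poisson, NB, ZIP or ZINB regression with a log link for the
#' count-component mean, `log(lambda_i) = X_i' beta`, and (for the
#' zero-inflated families) a logit link for the structural-zero probability,
#' `logit(p_i) = Z_i' gamma`. The NB shape `k` is estimated on the log scale.
#' Optimization is quasi-Newton (BFGS) on the joint parameter vector with
#' analytic gradients; standard errors come from the inverse observed
#' information (numerical Hessian at the optimum).
#'
#' @param formula model formula for the count part, e.g. `y ~ x1 + x2`.
#' @param data data frame containing the response and covariates.
#' @param family one of `"poisson"`, `"nb"`, `"zip"`, `"zinb"`.
#' @param zero_formula one-sided formula for the zero part (ZI families
#'   only); default `~ 1`, an intercept-only structural-zero probability.
#' @param control list passed to [stats::optim()]'s `control` (the defaults
#'   set `maxit = 500` and a tight `reltol`).
#' @return an object of class `"count_fit"`: a list with components `beta`,
#'   `gamma`, `k_hat`, `loglik`, `n_params`, `se`, `vcov`, `converged`,
#'   `fitted_family` (a [count_family()] with fitted per-observation
#'   parameters), `mu_hat` (fitted marginal means `(1 - p_i) * lambda_i`),
#'   plus the design matrices and model frame needed for refitting and
#'   diagnostics.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(200, -1, 1))
#' d$y <- rpois(200, exp(0.5 + d$x))
#' fit <- fit_count_model(y ~ x, d, family = "poisson")
#' coef(fit)
#' AIC(fit)
#' @export
fit_count_model <- function(formula, data, family = c("poisson", "nb",
                                                      "zip", "zinb"),
                            zero_formula = ~1, control = list()) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != floor(y)))
    stop("response must be a non-negative integer count", call. = FALSE)
  y <- as.numeric(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X))
    stop("count-part design matrix is rank deficient", call. = FALSE)
  Z <- NULL
  if (family %in% c("zip", "zinb")) {
    Z <- stats::model.matrix(zero_formula, data = data)
    if (nrow(Z) != nrow(X))
      stop("zero-part covariates must have the same rows as the count part",
           call. = FALSE)
    if (qr(Z)$rank < ncol(Z))
      stop("zero-part design matrix is rank deficient", call. = FALSE)
  }
  if (family %in% c("nb", "zinb") && all(y == 0))
    stop("all-zero response: NB shape is not identifiable", call. = FALSE)
  fit <- fit_count_mle(X, Z, y, family, control)
  fit$call <- match.call()
  fit$formula <- formula
  fit$zero_formula <- if (!is.null(Z)) zero_formula
  fit$model <- mf
  fit$data <- data
  fit
}

# Core MLE on prepared design matrices; also the refitting entry point used
# by the simulated-envelope procedure.
fit_count_mle <- function(X, Z, y, family, control = list(),
                          start = NULL) {
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12), control)
  if (is.null(start)) start <- start_values(X, Z, y, family)
  # out-of-range steps (overflowing exp) get a large finite penalty so the
  # BFGS line search backtracks instead of erroring
  negll <- function(th) {
    v <- -count_loglik(th, X, Z, y, family)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(th) {
    g <- -count_score(th, X, Z, y, family)
    g[!is.finite(g)] <- 0
    g
  }
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = ctrl, hessian = TRUE)
  theta <- opt$par
  ll <- -opt$value
  g <- count_score(theta, X, Z, y, family)
  converged <- opt$convergence == 0L &&
    max(abs(g)) < 1e-3 * (1 + abs(ll))
  se <- rep(NA_real_, length(theta))
  vc <- matrix(NA_real_, length(theta), length(theta))
  ev <- eigen(opt$hessian, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev > 0)) {
    vc <- solve(opt$hessian)
    se <- sqrt(pmax(diag(vc), 0))
  }
  pX <- ncol(X)
  pZ <- if (is.null(Z)) 0L else ncol(Z)
  pr <- unpack_theta(theta, pX, pZ, family)
  lam <- exp(drop(X %*% pr$beta))
  p <- if (!is.null(Z)) stats::plogis(drop(Z %*% pr$gamma))
  k <- if (!is.null(pr$logk)) unname(exp(pr$logk))
  fitted_family <- switch(family,
    poisson = count_family("poisson", lam),
    nb      = count_family("nb", lam, k = k),
    zip     = count_family("zip", lam, p_zero = pmin(p, 1 - 1e-12)),
    zinb    = count_family("zinb", lam, k = k,
                           p_zero = pmin(p, 1 - 1e-12)))
  mv <- count_mean_var(fitted_family)
  nm <- colnames(X)
  if (!is.null(Z)) nm <- c(nm, paste0("zero_", colnames(Z)))
  if (!is.null(k)) nm <- c(nm, "log(k)")
  names(theta) <- names(se) <- nm
  dimnames(vc) <- list(nm, nm)
  structure(list(
    family = family,
    beta = stats::setNames(pr$beta, colnames(X)),
    gamma = if (!is.null(Z)) stats::setNames(pr$gamma, colnames(Z)),
    k_hat = k,
    theta = theta,
    loglik = ll,
    n_params = length(theta),
    n = length(y),
    se = se,
    vcov = vc,
    converged = converged,
    max_grad = max(abs(g)),
    fitted_family = fitted_family,
    mu_hat = mv$mean,
    y = y, X = X, Z = Z
  ), class = "count_fit")
}

# Refit the same model to a new response (same designs, warm start).
refit_response <- function(fit, ynew) {
  fit_count_mle(fit$X, fit$Z, as.numeric(ynew), fit$family,
                start = fit$theta)
}

#' @export
print.count_fit <- function(x, ...) {
  cat("Count regression fit (", x$family, "), n = ", x$n, "\n", sep = "")
  cat("log-likelihood:", format(x$loglik, digits = 7),
      " AIC:", format(aic(x), digits = 7), "\n")
  cat("count part (log link):\n")
  print(signif(x$beta, 4))
  if (!is.null(x$gamma)) {
    cat("zero part (logit link):\n")
    print(signif(x$gamma, 4))
  }
  if (!is.null(x$k_hat)) cat("shape k:", signif(x$k_hat, 4), "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.count_fit <- function(object, ...) {
  est <- object$theta
  se <- object$se
  zval <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.count_fit"
  out
}

#' @export
print.summary.count_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (zero part prefixed 'zero_', k on log scale):\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.count_fit <- function(object, ...) object$theta

#' @export
vcov.count_fit <- function(object, ...) object$vcov

#' @export
logLik.count_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.count_fit <- function(object, ...) object$n

#' @export
fitted.count_fit <- function(object, ...) object$mu_hat

#' Akaike information criterion of a count model fit
#'
#' `2 * n_params - 2 * loglik`, counting `beta`, `gamma` and `k` (when
#' estimated) as parameters. Errors on an unconverged fit; `stats::AIC()`
#' also works via the `logLik` method but performs no convergence check.
#'
#' @param fit a [fit_count_model()] result.
#' @return the AIC (smaller is better).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  if (!fit$converged)
    stop("AIC requested for an unconverged fit", call. = FALSE)
  2 * fit$n_params - 2 * fit$loglik
}

#' Per-observation saturated log-likelihood
#'
#' The saturated model has one parameter per observation and attains the
#' maximal log-likelihood. For Poisson and ZIP the saturated model is
#' Poisson(`y_i`) evaluated at `y_i`; for NB and ZINB it is NB(`y_i`, `k`)
#' evaluated at `y_i` (with the fitted shape held fixed). The convention
#' `y*log(y) = 0` at `y = 0` makes the Poisson saturated log-likelihood
#' exactly 0 there.
#'
#' @param y non-negative integer response vector.
#' @param family one of `"poisson"`, `"nb"`, `"zip"`, `"zinb"`.
#' @param k NB shape (required for `"nb"`/`"zinb"`).
#' @return numeric vector of per-observation saturated log-likelihoods.
#' @export
loglik_saturated <- function(y, family = c("poisson", "nb", "zip", "zinb"),
                             k = NULL) {
  family <- match.arg(family)
  y <- check_counts(y)
  if (family %in% c("poisson", "zip")) {
    stats::dpois(y, y, log = TRUE)
  } else {
    if (is.null(k) || k <= 0)
      stop("NB-family saturated log-likelihood needs a positive 'k'",
           call. = FALSE)
    stats::dnbinom(y, size = k, mu = y, log = TRUE)
  }
}
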