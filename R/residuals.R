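new_resid_set <- function(values, rtype, standardized = FALSE,
                          seed = NULL, u = NULL, pit = NULL, family = NULL) {
  structure(as.numeric(values), rtype = rtype, standardized = standardized,
            seed = seed, u = u, pit = pit, family = family,
            class = "count_resid")
}

#' @export
print.count_resid <- function(x, ...) {
  cat("<count_resid> type =", attr(x, "rtype"),
      if (isTRUE(attr(x, "standardized"))) "(standardized)",
      " n =", length(x), "\n")
  print(summary(as.numeric(x)))
  invisible(x)
}

check_fit <- function(fit) {
  if (!inherits(fit, "count_fit")) stop("need a 'count_fit' object",
                                        call. = FALSE)
  if (!fit$converged)
    stop("residuals requested for an unconverged fit", call. = FALSE)
  invisible(fit)
}

#' Pearson residuals for a count model fit
#'
#' The raw residual scaled by the fitted standard deviation,
#' `(y - mu_hat) / sqrt(V_hat(y))`, with the family-specific variance:
#' Poisson `lambda`; NB `lambda + lambda^2/k`; ZIP
#' `(1-p) * lambda * (1 + p*lambda)`; ZINB
#' `(1-p) * (lambda + lambda^2/k) + lambda^2 * (p^2 + p)` (the conventional
#' printed form for this residual, which differs from the exact ZINB
#' variance in its `p`-quadratic term).
#'
#' @param fit a converged [fit_count_model()] result.
#' @return a `"count_resid"` vector (`rtype = "pearson"`).
#' @export
pearson_resid <- function(fit) {
  check_fit(fit)
  fam <- fit$fitted_family
  lam <- fam$lambda
  v <- switch(fit$family,
    poisson = lam,
    nb      = lam + lam^2 / fam$k,
    zip     = (1 - fam$p_zero) * lam * (1 + fam$p_zero * lam),
    zinb    = (1 - fam$p_zero) * (lam + lam^2 / fam$k) +
              lam^2 * (fam$p_zero^2 + fam$p_zero))
  if (any(v <= 0)) stop("zero fitted variance", call. = FALSE)
  new_resid_set((fit$y - fit$mu_hat) / sqrt(v), "pearson",
                family = fit$family)
}

#' Deviance residuals for a count model fit
#'
#' Signed square roots of the per-observation deviance contributions,
#' `sign(y - mu_hat) * sqrt(2 * (l_sat - l_fit))`, where the saturated
#' log-likelihood follows [loglik_saturated()] (Poisson(`y_i`) for Poisson
#' and ZIP; NB(`y_i`, `k_hat`) for NB and ZINB). A deviance contribution
#' below `-1e-10` signals an inconsistent saturated model and raises an
#' error; tiny negative values from floating point are clamped to zero.
#'
#' @param fit a converged [fit_count_model()] result.
#' @return a `"count_resid"` vector (`rtype = "deviance"`).
#' @export
deviance_resid <- function(fit) {
  check_fit(fit)
  l_fit <- count_pmf(fit$y, fit$fitted_family, log = TRUE)
  l_sat <- loglik_saturated(fit$y, fit$family, k = fit$k_hat)
  d <- 2 * (l_sat - l_fit)
  if (any(d < -1e-10))
    stop("negative deviance contribution: saturated model inconsistent",
         call. = FALSE)
  d <- pmax(d, 0)
  new_resid_set(sign(fit$y - fit$mu_hat) * sqrt(d), "deviance",
                family = fit$family)
}

# Shared randomized/middle-point quantile residual core: F*(y) =
# F(y-) + u * p(y), z = qnorm(F*). F* is clipped away from {0, 1} so a
# catastrophic misfit still yields finite residuals.
quantile_resid_core <- function(fit, u, rtype, seed = NULL) {
  fam <- fit$fitted_family
  pit <- count_cdf_lower(fit$y, fam) + u * count_pmf(fit$y, fam)
  pit <- pmin(pmax(pit, 1e-16), 1 - 1e-16)
  new_resid_set(stats::qnorm(pit), rtype, seed = seed, u = u, pit = pit,
                family = fit$family)
}

#' Randomized quantile residuals (RQR)
#'
#' For each observation the fitted discrete CDF gap at `y_i` is filled with
#' a uniform draw, `F* = F(y_i -) + u_i * p(y_i)` with
#' `u_i ~ Uniform(0, 1)`, and the residual is the standard normal quantile
#' `qnorm(F*)`. Under the true model the randomized probability integral
#' transform `F*` is exactly Uniform(0, 1), so RQRs are exactly standard
#' normal; with estimated parameters they are approximately so. By default
#' the residuals are standardized to mean 0 and unit sample variance
#' (Klar-Meintanis standardization) as used by the Shapiro-Wilk
#' goodness-of-fit test.
#'
#' @param fit a converged [fit_count_model()] result.
#' @param seed optional integer; when supplied the uniform draws are
#'   generated under this seed (the caller's RNG state is restored), making
#'   the residuals reproducible.
#' @param standardize logical; apply [standardize_residuals()]?
#' @return a `"count_resid"` vector (`rtype = "rqr"`) with attributes `u`
#'   (the uniform draws) and `pit` (the randomized PIT values).
#' @export
rqr <- function(fit, seed = NULL, standardize = TRUE) {
  check_fit(fit)
  u <- if (is.null(seed)) {
    stats::runif(fit$n)
  } else {
    with_seed(seed, stats::runif(fit$n))
  }
  res <- quantile_resid_core(fit, u, "rqr", seed = seed)
  if (standardize) standardize_residuals(res) else res
}

#' Middle-point quantile residuals (MQR)
#'
#' The quantile residual with the uniform draw fixed at 0.5: deterministic,
#' but non-normal for discrete data (values cluster on curves indexed by
#' the distinct response values).
#'
#' @param fit a converged [fit_count_model()] result.
#' @return a `"count_resid"` vector (`rtype = "mqr"`).
#' @export
mqr <- function(fit) {
  check_fit(fit)
  quantile_resid_core(fit, rep(0.5, fit$n), "mqr")
}

#' Standardize a residual vector to mean 0, sample variance 1
#'
#' `(x - mean(x)) / sd(x)` with the `n - 1` variance denominator.
#' Idempotent; errors on constant input.
#'
#' @param res a `"count_resid"` vector or plain numeric vector, `n >= 2`.
#' @return the standardized vector, with `standardized = TRUE` when the
#'   input is a `"count_resid"`.
#' @export
standardize_residuals <- function(res) {
  x <- as.numeric(res)
  if (length(x) < 2L) stop("need at least two residuals", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant residual vector", call. = FALSE)
  z <- (x - mean(x)) / s
  if (inherits(res, "count_resid")) {
    out <- res
    out[] <- z
    attr(out, "standardized") <- TRUE
    out
  } else z
}

#' Extract residuals from a count model fit
#'
#' Dispatches to [rqr()], [mqr()], [pearson_resid()] or [deviance_resid()].
#'
#' @param object a converged [fit_count_model()] result.
#' @param type residual type.
#' @param seed,standardize passed to [rqr()] (ignored otherwise).
#' @param ... unused.
#' @return a `"count_resid"` vector.
#' @export
residuals.count_fit <- function(object, type = c("rqr", "pearson",
                                                 "deviance", "mqr"),
                                seed = NULL, standardize = TRUE, ...) {
  type <- match.arg(type)
  switch(type,
    rqr = rqr(object, seed = seed, standardize = standardize),
    pearson = pearson_resid(object),
    deviance = deviance_resid(object),
    mqr = mqr(object))
}

# Evaluate 'expr' under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
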