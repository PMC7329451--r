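#' Shapiro-Wilk goodness-of-fit test on residuals
#'
#' Applies the Shapiro-Wilk normality test to a residual vector, treating
#' residual normality as the goodness-of-fit null: H0 "the model fits the
#' data well" vs Ha "the model does not fit the data well". Valid for
#' 3 <= n <= 5000 (the SW implementation's range); larger samples must be
#' subsampled by the caller.
#'
#' @param res a `"count_resid"` vector (or plain numeric vector).
#' @return a list of class `"gof_report"` with `sw_pvalue`, `sw_statistic`,
#'   `rtype`, `moments` (see [moments_summary()]) and `n`.
#' @export
sw_gof <- function(res) {
  x <- as.numeric(res)
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000; subsample larger vectors",
         call. = FALSE)
  if (stats::sd(x) == 0) stop("constant residuals", call. = FALSE)
  sw <- stats::shapiro.test(x)
  structure(list(sw_pvalue = unname(sw$p.value),
                 sw_statistic = unname(sw$statistic),
                 rtype = attr(res, "rtype"),
                 moments = moments_summary(res),
                 n = n),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat("Goodness-of-fit (Shapiro-Wilk on residuals",
      if (!is.null(x$rtype)) paste0("[", x$rtype, "]"), "), n =", x$n, "\n")
  if (!is.null(x$sw_pvalue))
    cat("  SW p-value:", format.pval(x$sw_pvalue, digits = 4), "\n")
  if (!is.null(x$mean_pvalue)) {
    cat("  replicates:", length(x$replicate_pvalues),
        " mean p:", signif(x$mean_pvalue, 4),
        " prop > alpha:", signif(x$prop_above_alpha, 4), "\n")
  }
  if (!is.null(x$moments))
    cat("  moments (mean, var, skew, ex.kurt):",
        paste(signif(unlist(x$moments), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Replicated-RQR Shapiro-Wilk summary
#'
#' Draws `R` independent standardized RQR realizations from a fit, SW-tests
#' each, and summarizes the p-values. Because RQRs are randomized, a single
#' p-value can mislead; the spread of replicated p-values shows how much of
#' a rejection (or non-rejection) is due to the randomization itself. No
#' significance is attached to the mean p-value, whose null distribution is
#' not a solved problem.
#'
#' @param fit a converged [fit_count_model()] result with `n <= 5000`.
#' @param R number of RQR replicates (>= 1).
#' @param alpha level used for the proportion-above summary.
#' @param seed optional master seed controlling all `R` draws.
#' @return a `"gof_report"` list with `replicate_pvalues`, `mean_pvalue`,
#'   `prop_above_alpha`, `alpha`, `moments` (of the last replicate), `n`.
#' @export
replicated_sw <- function(fit, R = 1000L, alpha = 0.05, seed = NULL) {
  check_fit(fit)
  stopifnot(R >= 1L, alpha > 0, alpha < 1)
  run <- function() {
    pv <- numeric(R)
    res <- NULL
    for (r in seq_len(R)) {
      res <- rqr(fit, standardize = TRUE)
      pv[r] <- stats::shapiro.test(as.numeric(res))$p.value
    }
    list(pv = pv, last = res)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(replicate_pvalues = out$pv,
                 mean_pvalue = mean(out$pv),
                 prop_above_alpha = mean(out$pv > alpha),
                 alpha = alpha,
                 rtype = "rqr",
                 moments = moments_summary(out$last),
                 seed = seed,
                 n = fit$n),
            class = "gof_report")
}

#' Sample moments of a residual vector
#'
#' Mean, variance (`n - 1` denominator), skewness `m3 / m2^(3/2)` and excess
#' kurtosis `m4 / m2^2 - 3`, using population-style central-moment
#' estimators for the shape measures. For a standard normal sample these are
#' close to (0, 1, 0, 0).
#'
#' @param res numeric or `"count_resid"` vector, `n >= 4`.
#' @return list with `mean`, `variance`, `skewness`, `excess_kurtosis`.
#' @export
moments_summary <- function(res) {
  x <- as.numeric(res)
  n <- length(x)
  if (n < 4L) stop("need at least 4 values", call. = FALSE)
  m <- mean(x)
  c2 <- mean((x - m)^2)
  if (c2 == 0) stop("degenerate (constant) input", call. = FALSE)
  c3 <- mean((x - m)^3)
  c4 <- mean((x - m)^4)
  list(mean = m,
       variance = stats::var(x),
       skewness = c3 / c2^1.5,
       excess_kurtosis = c4 / c2^2 - 3)
}

#' Normal QQ plot data with a simulated envelope
#'
#' Builds the simulated envelope for a residual QQ plot: (1) take the fitted
#' model; (2) sort its residuals; (3) simulate `n_sim` response vectors from
#' the fitted parameters on the same design; (4) refit the same model to
#' each simulated response and sort its residuals; (5) per order statistic,
#' take the 2.5% and 97.5% percentiles across simulations as the envelope.
#' Theoretical quantiles are the usual normal-scores approximation
#' `qnorm((i - 3/8) / (n + 1/4))`. Refits that fail to converge are dropped;
#' more than 10% failures is an error.
#'
#' @param fit a converged [fit_count_model()] result.
#' @param type residual type to diagnose (default `"rqr"`).
#' @param n_sim number of simulated response vectors (>= 20; default 100).
#' @param seed optional seed controlling simulation and randomization.
#' @param probs lower/upper envelope percentiles.
#' @return a list of class `"qq_envelope"`: `sorted_residuals`,
#'   `theoretical_quantiles`, `lower_band`, `upper_band`, `n_sim` (number
#'   actually used), `n_failed`, `prop_outside`.
#' @export
qq_envelope <- function(fit, type = c("rqr", "pearson", "deviance", "mqr"),
                        n_sim = 100L, seed = NULL,
                        probs = c(0.025, 0.975)) {
  check_fit(fit)
  type <- match.arg(type)
  if (n_sim < 20L) stop("'n_sim' must be at least 20", call. = FALSE)
  run <- function() {
    obs <- sort(as.numeric(residuals(fit, type = type)))
    n <- fit$n
    sims <- matrix(NA_real_, n, n_sim)
    failed <- 0L
    for (s in seq_len(n_sim)) {
      ysim <- count_sample(fit$fitted_family)
      rf <- tryCatch(refit_response(fit, ysim), error = function(e) NULL)
      if (is.null(rf) || !rf$converged) {
        failed <- failed + 1L
        next
      }
      sims[, s] <- sort(as.numeric(residuals(rf, type = type)))
    }
    if (failed > 0.1 * n_sim)
      stop("more than 10% of envelope refits failed (", failed, "/", n_sim,
           ")", call. = FALSE)
    if (failed > 0L)
      message(failed, " envelope refit(s) failed and were dropped")
    sims <- sims[, colSums(is.na(sims)) == 0, drop = FALSE]
    lo <- apply(sims, 1, stats::quantile, probs = probs[1])
    hi <- apply(sims, 1, stats::quantile, probs = probs[2])
    i <- seq_len(n)
    structure(list(
      sorted_residuals = obs,
      theoretical_quantiles = stats::qnorm((i - 3 / 8) / (n + 1 / 4)),
      lower_band = lo,
      upper_band = hi,
      n_sim = ncol(sims),
      n_failed = failed,
      prop_outside = mean(obs < lo | obs > hi),
      rtype = type
    ), class = "qq_envelope")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.qq_envelope <- function(x, ...) {
  cat("Simulated-envelope QQ data (", x$rtype, "), n = ",
      length(x$sorted_residuals), ", n_sim = ", x$n_sim, "\n", sep = "")
  cat("  fraction of residuals outside the envelope:",
      signif(x$prop_outside, 4), "\n")
  invisible(x)
}

#' Plot a simulated-envelope QQ diagnostic
#'
#' @param x a [qq_envelope()] result.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.qq_envelope <- function(x, ...) {
  rng <- range(x$sorted_residuals, x$lower_band, x$upper_band)
  plot(x$theoretical_quantiles, x$sorted_residuals, ylim = rng,
       xlab = "Theoretical quantiles", ylab = "Sorted residuals",
       main = paste0("QQ plot with simulated envelope (", x$rtype, ")"),
       ...)
  graphics::lines(x$theoretical_quantiles, x$lower_band, lty = 2,
                  col = "red")
  graphics::lines(x$theoretical_quantiles, x$upper_band, lty = 2,
                  col = "red")
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' Residual scatter-plot payload
#'
#' Returns the data behind residual-vs-fitted or residual-vs-covariate
#' scatter plots: one row per observation with the x variable, the
#' residual, the response, and the PIT value when the residual type
#' carries one.
#'
#' @param fit the [fit_count_model()] result the residuals came from.
#' @param res a `"count_resid"` vector computed from `fit`.
#' @param against `"fitted"` or `"covariate"`.
#' @param covariate covariate name (required when `against = "covariate"`).
#' @return a data frame with columns `x`, `residual`, `y`, and `pit`
#'   (NA for Pearson/deviance residuals).
#' @export
scatter_data <- function(fit, res, against = c("fitted", "covariate"),
                         covariate = NULL) {
  check_fit(fit)
  against <- match.arg(against)
  if (length(res) != fit$n)
    stop("residuals and fit have different lengths", call. = FALSE)
  x <- if (against == "fitted") {
    fit$mu_hat
  } else {
    if (is.null(covariate)) stop("'covariate' must be named", call. = FALSE)
    if (!covariate %in% names(fit$data))
      stop("unknown covariate '", covariate, "'", call. = FALSE)
    fit$data[[covariate]]
  }
  pit <- attr(res, "pit")
  data.frame(x = x, residual = as.numeric(res), y = fit$y,
             pit = if (is.null(pit)) NA_real_ else pit)
}
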