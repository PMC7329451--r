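#' Per-observation parameters of a count distribution family
#'
#' Bundles the parameters of one of four count families: Poisson, negative
#' binomial (NB), zero-inflated Poisson (ZIP) or zero-inflated negative
#' binomial (ZINB). `lambda` is the mean of the count component (per
#' observation), `k` the NB shape shared across observations (variance of the
#' count component is `lambda + lambda^2/k`), and `p_zero` the per-observation
#' probability of a structural zero in the zero-inflated families.
#'
#' @param family one of `"poisson"`, `"nb"`, `"zip"`, `"zinb"`.
#' @param lambda positive numeric vector of count-component means.
#' @param k positive scalar shape; required for `"nb"`/`"zinb"`, forbidden
#'   otherwise.
#' @param p_zero numeric vector in `[0, 1)` of structural-zero probabilities;
#'   required for `"zip"`/`"zinb"`, forbidden otherwise. Recycled to the
#'   length of `lambda`.
#' @return an object of class `"count_family"`: a list with elements
#'   `family`, `lambda`, and (when present) `k` and `p_zero`.
#' @examples
#' count_family("zip", lambda = 2, p_zero = 0.3)
#' count_family("nb", lambda = c(1, 5), k = 2)
#' @export
count_family <- function(family = c("poisson", "nb", "zip", "zinb"),
                         lambda, k = NULL, p_zero = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) < 1L ||
      any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("'lambda' must be a finite positive numeric vector", call. = FALSE)
  }
  has_k <- family %in% c("nb", "zinb")
  has_p <- family %in% c("zip", "zinb")
  if (has_k) {
    if (is.null(k) || length(k) != 1L || !is.finite(k) || k <= 0)
      stop("family '", family, "' requires a positive scalar shape 'k'",
           call. = FALSE)
  } else if (!is.null(k)) {
    stop("family '", family, "' does not take a shape 'k'", call. = FALSE)
  }
  if (has_p) {
    if (is.null(p_zero) || any(!is.finite(p_zero)) ||
        any(p_zero < 0) || any(p_zero >= 1))
      stop("family '", family, "' requires 'p_zero' in [0, 1)", call. = FALSE)
    p_zero <- rep_len(as.numeric(p_zero), length(lambda))
  } else if (!is.null(p_zero)) {
    stop("family '", family, "' does not take 'p_zero'", call. = FALSE)
  }
  structure(
    list(family = family, lambda = as.numeric(lambda),
         k = if (has_k) as.numeric(k), p_zero = if (has_p) p_zero),
    class = "count_family"
  )
}

#' @export
print.count_family <- function(x, ...) {
  cat("<count_family> ", x$family, ", n = ", length(x$lambda), "\n", sep = "")
  cat("  lambda: ", paste(signif(utils::head(x$lambda, 5), 4), collapse = " "),
      if (length(x$lambda) > 5) " ...", "\n", sep = "")
  if (!is.null(x$k)) cat("  k:      ", signif(x$k, 6), "\n", sep = "")
  if (!is.null(x$p_zero))
    cat("  p_zero: ", paste(signif(utils::head(x$p_zero, 5), 4),
                            collapse = " "),
        if (length(x$p_zero) > 5) " ...", "\n", sep = "")
  invisible(x)
}

check_counts <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      any(y != floor(y)))
    stop("'y' must be a vector of non-negative integers", call. = FALSE)
  as.numeric(y)
}

# log(exp(a) + exp(b)), elementwise, without underflow
log_add <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Probability mass function of a ZIP distribution
#'
#' The zero-inflated Poisson mixes a point mass at zero (probability
#' `p_zero`) with a Poisson(`lambda`) count. Its mass at zero is
#' `p_zero + (1 - p_zero) * exp(-lambda)`.
#'
#' @param y vector of non-negative integers.
#' @param lambda Poisson-component mean(s).
#' @param p_zero structural-zero probability(ies) in `[0, 1)`.
#' @param log logical; return log-probabilities?
#' @return numeric vector of (log) probabilities.
#' @examples
#' dzip(0, lambda = 1, p_zero = 0.5)  # 0.5 + 0.5 * exp(-1)
#' @export
dzip <- function(y, lambda, p_zero, log = FALSE) {
  y <- check_counts(y)
  lp0 <- log(p_zero)
  l1p <- log1p(-p_zero)
  out <- ifelse(y == 0,
                log_add(lp0, l1p - lambda),
                l1p + stats::dpois(y, lambda, log = TRUE))
  # p_zero = 0 gives lp0 = -Inf and log_add() -Inf - -Inf = NaN; degenerate
  # mixture reduces to the plain Poisson mass exp(-lambda)
  out <- ifelse(y == 0 & rep_len(p_zero, length(y)) == 0,
                -rep_len(lambda, length(y)), out)
  if (log) out else exp(out)
}

#' Cumulative distribution function of a ZIP distribution
#'
#' Closed form `p_zero + (1 - p_zero) * ppois(y, lambda)` for `y >= 0`,
#' 0 below the support.
#'
#' @inheritParams dzip
#' @return numeric vector of probabilities.
#' @export
pzip <- function(y, lambda, p_zero) {
  ifelse(y < 0, 0, p_zero + (1 - p_zero) * stats::ppois(y, lambda))
}

#' Random generation from a ZIP distribution
#'
#' Two-stage mixture draw: a structural zero with probability `p_zero`,
#' otherwise a Poisson(`lambda`) count.
#'
#' @param n number of draws.
#' @inheritParams dzip
#' @return integer vector of length `n`.
#' @export
rzip <- function(n, lambda, p_zero) {
  structural <- stats::rbinom(n, 1L, p_zero) == 1L
  out <- stats::rpois(n, lambda)
  out[structural] <- 0L
  out
}

#' Probability mass function of a ZINB distribution
#'
#' Zero-inflated negative binomial: a point mass at zero with probability
#' `p_zero`, otherwise NB with mean `lambda` and shape `k`
#' (count-component variance `lambda + lambda^2/k`).
#'
#' @inheritParams dzip
#' @param k positive NB shape.
#' @return numeric vector of (log) probabilities.
#' @export
dzinb <- function(y, lambda, k, p_zero, log = FALSE) {
  y <- check_counts(y)
  lp0 <- log(p_zero)
  l1p <- log1p(-p_zero)
  lnb <- stats::dnbinom(y, size = k, mu = lambda, log = TRUE)
  out <- ifelse(y == 0, log_add(lp0, l1p + lnb), l1p + lnb)
  out <- ifelse(y == 0 & rep_len(p_zero, length(y)) == 0, lnb, out)
  if (log) out else exp(out)
}

#' Cumulative distribution function of a ZINB distribution
#'
#' @inheritParams dzinb
#' @return numeric vector of probabilities.
#' @export
pzinb <- function(y, lambda, k, p_zero) {
  ifelse(y < 0, 0,
         p_zero + (1 - p_zero) * stats::pnbinom(y, size = k, mu = lambda))
}

#' Random generation from a ZINB distribution
#'
#' @param n number of draws.
#' @inheritParams dzinb
#' @return integer vector of length `n`.
#' @export
rzinb <- function(n, lambda, k, p_zero) {
  structural <- stats::rbinom(n, 1L, p_zero) == 1L
  out <- stats::rnbinom(n, size = k, mu = lambda)
  out[structural] <- 0L
  out
}

#' Family-generic PMF, CDF, lower-limit CDF, moments and sampling
#'
#' These helpers evaluate the distribution of a [count_family()] object
#' observation-wise: `count_pmf()` and `count_cdf()` are the mass and
#' distribution functions, `count_cdf_lower()` is the lower limit
#' `F(y-) = F(y - 1)` on integer support (exactly 0 at `y = 0`),
#' `count_mean_var()` returns the marginal mean and variance per observation,
#' and `count_sample()` draws one response per observation.
#'
#' For ZIP the marginal moments are `E(y) = (1 - p) * lambda` and
#' `V(y) = (1 - p) * lambda * (1 + p * lambda)`; for ZINB,
#' `V(y) = (1 - p) * (lambda + lambda^2/k) + p * (1 - p) * lambda^2`.
#'
#' @param y vector of non-negative integers, recycled against the parameters.
#' @param fam a [count_family()] object.
#' @param log logical; return log-probabilities from `count_pmf()`?
#' @return `count_pmf()`, `count_cdf()`, `count_cdf_lower()`: numeric vectors
#'   of probabilities; `count_mean_var()`: a list with `mean` and `var`
#'   vectors; `count_sample()`: an integer vector with one draw per
#'   observation.
#' @examples
#' fam <- count_family("zip", lambda = 2, p_zero = 0.3)
#' count_pmf(0:3, count_family("zip", lambda = rep(2, 4), p_zero = 0.3))
#' count_mean_var(fam)  # mean 1.4, var 2.24
#' @export
count_pmf <- function(y, fam, log = FALSE) {
  stopifnot(inherits(fam, "count_family"))
  y <- check_counts(y)
  switch(fam$family,
    poisson = stats::dpois(y, fam$lambda, log = log),
    nb      = stats::dnbinom(y, size = fam$k, mu = fam$lambda, log = log),
    zip     = dzip(y, fam$lambda, fam$p_zero, log = log),
    zinb    = dzinb(y, fam$lambda, fam$k, fam$p_zero, log = log))
}

#' @rdname count_pmf
#' @export
count_cdf <- function(y, fam) {
  stopifnot(inherits(fam, "count_family"))
  if (any(!is.finite(y))) stop("'y' must be finite", call. = FALSE)
  yf <- floor(y)
  switch(fam$family,
    poisson = ifelse(yf < 0, 0, stats::ppois(yf, fam$lambda)),
    nb      = ifelse(yf < 0, 0,
                     stats::pnbinom(yf, size = fam$k, mu = fam$lambda)),
    zip     = pzip(yf, fam$lambda, fam$p_zero),
    zinb    = pzinb(yf, fam$lambda, fam$k, fam$p_zero))
}

#' @rdname count_pmf
#' @export
count_cdf_lower <- function(y, fam) {
  y <- check_counts(y)
  count_cdf(y - 1, fam)
}

#' @rdname count_pmf
#' @export
count_mean_var <- function(fam) {
  stopifnot(inherits(fam, "count_family"))
  lam <- fam$lambda
  switch(fam$family,
    poisson = list(mean = lam, var = lam),
    nb      = list(mean = lam, var = lam + lam^2 / fam$k),
    zip     = {
      p <- fam$p_zero
      list(mean = (1 - p) * lam, var = (1 - p) * lam * (1 + p * lam))
    },
    zinb    = {
      p <- fam$p_zero
      list(mean = (1 - p) * lam,
           var = (1 - p) * (lam + lam^2 / fam$k) + p * (1 - p) * lam^2)
    })
}

#' @rdname count_pmf
#' @export
count_sample <- function(fam) {
  stopifnot(inherits(fam, "count_family"))
  n <- length(fam$lambda)
  switch(fam$family,
    poisson = stats::rpois(n, fam$lambda),
    nb      = stats::rnbinom(n, size = fam$k, mu = fam$lambda),
    zip     = rzip(n, fam$lambda, fam$p_zero),
    zinb    = rzinb(n, fam$lambda, fam$k, fam$p_zero))
}
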