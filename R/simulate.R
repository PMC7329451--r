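# Scenario generators. Each returns a list with the simulated data frame and
# the paired true/wrong model specifications (family + formula + zero part),
# so the harness can fit both sides mechanically.

spec_entry <- function(family, formula, zero_formula = NULL) {
  list(family = family, formula = formula, zero_formula = zero_formula)
}

#' Simulation scenario generators
#'
#' Each generator draws one dataset from a known true count model paired
#' with a misspecified alternative:
#'
#' * `gen_illustrative(n)`: Poisson with a sinusoidal log mean,
#'   `log(mu) = -1 + 2*sin(2*x)`, `x ~ Uniform(0, 2*pi)`; the wrong model
#'   forces a linear effect `log(mu) = b0 + b1*x`.
#' * `gen_nonlinearity(n, beta1, k)`: NB (shape `k`, default 2) with a
#'   quadratic log mean `log(mu) = beta1 * x^2`, `x ~ Uniform(-1.5, 1.5)`;
#'   the wrong model takes `x` as linear. `beta1` in `{0.5, 1, 2}` grades
#'   the degree of non-linearity (default 1).
#' * `gen_overdispersion(n, k)`: NB with `log(mu) = 1 + 2*x`,
#'   `x ~ Uniform(-1, 2)`, shape `k` in `{1, 2, 10}` (default 2); the wrong
#'   model is Poisson with the same mean structure.
#' * `gen_zeroinflation(n, p_zero)`: ZIP with `lambda = exp(1 + 2*x)`,
#'   `x ~ Uniform(-1, 2)` and constant structural-zero probability
#'   `p_zero` in `{0.1, 0.3, 0.5}` (default 0.3); the wrong model is
#'   Poisson ignoring the zero inflation.
#'
#' @param n sample size.
#' @param beta1 quadratic-effect size (non-linearity scenario).
#' @param k NB shape.
#' @param p_zero structural-zero probability (zero-inflation scenario).
#' @return a list with `data` (data frame with columns `x`, `y`), `true`
#'   and `wrong` model specifications, and `truth` (the generating
#'   parameters).
#' @examples
#' set.seed(7)
#' d <- gen_zeroinflation(200, p_zero = 0.3)
#' mean(d$data$y == 0)  # at least 0.3
#' @export
gen_illustrative <- function(n) {
  x <- stats::runif(n, 0, 2 * pi)
  lam <- exp(-1 + 2 * sin(2 * x))
  list(data = data.frame(x = x, y = stats::rpois(n, lam)),
       true = spec_entry("poisson", y ~ sin(2 * x)),
       wrong = spec_entry("poisson", y ~ x),
       truth = list(beta = c(-1, 2), family = "poisson"))
}

#' @rdname gen_illustrative
#' @export
gen_nonlinearity <- function(n, beta1 = 1, k = 2) {
  x <- stats::runif(n, -1.5, 1.5)
  lam <- exp(beta1 * x^2)
  list(data = data.frame(x = x,
                         y = stats::rnbinom(n, size = k, mu = lam)),
       true = spec_entry("nb", y ~ I(x^2)),
       wrong = spec_entry("nb", y ~ x),
       truth = list(beta = c(0, beta1), k = k, family = "nb"))
}

#' @rdname gen_illustrative
#' @export
gen_overdispersion <- function(n, k = 2) {
  x <- stats::runif(n, -1, 2)
  lam <- exp(1 + 2 * x)
  list(data = data.frame(x = x,
                         y = stats::rnbinom(n, size = k, mu = lam)),
       true = spec_entry("nb", y ~ x),
       wrong = spec_entry("poisson", y ~ x),
       truth = list(beta = c(1, 2), k = k, family = "nb"))
}

#' @rdname gen_illustrative
#' @export
gen_zeroinflation <- function(n, p_zero = 0.3) {
  x <- stats::runif(n, -1, 2)
  lam <- exp(1 + 2 * x)
  list(data = data.frame(x = x, y = rzip(n, lam, p_zero)),
       true = spec_entry("zip", y ~ x, ~1),
       wrong = spec_entry("poisson", y ~ x),
       truth = list(beta = c(1, 2), p_zero = p_zero, family = "zip"))
}

generator_for <- function(name, param) {
  switch(name,
    illustrative   = function(n) gen_illustrative(n),
    nonlinearity   = function(n) gen_nonlinearity(n, beta1 = param),
    overdispersion = function(n) gen_overdispersion(n, k = param),
    zeroinflation  = function(n) gen_zeroinflation(n, p_zero = param),
    stop("unknown scenario '", name, "'", call. = FALSE))
}

#' Define a simulation scenario
#'
#' A container for one type-I-error/power experiment: which generator, what
#' sample sizes, the scenario parameter (effect size `beta1`, shape `k`, or
#' `p_zero` depending on the scenario), replicate count, test level and
#' master seed.
#'
#' @param name `"illustrative"`, `"nonlinearity"`, `"overdispersion"` or
#'   `"zeroinflation"`.
#' @param n vector of sample sizes (the power-study grid is
#'   `c(20, 50, 100, 200, 400, 600, 800, 1000)`).
#' @param param scenario parameter; `NA` for `"illustrative"`. Defaults to
#'   the middle setting of each scenario.
#' @param reps replicates per cell (default 1000; MC SE of a 5% rate is then
#'   about 0.007).
#' @param alpha rejection level for the SW p-values.
#' @param seed master seed; each replicate gets its own derived substream.
#' @return a list of class `"count_scenario"`.
#' @export
count_scenario <- function(name = c("illustrative", "nonlinearity",
                                    "overdispersion", "zeroinflation"),
                           n = 400L, param = NULL, reps = 1000L,
                           alpha = 0.05, seed = 1L) {
  name <- match.arg(name)
  if (is.null(param))
    param <- switch(name, illustrative = NA_real_, nonlinearity = 1,
                    overdispersion = 2, zeroinflation = 0.3)
  stopifnot(reps >= 1L, alpha > 0, alpha < 1, all(n >= 10))
  structure(list(name = name, n = as.integer(n), param = param,
                 reps = as.integer(reps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "count_scenario")
}

fit_from_spec <- function(spec, data) {
  if (is.null(spec$zero_formula)) {
    fit_count_model(spec$formula, data, family = spec$family)
  } else {
    fit_count_model(spec$formula, data, family = spec$family,
                    zero_formula = spec$zero_formula)
  }
}

#' Type-I-error and power study of residual-based SW tests
#'
#' For each sample size in the scenario and each replicate: simulate a
#' dataset from the true model, fit the true and the misspecified model,
#' compute all four residual types on each (one standardized RQR draw per
#' replicate), Shapiro-Wilk-test each residual vector, and record whether
#' its p-value falls below `alpha`. The rejection rate under the true model
#' is the empirical type I error; under the wrong model it is the power.
#' Replicates in which a fit does not converge are excluded (and counted),
#' not treated as rejections.
#'
#' @param scenario a [count_scenario()].
#' @param models which side(s) to fit: `"true"`, `"wrong"` or both.
#' @param residuals which residual types to tabulate.
#' @return a tidy data frame with one row per (n, model, residual type):
#'   columns `scenario`, `param`, `n`, `model`, `residual`,
#'   `rejection_rate`, `mc_se` (`sqrt(r*(1-r)/reps_used)`), `reps_used`,
#'   `reps_failed`, `alpha`.
#' @examples
#' \donttest{
#' sc <- count_scenario("overdispersion", n = 100, reps = 50, seed = 42)
#' run_type1_power(sc, models = "true", residuals = "rqr")
#' }
#' @export
run_type1_power <- function(scenario,
                            models = c("true", "wrong"),
                            residuals = c("rqr", "mqr", "deviance",
                                          "pearson")) {
  stopifnot(inherits(scenario, "count_scenario"))
  models <- match.arg(models, several.ok = TRUE)
  residuals <- match.arg(residuals, several.ok = TRUE)
  gen <- generator_for(scenario$name, scenario$param)
  rows <- list()
  for (n in scenario$n) {
    rep_seeds <- with_seed(scenario$seed + n,
                           sample.int(.Machine$integer.max - 1L,
                                      scenario$reps))
    rej <- array(NA, dim = c(scenario$reps, length(models),
                             length(residuals)),
                 dimnames = list(NULL, models, residuals))
    failed <- 0L
    for (r in seq_len(scenario$reps)) {
      ok <- with_seed(rep_seeds[r], {
        sim <- gen(n)
        fits <- lapply(sim[models], function(sp) {
          tryCatch({
            f <- fit_from_spec(sp, sim$data)
            if (!f$converged) NULL else f
          }, error = function(e) NULL)
        })
        if (any(vapply(fits, is.null, logical(1)))) {
          FALSE
        } else {
          for (m in models) {
            for (rt in residuals) {
              res <- residuals(fits[[m]], type = rt)
              rej[r, m, rt] <- stats::shapiro.test(
                as.numeric(res))$p.value < scenario$alpha
            }
          }
          TRUE
        }
      })
      if (!ok) failed <- failed + 1L
    }
    for (m in models) {
      for (rt in residuals) {
        v <- rej[, m, rt]
        v <- v[!is.na(v)]
        rate <- mean(v)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scenario$name, param = scenario$param, n = n,
          model = m, residual = rt, rejection_rate = rate,
          mc_se = sqrt(rate * (1 - rate) / length(v)),
          reps_used = length(v), reps_failed = failed,
          alpha = scenario$alpha)
      }
    }
  }
  do.call(rbind, rows)
}
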