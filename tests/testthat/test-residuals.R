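test_that("Pearson residuals reproduce the family-specific scalings", {
  # Poisson: (y - lambda)/sqrt(lambda)
  f <- fake_fit("poisson", y = c(4, 1), lambda = 4)
  expect_equal(as.numeric(pearson_resid(f)), c(0, -1.5), tolerance = 1e-12)
  # ZIP: mean 2.4, variance 2.4 * 1.6
  fz <- fake_fit("zip", y = 2, lambda = 3, p_zero = 0.2)
  expect_equal(as.numeric(pearson_resid(fz)),
               (2 - 2.4) / sqrt(2.4 * 1.6), tolerance = 1e-10)
  # NB: variance lambda + lambda^2/k
  fnb <- fake_fit("nb", y = 7, lambda = 3, k = 2)
  expect_equal(as.numeric(pearson_resid(fnb)), (7 - 3) / sqrt(3 + 9 / 2),
               tolerance = 1e-12)
  # ZINB uses the printed denominator with the p^2 + p term
  fzb <- fake_fit("zinb", y = 5, lambda = 3, k = 2, p_zero = 0.2)
  denom <- 0.8 * (3 + 9 / 2) + 9 * (0.04 + 0.2)
  expect_equal(as.numeric(pearson_resid(fzb)), (5 - 2.4) / sqrt(denom),
               tolerance = 1e-12)
})

test_that("deviance residuals match hand values and the deviance identity", {
  # Poisson y = lambda: saturated equals fitted
  f <- fake_fit("poisson", y = c(2, 0), lambda = c(2, 2))
  r <- deviance_resid(f)
  expect_equal(r[1], 0, tolerance = 1e-12)
  # Poisson y = 0, lambda = 2: -sqrt(2 * 2) = -2
  expect_equal(r[2], -2, tolerance = 1e-12)
  # NB closed form (independent of the loglik-difference implementation)
  y <- c(0, 1, 4, 9); lam <- c(2, 2, 3, 3); k <- 2
  fnb <- fake_fit("nb", y = y, lambda = lam, k = k)
  ylogy <- ifelse(y == 0, 0, y * log(y / lam))
  d_closed <- 2 * (ylogy - (y + k) * log((y + k) / (lam + k)))
  expect_equal(as.numeric(deviance_resid(fnb)),
               sign(y - lam) * sqrt(d_closed), tolerance = 1e-10)
  # sum of squares equals twice the saturated-fitted loglik gap
  fit <- small_pois_fit()
  r2 <- sum(deviance_resid(fit)^2)
  gap <- 2 * (sum(loglik_saturated(fit$y, "poisson")) -
                sum(count_pmf(fit$y, fit$fitted_family, log = TRUE)))
  expect_equal(r2, gap, tolerance = 1e-8)
})

test_that("ZIP deviance follows the zero/positive branch decomposition", {
  y <- c(0, 0, 3, 6); lam <- 2.5; p <- 0.25
  fz <- fake_fit("zip", y = y, lambda = lam, p_zero = p)
  # branch formula written out directly
  sat <- dpois(y, y, log = TRUE)
  lfit <- ifelse(y == 0, log(p + (1 - p) * exp(-lam)),
                 log(1 - p) + dpois(y, lam, log = TRUE))
  expect_equal(as.numeric(deviance_resid(fz)),
               sign(y - (1 - p) * lam) * sqrt(2 * (sat - lfit)),
               tolerance = 1e-10)
})

test_that("randomized PIT is uniform under the true parameters", {
  set.seed(11)
  n <- 2e4
  cases <- list(
    fake_fit("poisson", rpois(n, 2.5), 2.5),
    fake_fit("nb", rnbinom(n, size = 2, mu = 3), 3, k = 2),
    fake_fit("zip", rzip(n, 2, 0.3), 2, p_zero = 0.3),
    fake_fit("zinb", rzinb(n, 2, 2, 0.3), 2, k = 2, p_zero = 0.3))
  for (f in cases) {
    r <- rqr(f, standardize = FALSE)
    expect_gt(ks.test(attr(r, "pit"), "punif")$p.value, 0.01)
    # and the residuals themselves look standard normal
    expect_gt(ks.test(as.numeric(r), "pnorm")$p.value, 0.01)
  }
})

test_that("rqr is bitwise reproducible under a seed, and restores RNG", {
  fit <- small_pois_fit()
  r1 <- rqr(fit, seed = 99)
  set.seed(1234)
  before <- .Random.seed
  r2 <- rqr(fit, seed = 99)
  expect_identical(.Random.seed, before)  # caller's stream untouched
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_false(identical(as.numeric(rqr(fit)), as.numeric(rqr(fit))))
})

test_that("mqr is the u = 0.5 quantile residual and is deterministic", {
  # y = 0, Poisson lambda = 1: qnorm(0.5 * exp(-1))
  f <- fake_fit("poisson", y = 0, lambda = 1)
  expect_equal(as.numeric(mqr(f)), qnorm(0.5 * exp(-1)), tolerance = 1e-6)
  fit <- small_pois_fit()
  expect_identical(as.numeric(mqr(fit)), as.numeric(mqr(fit)))
  # quantile residual is increasing in u at fixed y
  pit_lo <- attr(mqr(f), "pit")
  r_hi <- rqrdiag:::quantile_resid_core(f, 0.9, "rqr")
  expect_gt(as.numeric(r_hi), as.numeric(mqr(f)))
})

test_that("deterministic residuals sit on curves; RQRs do not", {
  set.seed(12)
  d <- gen_overdispersion(400, k = 2)$data
  fit <- fit_count_model(y ~ x, d, family = "nb")
  at_y <- d$y == min(d$y[d$y > 0])  # a common response value
  stopifnot(sum(at_y) > 10)
  for (rt in c("pearson", "deviance", "mqr")) {
    res <- as.numeric(residuals(fit, type = rt))
    # residual at fixed y is a smooth monotone function of mu_hat:
    # ordering by mu_hat reverses the residual ordering exactly
    o <- order(fit$mu_hat[at_y])
    expect_true(all(diff(res[at_y][o]) <= 1e-12))
  }
  rres <- as.numeric(rqr(fit, seed = 5))
  expect_false(all(diff(rres[at_y][order(fit$mu_hat[at_y])]) <= 0))
})

test_that("standardization gives exact zero mean and unit variance", {
  expect_equal(standardize_residuals(c(1, 2, 3)), c(-1, 0, 1))
  fit <- small_pois_fit()
  r <- rqr(fit, seed = 3, standardize = FALSE)
  z <- standardize_residuals(r)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(var(as.numeric(z)), 1, tolerance = 1e-12)
  expect_true(attr(z, "standardized"))
  # idempotent
  expect_equal(as.numeric(standardize_residuals(z)), as.numeric(z),
               tolerance = 1e-12)
  expect_error(standardize_residuals(rep(1, 10)), "constant")
  expect_error(standardize_residuals(1), "at least two")
})

test_that("residuals() dispatches on type and refuses unconverged fits", {
  fit <- small_pois_fit()
  expect_identical(as.numeric(residuals(fit, "mqr")),
                   as.numeric(mqr(fit)))
  expect_identical(as.numeric(residuals(fit, "rqr", seed = 2)),
                   as.numeric(rqr(fit, seed = 2)))
  bad <- fit
  bad$converged <- FALSE
  expect_error(rqr(bad), "unconverged")
  expect_error(pearson_resid(bad), "unconverged")
})
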