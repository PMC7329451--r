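test_that("ZIP pmf matches its closed form and degenerates to Poisson", {
  # hand evaluation of the mixture mass at zero
  expect_equal(dzip(0, lambda = 1, p_zero = 0.5), 0.5 + 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(dzip(0, lambda = 7, p_zero = 0.2), 0.2 + 0.8 * exp(-7),
               tolerance = 1e-12)
  # degenerate mixture: p_zero = 0 is a plain Poisson at every y
  y <- 0:20
  expect_equal(dzip(y, lambda = 3, p_zero = 0), dpois(y, 3),
               tolerance = 1e-12)
  # log scale agrees with linear scale
  expect_equal(dzip(y, 2.5, 0.3, log = TRUE), log(dzip(y, 2.5, 0.3)),
               tolerance = 1e-10)
})

test_that("ZIP/ZINB closed-form CDFs agree with brute-force pmf summation", {
  y <- 0:50
  brute_zip <- cumsum(dzip(y, lambda = 2, p_zero = 0.3))
  expect_equal(pzip(y, 2, 0.3), brute_zip, tolerance = 1e-12)
  brute_zinb <- cumsum(dzinb(y, lambda = 2, k = 1.5, p_zero = 0.3))
  expect_equal(pzinb(y, 2, 1.5, 0.3), brute_zinb, tolerance = 1e-12)
  # normalization: total mass reaches 1
  expect_equal(brute_zip[length(y)], 1, tolerance = 1e-10)
  expect_equal(brute_zinb[length(y)], 1, tolerance = 1e-9)
})

test_that("lower-limit CDF satisfies F(y-) + p(y) = F(y) with F(0-) = 0", {
  fams <- list(
    count_family("poisson", rep(2, 31)),
    count_family("nb", rep(2, 31), k = 2),
    count_family("zip", rep(2, 31), p_zero = 0.3),
    count_family("zinb", rep(2, 31), k = 2, p_zero = 0.3))
  y <- 0:30
  for (fam in fams) {
    expect_equal(count_cdf_lower(y, fam) + count_pmf(y, fam),
                 count_cdf(y, fam), tolerance = 1e-12)
    expect_equal(count_cdf_lower(0, count_family(fam$family, 2, k = fam$k,
                                                 p_zero = fam$p_zero[1])),
                 0)
  }
  # Poisson: F(2-) = ppois(1; 3)
  expect_equal(count_cdf_lower(2, count_family("poisson", 3)), ppois(1, 3),
               tolerance = 1e-12)
})

test_that("cdf is nondecreasing and normalizes across a parameter grid", {
  grid <- expand.grid(lambda = c(0.3, 2, 10), k = c(0.5, 2),
                      p_zero = c(0, 0.4))
  y <- 0:3000  # wide enough that even the heavy NB(k = 0.5) tail is spent
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (famname in c("poisson", "nb", "zip", "zinb")) {
      fam <- switch(famname,
        poisson = count_family("poisson", rep(g$lambda, length(y))),
        nb = count_family("nb", rep(g$lambda, length(y)), k = g$k),
        zip = count_family("zip", rep(g$lambda, length(y)),
                           p_zero = g$p_zero),
        zinb = count_family("zinb", rep(g$lambda, length(y)), k = g$k,
                            p_zero = g$p_zero))
      cdf <- count_cdf(y, fam)
      expect_true(all(diff(cdf) >= -1e-15))
      expect_lt(1 - cdf[length(y)], 1e-10)           # tail is exhausted
      expect_equal(sum(count_pmf(y, fam)), 1, tolerance = 1e-9)
    }
  }
})

test_that("family nesting: ZI with p=0 and NB with huge k reduce correctly", {
  y <- 0:40
  lam <- rep(4, length(y))
  expect_equal(count_pmf(y, count_family("zip", lam, p_zero = 0)),
               count_pmf(y, count_family("poisson", lam)),
               tolerance = 1e-12)
  expect_equal(count_pmf(y, count_family("zinb", lam, k = 2, p_zero = 0)),
               count_pmf(y, count_family("nb", lam, k = 2)),
               tolerance = 1e-12)
  for (l in c(0.5, 3, 10)) {
    expect_equal(count_pmf(y, count_family("nb", rep(l, length(y)),
                                           k = 1e8)),
                 count_pmf(y, count_family("poisson", rep(l, length(y)))),
                 tolerance = 1e-6)
  }
})

test_that("ZIP/ZINB moments match hand values and Monte Carlo", {
  fam <- count_family("zip", 2, p_zero = 0.3)
  mv <- count_mean_var(fam)
  expect_equal(mv$mean, 1.4, tolerance = 1e-12)
  expect_equal(mv$var, 1.4 * (1 + 0.6), tolerance = 1e-12)
  # p = 0 reduces to Poisson moments
  mv0 <- count_mean_var(count_family("zip", 2, p_zero = 0))
  expect_equal(mv0$mean, 2)
  expect_equal(mv0$var, 2)
  # NB variance lambda + lambda^2/k
  mvnb <- count_mean_var(count_family("nb", 3, k = 2))
  expect_equal(mvnb$var, 3 + 9 / 2)
  # Monte Carlo check of ZIP and ZINB marginal moments (3 SE bands)
  set.seed(101)
  n <- 1e6
  yz <- rzip(n, 2, 0.3)
  expect_lt(abs(mean(yz) - 1.4), 3 * sqrt(2.24 / n))
  expect_lt(abs(var(yz) - 2.24), 0.02)
  fam2 <- count_family("zinb", 2, k = 2, p_zero = 0.3)
  mv2 <- count_mean_var(fam2)
  yz2 <- rzinb(n, 2, 2, 0.3)
  expect_lt(abs(mean(yz2) - mv2$mean), 3 * sqrt(mv2$var / n))
  expect_lt(abs(var(yz2) - mv2$var), 0.05)
})

test_that("sampling is reproducible and matches the pmf", {
  fam <- count_family("nb", rep(3, 1e5), k = 2)
  set.seed(7)
  s1 <- count_sample(fam)
  set.seed(7)
  s2 <- count_sample(fam)
  expect_identical(s1, s2)
  # chi-square GOF of the empirical distribution against the pmf
  cut <- 25
  obs <- tabulate(pmin(s1, cut) + 1L, nbins = cut + 1L)
  p <- count_pmf(0:(cut - 1), count_family("nb", rep(3, cut), k = 2))
  p <- c(p, 1 - sum(p))
  expect_gt(suppressWarnings(chisq.test(obs, p = p))$p.value, 0.001)
  # near-degenerate mixture: almost all structural zeros
  set.seed(8)
  expect_true(all(rzip(1000, 5, 1 - 1e-9) == 0))
})

test_that("invalid inputs are rejected", {
  expect_error(count_family("poisson", -1), "lambda")
  expect_error(count_family("nb", 1), "shape")
  expect_error(count_family("zip", 1), "p_zero")
  expect_error(count_family("zip", 1, p_zero = 1), "p_zero")
  expect_error(count_family("poisson", 1, k = 2), "does not take")
  expect_error(count_family("nb", 1, k = 2, p_zero = 0.1), "does not take")
  fam <- count_family("poisson", 2)
  expect_error(count_pmf(-1, fam), "non-negative")
  expect_error(count_pmf(1.5, fam), "non-negative")
})
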